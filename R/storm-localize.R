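# Frame-by-frame emitter localization and cross-correlation drift
# correction for blinking movies.

# shift a matrix by (dr, dc) with edge replication
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# local 3x3 maximum of a matrix
local_max3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- pmax(out, shift_mat(m, dr, dc))
  }
  out
}

# least-squares 2D Gaussian fit on a window; returns pixel-center coords
fit_gaussian_2d <- function(win, sigma0) {
  nr <- nrow(win); nc <- ncol(win)
  off0 <- median(win)
  wpos <- pmax(win - off0, 0)
  tot <- sum(wpos)
  if (tot <= 0) return(NULL)
  cx0 <- sum(col(win) * wpos) / tot
  cy0 <- sum(row(win) * wpos) / tot
  amp0 <- max(win) - off0
  obj <- function(p) {
    amp <- p[1]; cx <- p[2]; cy <- p[3]; lsig <- p[4]; off <- p[5]
    s2 <- exp(2 * lsig)
    mdl <- off + amp * exp(-((col(win) - cx)^2 + (row(win) - cy)^2) / (2 * s2))
    sum((win - mdl)^2)
  }
  res <- tryCatch(
    optim(c(amp0, cx0, cy0, log(sigma0), off0), obj, method = "L-BFGS-B",
          lower = c(0, 1, 1, log(0.3), -Inf),
          upper = c(Inf, nc, nr, log(max(nr, nc)), Inf)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  list(amp = res$par[1], cx = res$par[2], cy = res$par[3],
       sigma = exp(res$par[4]), offset = res$par[5])
}

#' Localize emitters frame by frame
#'
#' Per frame: background statistics are estimated robustly (median and
#' MAD); candidate peaks are 3x3 local maxima whose amplitude above
#' background is at least `snr_min` times the background SD; a
#' `peak_mask x peak_mask` window is cut around each candidate and windows
#' containing more than one candidate are discarded (multi-emitter
#' rejection); the surviving windows are fit with a 2D Gaussian for
#' sub-pixel positions, converted to nm.
#'
#' @param movie a `blink_movie` (3D array `[row, col, frame]`) or list of
#'   frame matrices.
#' @param peak_mask odd window size in pixels (default 9).
#' @param snr_min peak-intensity-to-noise threshold (default 6).
#' @param pixel_size_nm pixel pitch; taken from the movie attribute when
#'   present.
#' @param psf_sigma initial Gaussian width for the fits (pixels).
#' @return A `localization_table` data frame (`frame`, `x_nm`, `y_nm`,
#'   `intensity`, `precision_nm`).
#' @export
localize_frames <- function(movie, peak_mask = 9, snr_min = 6,
                            pixel_size_nm = NULL, psf_sigma = 1.3) {
  if (peak_mask %% 2 != 1) stop("peak_mask must be odd", call. = FALSE)
  if (is.null(pixel_size_nm))
    pixel_size_nm <- attr(movie, "pixel_size_nm")
  if (is.null(pixel_size_nm))
    stop("pixel_size_nm required", call. = FALSE)
  frames <- if (is.list(movie)) movie
  else lapply(seq_len(dim(movie)[3]), function(f) movie[, , f])
  half <- (peak_mask - 1L) / 2L
  rows <- list()
  for (f in seq_along(frames)) {
    img <- frames[[f]]
    bg <- median(img)
    noise <- mad(img)
    if (noise == 0) next # zero-variance frame: nothing to localize
    is_max <- img >= local_max3(img) & (img - bg) >= snr_min * noise
    cand <- which(is_max, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    # drop candidates whose window leaves the frame
    inside <- cand[, 1] > half & cand[, 1] <= nrow(img) - half &
      cand[, 2] > half & cand[, 2] <= ncol(img) - half
    cand <- cand[inside, , drop = FALSE]
    if (nrow(cand) == 0) next
    # multi-emitter rejection: discard every candidate whose window
    # contains another candidate
    if (nrow(cand) > 1) {
      cheb <- pmax(abs(outer(cand[, 1], cand[, 1], "-")),
                   abs(outer(cand[, 2], cand[, 2], "-")))
      crowded <- rowSums(cheb <= half) > 1
      cand <- cand[!crowded, , drop = FALSE]
    }
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; c <- cand[k, 2]
      win <- img[(r - half):(r + half), (c - half):(c + half)]
      fit <- fit_gaussian_2d(win, psf_sigma)
      if (is.null(fit)) next
      cx <- c - half - 1 + fit$cx  # frame pixel-center coords
      cy <- r - half - 1 + fit$cy
      photons <- max(fit$amp, 1) * 2 * pi * fit$sigma^2
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f,
        x_nm = (cx - 0.5) * pixel_size_nm,
        y_nm = (cy - 0.5) * pixel_size_nm,
        intensity = fit$amp,
        precision_nm = fit$sigma * pixel_size_nm / sqrt(photons))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                  intensity = numeric(0), precision_nm = numeric(0))
  structure(out, class = c("localization_table", "data.frame"))
}

# cross-correlation of two equally sized 2D histograms; returns the shift
# (in bins) of b relative to a, with sub-bin quadratic peak interpolation
xcorr_shift <- function(a, b) {
  fa <- fft(a)
  fb <- fft(b)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(cc); nc <- ncol(cc)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  # quadratic interpolation around the peak (cyclic indexing)
  interp <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den == 0) 0 else 0.5 * (cm - cp) / den
  }
  r <- pk[1]; c <- pk[2]
  rm <- ((r - 2) %% nr) + 1; rp <- (r %% nr) + 1
  cm <- ((c - 2) %% nc) + 1; cp <- (c %% nc) + 1
  dr <- interp(cc[rm, c], cc[r, c], cc[rp, c])
  dc <- interp(cc[r, cm], cc[r, c], cc[r, cp])
  c(dy = wrap(r, nr) - 1 + dr, dx = wrap(c, nc) - 1 + dc)
}

#' Correct stage drift by temporal-bin cross-correlation
#'
#' Splits the localizations into temporal bins, reconstructs a 2D
#' histogram image per bin, estimates each bin's translation relative to
#' the first by Fourier cross-correlation with sub-pixel quadratic peak
#' interpolation, interpolates the per-bin shifts to per-frame drift and
#' subtracts it from the coordinates.
#'
#' @param table a `localization_table`.
#' @param n_bins number of temporal bins (>= 2).
#' @param bin_nm histogram pixel size (nm).
#' @param min_per_bin minimum localizations required per temporal bin.
#' @return List with `table` (corrected), `drift` (per-frame `dx`, `dy`
#'   in nm) and `bin_shifts`.
#' @export
drift_correct <- function(table, n_bins = 5, bin_nm = 20, min_per_bin = 20) {
  if (n_bins < 2)
    stop("n_bins must be >= 2", call. = FALSE)
  fr <- table$frame
  edges <- seq(min(fr), max(fr) + 1, length.out = n_bins + 1)
  bin <- findInterval(fr, edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, n_bins)
  if (any(counts < min_per_bin))
    stop("insufficient localizations per temporal bin; try fewer bins",
         call. = FALSE)
  xr <- range(table$x_nm); yr <- range(table$y_nm)
  bx <- seq(xr[1], xr[2] + bin_nm, by = bin_nm)
  by <- seq(yr[1], yr[2] + bin_nm, by = bin_nm)
  hist2 <- function(idx) {
    h <- matrix(0, length(by) - 1, length(bx) - 1)
    ix <- findInterval(table$x_nm[idx], bx, rightmost.closed = TRUE)
    iy <- findInterval(table$y_nm[idx], by, rightmost.closed = TRUE)
    for (k in seq_along(ix)) h[iy[k], ix[k]] <- h[iy[k], ix[k]] + 1
    h
  }
  ref <- hist2(bin == 1)
  shifts <- t(vapply(seq_len(n_bins), function(b) {
    if (b == 1) return(c(dy = 0, dx = 0))
    xcorr_shift(hist2(bin == b), ref)
  }, c(dy = 0, dx = 0)))
  bin_centers <- (edges[-1] + edges[-length(edges)]) / 2
  frames_all <- seq(min(fr), max(fr))
  dx <- stats::approx(bin_centers, shifts[, "dx"] * bin_nm, xout = frames_all,
                      rule = 2)$y
  dy <- stats::approx(bin_centers, shifts[, "dy"] * bin_nm, xout = frames_all,
                      rule = 2)$y
  drift <- data.frame(frame = frames_all, dx_nm = dx, dy_nm = dy)
  idx <- match(fr, frames_all)
  out <- table
  out$x_nm <- table$x_nm - dx[idx]
  out$y_nm <- table$y_nm - dy[idx]
  list(table = out, drift = drift,
       bin_shifts = data.frame(bin = seq_len(n_bins),
                               frame = bin_centers,
                               dx_nm = shifts[, "dx"] * bin_nm,
                               dy_nm = shifts[, "dy"] * bin_nm))
}
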