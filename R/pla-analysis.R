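# Quantification of three-channel PLA stacks: channel segmentation
# (Gaussian blur + triangle threshold), punctum detection (in-plane
# maximum filter + prominence), signed Euclidean distance to the nuclear
# mask, and per-cell metrics.

# shift a [y, x, z] array by (dy, dx, dz) with edge replication
shift_arr <- function(a, dy, dx, dz) {
  d <- dim(a)
  yi <- pmin(pmax(seq_len(d[1]) - dy, 1L), d[1])
  xi <- pmin(pmax(seq_len(d[2]) - dx, 1L), d[2])
  zi <- pmin(pmax(seq_len(d[3]) - dz, 1L), d[3])
  a[yi, xi, zi, drop = FALSE]
}

# separable 3D Gaussian blur; sigma per axis (y, x, z) in voxels
gaussian_blur_3d <- function(a, sigma) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  out <- a
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (k in seq(-r, r)) {
      sh <- c(0L, 0L, 0L)
      sh[ax] <- k
      acc <- acc + w[k + r + 1] * shift_arr(out, sh[1], sh[2], sh[3])
    }
    out <- acc
  }
  out
}

#' Triangle threshold of a histogram
#'
#' Geometric automatic threshold: a chord is drawn from the histogram peak
#' to the far end of the longer tail; the threshold is the bin maximizing
#' the perpendicular distance between histogram and chord (axes normalized
#' to unit range).
#'
#' @param counts histogram counts.
#' @param mids bin midpoints (same length).
#' @return The threshold value (a bin midpoint).
#' @export
triangle_threshold_hist <- function(counts, mids) {
  stopifnot(length(counts) == length(mids), length(counts) >= 2)
  nz <- which(counts > 0)
  if (length(nz) < 2)
    stop("degenerate histogram: all mass in one bin", call. = FALSE)
  peak <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  # side with the longer tail
  end <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (end == peak)
    stop("degenerate histogram: no tail on either side", call. = FALSE)
  idx <- if (end > peak) peak:end else end:peak
  x <- (idx - peak) / (end - peak)          # 0 at peak, 1 at tail end
  y <- counts[idx] / counts[peak]           # 1 at peak, ~0 at tail end
  # distance from (x, y) to the chord from (0, 1) to (1, 0)
  dist_chord <- abs(x + y - 1) / sqrt(2)
  mids[idx[which.max(dist_chord)]]
}

#' Segment a channel by Gaussian blur and triangle thresholding
#'
#' Applies a 3D Gaussian blur to suppress noise, computes a 256-bin
#' histogram of the blurred volume and thresholds it with the triangle
#' method.
#'
#' @param volume a `[y, x, z]` array (non-constant).
#' @param sigma blur SD in voxels (scalar, or per-axis `(y, x, z)`).
#' @param n_bins number of histogram bins.
#' @return A logical mask array with attribute `threshold`.
#' @export
segment_channel <- function(volume, sigma = 0.5, n_bins = 256) {
  if (diff(range(volume)) == 0)
    stop("degenerate histogram: constant volume", call. = FALSE)
  blurred <- gaussian_blur_3d(volume, sigma)
  rng <- range(blurred)
  # for count-valued data narrower than n_bins, use unit-width integer bins
  # (the 8-bit histogram convention); fractional-width bins would leave
  # empty bins between integer values and break the triangle geometry
  breaks <- if (diff(rng) <= n_bins)
    seq(floor(rng[1]) - 0.5, ceiling(rng[2]) + 0.5, by = 1)
  else seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(as.vector(blurred), breaks = breaks, plot = FALSE)
  thr <- triangle_threshold_hist(h$counts, h$mids)
  structure(blurred > thr, threshold = thr)
}

#' Remove small connected components from a binary mask
#'
#' Thresholded Poisson noise leaves isolated speckle voxels in the masks;
#' components below `min_voxels` (6-connectivity) are discarded so that
#' the remaining components are genuine nuclei or cell volumes.
#'
#' @param mask logical `[y, x, z]` array.
#' @param min_voxels minimum component size kept.
#' @return The cleaned logical mask.
#' @export
clean_mask <- function(mask, min_voxels = 200) {
  lab <- label_components_3d(mask)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

# in-plane (3 x 3 x 1) maximum filter
max_filter_331 <- function(a) {
  out <- a
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, shift_arr(a, dy, dx, 0L))
  }
  out
}

#' Detect PLA puncta
#'
#' Candidate maxima are voxels equal to the 3 x 3 x 1 (in-plane) maximum
#' filter of the volume, i.e. voxels from which the difference
#' original-minus-max-filter is zero.  A candidate is retained when its
#' prominence over the local surround (value minus the median of a
#' 9 x 9 x 3 neighborhood excluding the 3 x 3 x 1 core) reaches
#' `noise_tolerance`; intensities are on the 8-bit-like scale of the
#' stack.  Plateaus within one in-plane voxel are collapsed to a single
#' detection.
#'
#' @param volume PLA channel `[y, x, z]` array.
#' @param noise_tolerance minimum prominence (default 15).
#' @return Data frame with columns `z`, `y`, `x`, `intensity` (may be
#'   empty).
#' @export
detect_pla_dots <- function(volume, noise_tolerance = 15) {
  d <- dim(volume)
  cand <- which(volume >= max_filter_331(volume))
  if (length(cand) == 0)
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      intensity = numeric(0)))
  pos <- arrayInd(cand, d)  # (y, x, z)
  # prominence over the local surround
  ry <- 4L; rx <- 4L; rz <- 1L
  keep <- logical(length(cand))
  prom <- numeric(length(cand))
  for (i in seq_along(cand)) {
    y <- pos[i, 1]; x <- pos[i, 2]; z <- pos[i, 3]
    yi <- max(1, y - ry):min(d[1], y + ry)
    xi <- max(1, x - rx):min(d[2], x + rx)
    zi <- max(1, z - rz):min(d[3], z + rz)
    box <- volume[yi, xi, zi]
    core <- abs(rep(yi, times = length(xi) * length(zi)) - y) <= 1 &
      abs(rep(rep(xi, each = length(yi)), times = length(zi)) - x) <= 1
    surround <- box[!core]
    prom[i] <- volume[y, x, z] - median(surround)
    keep[i] <- prom[i] >= noise_tolerance
  }
  pos <- pos[keep, , drop = FALSE]
  vals <- volume[cand[keep]]
  if (nrow(pos) == 0)
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      intensity = numeric(0)))
  # collapse plateau/adjacent detections (within 1 voxel in-plane, same
  # or adjacent slice), keeping the brightest
  ord <- order(-vals)
  taken <- rep(FALSE, nrow(pos))
  sel <- integer(0)
  for (i in ord) {
    if (taken[i]) next
    sel <- c(sel, i)
    close_by <- abs(pos[, 1] - pos[i, 1]) <= 1 &
      abs(pos[, 2] - pos[i, 2]) <= 1 & abs(pos[, 3] - pos[i, 3]) <= 1
    taken[close_by] <- TRUE
  }
  data.frame(z = pos[sel, 3], y = pos[sel, 1], x = pos[sel, 2],
             intensity = vals[sel])
}

# boundary voxel coordinates (y, x, z) of a mask: voxels of `which_side`
# having a 6-neighbor on the other side
boundary_voxels <- function(mask, which_side = c("inside", "outside")) {
  which_side <- match.arg(which_side)
  d <- dim(mask)
  other <- if (which_side == "inside") !mask else mask
  sel <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    sh <- c(0L, 0L, 0L)
    sh[ax] <- s
    sel <- sel | shift_arr(other, sh[1], sh[2], sh[3])
  }
  base <- if (which_side == "inside") mask else !mask
  arrayInd(which(base & sel), d)
}

#' Signed Euclidean distance from dots to the nuclear mask
#'
#' For each dot, the exact Euclidean distance (in micrometers, voxel
#' anisotropy respected) to the nearest voxel on the other side of the
#' mask: positive outside the mask (distance to the nearest mask voxel),
#' negative inside (distance to the nearest background voxel).  Dots are
#' taken at voxel centers.
#'
#' @param dots data frame with voxel columns `z`, `y`, `x`.
#' @param mask logical `[y, x, z]` array (e.g. the DAPI mask).
#' @param voxel_size micrometers per voxel `(z, y, x)`.
#' @return Numeric vector of signed distances (um); `+Inf` with a warning
#'   when the mask is empty.
#' @export
nuclear_distance <- function(dots, mask, voxel_size = c(1, 0.25, 0.25)) {
  if (nrow(dots) == 0) return(numeric(0))
  if (!any(mask)) {
    warning("empty mask: all distances are +Inf")
    return(rep(Inf, nrow(dots)))
  }
  vz <- voxel_size[1]; vy <- voxel_size[2]; vx <- voxel_size[3]
  # candidate nearest voxels always lie on the mask boundary
  b_in <- boundary_voxels(mask, "inside")    # mask voxels facing outside
  b_out <- boundary_voxels(mask, "outside")  # background voxels facing mask
  min_dist_to <- function(y, x, z, set) {
    if (nrow(set) == 0) return(Inf)
    sqrt(((set[, 1] - y) * vy)^2 + ((set[, 2] - x) * vx)^2 +
           ((set[, 3] - z) * vz)^2)
  }
  vapply(seq_len(nrow(dots)), function(i) {
    y <- dots$y[i]; x <- dots$x[i]; z <- dots$z[i]
    inside <- mask[y, x, z]
    if (inside) -min(min_dist_to(y, x, z, b_out))
    else min(min_dist_to(y, x, z, b_in))
  }, numeric(1))
}

# 3D connected components (6-connectivity) of a logical mask via igraph
label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0) return(lab)
  vox_id <- array(0L, d)
  vox_id[idx] <- seq_along(idx)
  edges <- list()
  for (ax in 1:3) {
    sh <- c(0L, 0L, 0L)
    sh[ax] <- 1L
    nb <- shift_arr(vox_id, sh[1], sh[2], sh[3])
    # shift with edge replication duplicates the border plane; mask it out
    valid <- array(TRUE, d)
    if (ax == 1) valid[1, , ] <- FALSE
    if (ax == 2) valid[, 1, ] <- FALSE
    if (ax == 3) valid[, , 1] <- FALSE
    both <- mask & valid & nb > 0L & vox_id > 0L & nb != vox_id
    if (any(both))
      edges[[length(edges) + 1]] <- cbind(vox_id[both], nb[both])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(t(e)))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Per-cell PLA metrics
#'
#' Labels connected components of the GFP mask as cells, assigns each dot
#' to its containing cell, integrates dot intensities
#' (background-subtracted sum over a 3-voxel-radius in-plane sphere) and
#' summarizes counts per GFP-positive cell as mean and SEM.  Dots outside
#' every cell are excluded from per-cell counts but retained in the dot
#' table (`cell_id = NA`).
#'
#' @param dots data frame from [detect_pla_dots()].
#' @param gfp_mask logical GFP mask `[y, x, z]`.
#' @param dapi_mask optional logical nuclear mask for signed distances.
#' @param voxel_size micrometers per voxel `(z, y, x)`.
#' @param intensity_volume volume used for intensity integration (normally
#'   the raw PLA channel); `NULL` skips integration.
#' @return A `pla_result`: list with `dots` (per-dot table: coordinates,
#'   intensity, integrated intensity, signed nuclear distance, cell id,
#'   inside-GFP flag), `per_cell` (cell id, dot count), and `summary`
#'   (mean and SEM of counts and intensities, number of cells).
#' @export
per_cell_metrics <- function(dots, gfp_mask, dapi_mask = NULL,
                             voxel_size = c(1, 0.25, 0.25),
                             intensity_volume = NULL) {
  labels <- label_components_3d(gfp_mask)
  n_cells <- max(labels)
  if (n_cells == 0)
    warning("no GFP-positive cell found")
  d <- dim(gfp_mask)
  cell_id <- rep(NA_integer_, nrow(dots))
  if (nrow(dots) > 0) {
    li <- labels[cbind(dots$y, dots$x, dots$z)]
    cell_id[li > 0] <- li[li > 0]
  }
  integrated <- rep(NA_real_, nrow(dots))
  if (!is.null(intensity_volume) && nrow(dots) > 0) {
    for (i in seq_len(nrow(dots))) {
      yi <- max(1, dots$y[i] - 3):min(d[1], dots$y[i] + 3)
      xi <- max(1, dots$x[i] - 3):min(d[2], dots$x[i] + 3)
      zi <- max(1, dots$z[i] - 1):min(d[3], dots$z[i] + 1)
      box <- intensity_volume[yi, xi, zi]
      in_sphere <- outer(outer((yi - dots$y[i])^2, (xi - dots$x[i])^2, "+"),
                         rep(0, length(zi)), "+") <= 9
      bg <- median(box[!in_sphere])
      if (!is.finite(bg)) bg <- median(intensity_volume)
      integrated[i] <- sum(box[in_sphere] - bg)
    }
  }
  nuc_dist <- if (!is.null(dapi_mask) && nrow(dots) > 0)
    nuclear_distance(dots, dapi_mask, voxel_size)
  else rep(NA_real_, nrow(dots))
  dot_tab <- cbind(dots,
                   data.frame(integrated_intensity = integrated,
                              nuclear_dist_um = nuc_dist,
                              cell_id = cell_id,
                              in_gfp = !is.na(cell_id)))
  counts <- if (n_cells > 0)
    vapply(seq_len(n_cells), function(ci) sum(!is.na(cell_id) &
                                                cell_id == ci), 0L)
  else integer(0)
  per_cell <- data.frame(cell_id = seq_len(n_cells), n_dots = counts)
  structure(list(
    dots = dot_tab, per_cell = per_cell, labels = labels,
    summary = list(n_cells = n_cells,
                   mean_dots_per_cell = if (n_cells) mean(counts) else NA_real_,
                   sem_dots_per_cell = if (n_cells) sem(counts) else NA_real_,
                   mean_intensity = mean(integrated, na.rm = TRUE),
                   sem_intensity = sem(integrated))),
    class = "pla_result")
}

#' @export
print.pla_result <- function(x, ...) {
  cat(sprintf("pla_result: %d dots in %d cells (%.2f +/- %.2f dots/cell)\n",
              nrow(x$dots), x$summary$n_cells, x$summary$mean_dots_per_cell,
              x$summary$sem_dots_per_cell))
  invisible(x)
}

#' Quantify a three-channel PLA stack
#'
#' Full chain: DAPI and GFP segmentation (Gaussian blur sigmas 0.5 and
#' 0.25 voxels), punctum detection at the given noise tolerance, signed
#' nuclear distances and per-cell metrics.
#'
#' @param stack a `pla_stack` (or any list with `dapi`, `gfp`, `pla`
#'   arrays and `voxel_size`).
#' @param dapi_sigma,gfp_sigma blur SDs (voxels).
#' @param noise_tolerance punctum prominence threshold.
#' @param min_component_voxels small-component cutoff applied to both
#'   masks (see [clean_mask()]).
#' @return A `pla_result` (see [per_cell_metrics()]) with the masks
#'   attached as `dapi_mask` / `gfp_mask`.
#' @export
quantify_pla_stack <- function(stack, dapi_sigma = 0.5, gfp_sigma = 0.25,
                               noise_tolerance = 15,
                               min_component_voxels = 200) {
  dapi_mask <- clean_mask(segment_channel(stack$dapi, dapi_sigma),
                          min_component_voxels)
  gfp_mask <- clean_mask(segment_channel(stack$gfp, gfp_sigma),
                         min_component_voxels)
  dots <- detect_pla_dots(stack$pla, noise_tolerance)
  res <- per_cell_metrics(dots, gfp_mask, dapi_mask,
                          voxel_size = stack$voxel_size,
                          intensity_volume = stack$pla)
  res$dapi_mask <- dapi_mask
  res$gfp_mask <- gfp_mask
  res
}
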