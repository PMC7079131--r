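# Synthetic single-molecule localization data: clustered 2D point patterns
# with known ground truth, and raw blinking movies for the frame-by-frame
# localizer.

#' Configuration for synthetic localization patterns and movies
#'
#' Molecules are placed either inside clusters (Gaussian scatter or fixed
#' geometric spacing around uniformly placed cluster centers) or as uniform
#' background monomers.  Each molecule then emits one or more blinks, each
#' displaced by the localization error.  Defaults emulate the plasma
#' membrane organization under study: a 5 x 5 um field in which 40% of
#' molecules sit in nanoscale clusters of ~8 nm radius.
#'
#' @param field_size region extent in nm, length-2 `(x, y)`.
#' @param n_clusters number of clusters.
#' @param molecules_per_cluster list `(mean, dispersion)`; dispersion is the
#'   variance-to-mean ratio (0 deterministic, 1 Poisson, >1 negative
#'   binomial).  At least one molecule per cluster.
#' @param cluster_radius list `(mean, sd)` in nm.  For `"gaussian"`
#'   geometry this is the isotropic scatter SD; for `"spaced"` geometry it
#'   is the exact nearest-neighbor spacing between molecules in the
#'   cluster.
#' @param clustered_fraction fraction of molecules belonging to clusters in
#'   `[0, 1]`; the number of background monomers is derived from it.  With
#'   `clustered_fraction = 0` no clusters are generated and the background
#'   is drawn from `background_density`.
#' @param background_density background monomers per um^2 (used when
#'   `clustered_fraction` is 0).
#' @param loc_error_sd per-axis localization error SD (nm).
#' @param blinks_per_molecule list `(mean)`; blinks are `1 + geometric`
#'   with the given mean (single-fluorophore overcounting).
#' @param cluster_geometry `"gaussian"` scatter or `"spaced"` regular
#'   polygon (dimers, tetramers, ... with exact spacing).
#' @param n_frames number of acquisition frames blinks are spread over.
#' @param seed integer seed or `NULL`.
#' @return An object of class `loc_sim_config`.
#' @export
loc_sim_config <- function(field_size = c(5000, 5000), n_clusters = 60,
                           molecules_per_cluster = list(mean = 8, dispersion = 1),
                           cluster_radius = list(mean = 8, sd = 2),
                           clustered_fraction = 0.4,
                           background_density = 30,
                           loc_error_sd = 10,
                           blinks_per_molecule = list(mean = 3),
                           cluster_geometry = c("gaussian", "spaced"),
                           n_frames = 10000, seed = NULL) {
  cluster_geometry <- match.arg(cluster_geometry)
  check_that(is.numeric(field_size) && length(field_size) == 2 &&
               all(field_size > 0), "field_size",
             "must be two positive extents (nm)")
  check_scalar(n_clusters, "n_clusters", lower = 0)
  check_scalar(clustered_fraction, "clustered_fraction", lower = 0, upper = 1)
  check_scalar(background_density, "background_density", lower = 0)
  check_scalar(loc_error_sd, "loc_error_sd", lower = 0)
  check_scalar(n_frames, "n_frames", lower = 1)
  check_that(is.list(molecules_per_cluster) &&
               is.numeric(molecules_per_cluster$mean) &&
               molecules_per_cluster$mean >= 1,
             "molecules_per_cluster", "must be a list with mean >= 1")
  check_that(is.list(cluster_radius) && is.numeric(cluster_radius$mean) &&
               cluster_radius$mean >= 0,
             "cluster_radius", "must be a list with mean >= 0")
  check_that(is.list(blinks_per_molecule) &&
               is.numeric(blinks_per_molecule$mean) &&
               blinks_per_molecule$mean >= 1,
             "blinks_per_molecule", "must be a list with mean >= 1")
  structure(list(field_size = field_size, n_clusters = n_clusters,
                 molecules_per_cluster = molecules_per_cluster,
                 cluster_radius = cluster_radius,
                 clustered_fraction = clustered_fraction,
                 background_density = background_density,
                 loc_error_sd = loc_error_sd,
                 blinks_per_molecule = blinks_per_molecule,
                 cluster_geometry = cluster_geometry,
                 n_frames = n_frames, seed = seed),
            class = "loc_sim_config")
}

# molecule positions for one cluster
cluster_molecules <- function(n, cx, cy, radius, geometry) {
  if (n == 1 || radius == 0)
    return(cbind(x = rep(cx, n), y = rep(cy, n)))
  if (geometry == "gaussian") {
    cbind(x = cx + rnorm(n, sd = radius), y = cy + rnorm(n, sd = radius))
  } else {
    # regular n-gon with nearest-neighbor (edge) spacing = radius
    r_circ <- radius / (2 * sin(pi / n))
    th <- 2 * pi * seq_len(n) / n + runif(1, 0, 2 * pi)
    cbind(x = cx + r_circ * cos(th), y = cy + r_circ * sin(th))
  }
}

#' Simulate a clustered localization pattern
#'
#' Places cluster centers uniformly in the field, scatters member
#' molecules around them, adds uniform background monomers so that the
#' requested clustered fraction holds in expectation, then emits blinks
#' (each displaced by the localization error).  Ground truth records the
#' molecule and cluster assignment of every blink.
#'
#' @param cfg a [loc_sim_config()].
#' @return A `localization_table`: data frame with columns `frame`, `x_nm`,
#'   `y_nm`, `intensity`, `precision_nm`, plus attributes `truth` (lists
#'   `molecules` and the per-blink `blinks` table with `molecule` and
#'   `cluster` ids, 0 = background) and `field_size`.
#' @export
simulate_localization_pattern <- function(cfg) {
  stopifnot(inherits(cfg, "loc_sim_config"))
  with_seed(cfg$seed, {
    fx <- cfg$field_size[1]; fy <- cfg$field_size[2]
    mols <- NULL
    if (cfg$clustered_fraction > 0 && cfg$n_clusters > 0) {
      counts <- draw_counts(cfg$n_clusters, cfg$molecules_per_cluster,
                            at_least = 1L)
      radii <- draw_positive(cfg$n_clusters, cfg$cluster_radius)
      cx <- runif(cfg$n_clusters, 0, fx)
      cy <- runif(cfg$n_clusters, 0, fy)
      mols <- do.call(rbind, lapply(seq_len(cfg$n_clusters), function(i) {
        xy <- cluster_molecules(counts[i], cx[i], cy[i], radii[i],
                                cfg$cluster_geometry)
        data.frame(x = xy[, "x"], y = xy[, "y"], cluster = i)
      }))
      n_cl <- nrow(mols)
      n_bg <- if (cfg$clustered_fraction < 1)
        round(n_cl * (1 - cfg$clustered_fraction) / cfg$clustered_fraction)
      else 0L
      truth_clusters <- data.frame(cluster = seq_len(cfg$n_clusters),
                                   x_nm = cx, y_nm = cy,
                                   n_molecules = counts, radius_nm = radii)
    } else {
      area_um2 <- fx * fy / 1e6
      n_bg <- rpois(1, cfg$background_density * area_um2)
      truth_clusters <- data.frame(cluster = integer(0), x_nm = numeric(0),
                                   y_nm = numeric(0),
                                   n_molecules = integer(0),
                                   radius_nm = numeric(0))
    }
    if (n_bg > 0) {
      bg <- data.frame(x = runif(n_bg, 0, fx), y = runif(n_bg, 0, fy),
                       cluster = 0L)
      mols <- rbind(mols, bg)
    }
    if (is.null(mols) || nrow(mols) == 0)
      mols <- data.frame(x = numeric(0), y = numeric(0), cluster = integer(0))
    mols$molecule <- seq_len(nrow(mols))

    # blinks: 1 + geometric with the requested mean
    mean_blinks <- cfg$blinks_per_molecule$mean
    k <- if (mean_blinks <= 1) rep(1L, nrow(mols))
    else 1L + rgeom(nrow(mols), prob = 1 / mean_blinks)
    idx <- rep(seq_len(nrow(mols)), k)
    n_blink <- length(idx)
    x <- mols$x[idx] + rnorm(n_blink, sd = cfg$loc_error_sd)
    y <- mols$y[idx] + rnorm(n_blink, sd = cfg$loc_error_sd)
    tab <- data.frame(frame = sample.int(cfg$n_frames, n_blink,
                                         replace = TRUE),
                      x_nm = x, y_nm = y,
                      intensity = rlnorm(n_blink, log(1000), 0.3),
                      precision_nm = rep(cfg$loc_error_sd, n_blink))
    truth <- list(molecules = mols, clusters = truth_clusters,
                  blinks = data.frame(molecule = mols$molecule[idx],
                                      cluster = mols$cluster[idx]))
    structure(tab, truth = truth, field_size = cfg$field_size,
              class = c("localization_table", "data.frame"))
  })
}

#' Simulate a raw blinking movie
#'
#' Renders a molecule set as stochastically blinking 2D Gaussian emitters
#' over a Poisson background, with optional cumulative linear stage drift.
#' Pixel `(row, col)` covers the half-open square
#' `[(col-1), col) x [(row-1), row)` in pixel units (origin top-left, y
#' down); a molecule at `x_nm` falls at column `x_nm / pixel_size + 0.5`
#' pixel-center coordinates.
#'
#' @param cfg a [loc_sim_config()]; the molecule pattern is drawn from it.
#' @param frames number of frames (>= 1).
#' @param psf_sigma point-spread-function SD in pixels (> 0).
#' @param drift linear drift in nm per frame, length-2 `(dx, dy)`, applied
#'   cumulatively.
#' @param snr emitter peak amplitude expressed in units of the background
#'   shot-noise SD (`sqrt(background)`).
#' @param p_on per-frame probability that a molecule emits.
#' @param pixel_size_nm camera pixel pitch (nm); default 100.
#' @param background mean background level (counts).
#' @return A `blink_movie`: 3D array `[row, col, frame]` with attributes
#'   `pixel_size_nm` and `truth` (per-frame true emitter positions in nm,
#'   drift included).
#' @export
simulate_blinking_movie <- function(cfg, frames = 100, psf_sigma = 1.3,
                                    drift = c(0, 0), snr = 10, p_on = 0.02,
                                    pixel_size_nm = 100, background = 100) {
  stopifnot(inherits(cfg, "loc_sim_config"))
  check_scalar(frames, "frames", lower = 1)
  check_scalar(psf_sigma, "psf_sigma", lower = 0, strict_lower = TRUE)
  check_scalar(p_on, "p_on", lower = 0, upper = 1)
  check_scalar(background, "background", lower = 1)
  pattern <- simulate_localization_pattern(cfg)
  mols <- attr(pattern, "truth")$molecules
  nx <- ceiling(cfg$field_size[1] / pixel_size_nm)
  ny <- ceiling(cfg$field_size[2] / pixel_size_nm)
  amp <- snr * sqrt(background)
  half <- ceiling(4 * psf_sigma)

  with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    movie <- array(0, dim = c(ny, nx, frames))
    truth <- vector("list", frames)
    for (f in seq_len(frames)) {
      img <- matrix(0, ny, nx)
      on <- if (nrow(mols) > 0) which(runif(nrow(mols)) < p_on) else integer(0)
      xs <- mols$x[on] + drift[1] * (f - 1)
      ys <- mols$y[on] + drift[2] * (f - 1)
      keep <- xs >= 0 & xs < cfg$field_size[1] &
        ys >= 0 & ys < cfg$field_size[2]
      xs <- xs[keep]; ys <- ys[keep]
      for (e in seq_along(xs)) {
        # pixel-center coordinates
        cxp <- xs[e] / pixel_size_nm + 0.5
        cyp <- ys[e] / pixel_size_nm + 0.5
        c0 <- max(1L, floor(cxp) - half); c1 <- min(nx, floor(cxp) + half)
        r0 <- max(1L, floor(cyp) - half); r1 <- min(ny, floor(cyp) + half)
        if (c0 > c1 || r0 > r1) next
        cols <- c0:c1; rows <- r0:r1
        gx <- exp(-((cols - cxp)^2) / (2 * psf_sigma^2))
        gy <- exp(-((rows - cyp)^2) / (2 * psf_sigma^2))
        img[rows, cols] <- img[rows, cols] + amp * outer(gy, gx)
      }
      movie[, , f] <- matrix(rpois(ny * nx, lambda = background + img),
                             ny, nx)
      truth[[f]] <- data.frame(frame = rep(f, length(xs)), x_nm = xs,
                               y_nm = ys)
    }
    structure(movie, pixel_size_nm = pixel_size_nm,
              field_size = cfg$field_size,
              truth = do.call(rbind, truth), class = "blink_movie")
  })
}
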