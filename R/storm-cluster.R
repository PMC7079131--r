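# Cluster detection, nearest-neighbor statistics and the two-sample
# Kolmogorov-Smirnov comparison for localization tables.

#' Detect clusters by density reachability
#'
#' DBSCAN-style clustering: points with at least `min_pts` neighbors
#' within `eps` seed clusters that grow by density reachability; remaining
#' points are background.  Per cluster the centroid, the RMS
#' member-to-centroid distance (the cluster radius) and the member count
#' are reported, together with the percentage of localizations assigned to
#' clusters and the cluster density per square micron.
#'
#' @param table a `localization_table` (columns `x_nm`, `y_nm`).
#' @param eps neighborhood radius (nm), > 0.
#' @param min_pts minimum neighborhood size for a core point, >= 2.
#' @param area_um2 analysis area for the density; defaults to the
#'   generator's field size when present, otherwise the bounding-box area.
#' @return An object of class `cluster_set`: list with `assignments`
#'   (per-localization cluster id, 0 = background), `clusters` (data frame
#'   `cluster`, `x_nm`, `y_nm`, `radius_nm`, `n_members`), and `summary`
#'   (`percent_clustered`, `cluster_density_um2`, `n_localizations`).
#' @export
detect_clusters <- function(table, eps = 20, min_pts = 3, area_um2 = NULL) {
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (min_pts < 2) stop("min_pts must be >= 2", call. = FALSE)
  n <- nrow(table)
  if (is.null(area_um2)) {
    fs <- attr(table, "field_size")
    area_um2 <- if (!is.null(fs)) prod(fs) / 1e6
    else if (n > 1) diff(range(table$x_nm)) * diff(range(table$y_nm)) / 1e6
    else NA_real_
  }
  if (n == 0) {
    return(structure(list(
      assignments = integer(0),
      clusters = data.frame(cluster = integer(0), x_nm = numeric(0),
                            y_nm = numeric(0), radius_nm = numeric(0),
                            n_members = integer(0)),
      summary = list(percent_clustered = NA_real_,
                     cluster_density_um2 = 0, n_localizations = 0L,
                     area_um2 = area_um2)), class = "cluster_set"))
  }
  ids <- .dbscan_grid(as.numeric(table$x_nm), as.numeric(table$y_nm),
                      eps, as.integer(min_pts))
  k <- max(ids)
  clusters <- if (k > 0) {
    do.call(rbind, lapply(seq_len(k), function(ci) {
      m <- ids == ci
      cx <- mean(table$x_nm[m]); cy <- mean(table$y_nm[m])
      data.frame(cluster = ci, x_nm = cx, y_nm = cy,
                 radius_nm = sqrt(mean((table$x_nm[m] - cx)^2 +
                                         (table$y_nm[m] - cy)^2)),
                 n_members = sum(m))
    }))
  } else {
    data.frame(cluster = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               radius_nm = numeric(0), n_members = integer(0))
  }
  structure(list(
    assignments = ids,
    clusters = clusters,
    summary = list(percent_clustered = 100 * mean(ids > 0),
                   cluster_density_um2 = k / area_um2,
                   n_localizations = n, area_um2 = area_um2)),
    class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters from %d localizations (%.1f%% clustered)\n",
              nrow(x$clusters), x$summary$n_localizations,
              x$summary$percent_clustered))
  invisible(x)
}

#' First-nearest-neighbor distances
#'
#' Computes each localization's Euclidean distance to its nearest other
#' localization via a spatial grid index, and a unit-area normalized
#' histogram of the distances.  When an ROI is supplied, neighbors are
#' searched over the full field but only points inside the ROI are
#' reported (edge-correct in the sense that a point's neighbor may lie
#' outside the ROI).
#'
#' @param table a `localization_table` with at least 2 points.
#' @param bin_width histogram bin width (nm), default 2.
#' @param roi optional list `(xmin, xmax, ymin, ymax)` (nm, half-open
#'   intervals).
#' @return An `nn_result`: list with `distances_nm`, `histogram` (data
#'   frame `mid_nm`, `density`), `bin_width` and `mode_nm` (modal distance,
#'   refined within the peak bin by parabolic interpolation of the
#'   neighboring densities).
#' @export
nearest_neighbor_distances <- function(table, bin_width = 2, roi = NULL) {
  if (nrow(table) < 2) stop("need at least 2 points", call. = FALSE)
  d <- .nn_dist_grid(as.numeric(table$x_nm), as.numeric(table$y_nm))
  if (!is.null(roi)) {
    keep <- table$x_nm >= roi$xmin & table$x_nm < roi$xmax &
      table$y_nm >= roi$ymin & table$y_nm < roi$ymax
    d <- d[keep]
    if (length(d) == 0) stop("no points inside the ROI", call. = FALSE)
  }
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(distances_nm = d,
                 histogram = data.frame(mid_nm = h$mids,
                                        density = h$density),
                 bin_width = bin_width,
                 mode_nm = refine_mode(h$mids, h$density,
                                       which.max(h$counts), bin_width)),
            class = "nn_result")
}

# sub-bin mode estimate: parabola through the peak bin and its neighbors
refine_mode <- function(mids, dens, i, bin_width) {
  if (i <= 1 || i >= length(dens)) return(mids[i])
  den <- dens[i - 1] - 2 * dens[i] + dens[i + 1]
  if (den >= 0) return(mids[i])
  mids[i] + 0.5 * bin_width * (dens[i - 1] - dens[i + 1]) / den
}

# asymptotic Kolmogorov distribution tail: P(sqrt(n) D > lambda)
kolmogorov_tail <- function(lambda) {
  if (lambda < 1e-8) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup |ECDF_a - ECDF_b|` exactly and the asymptotic
#' p-value from the Kolmogorov distribution with effective sample size
#' `n_a n_b / (n_a + n_b)`; optionally a permutation p-value.
#'
#' @param a,b numeric samples, non-empty.
#' @param permutations number of label permutations for an optional
#'   permutation p-value (0 = asymptotic only).
#' @return List with `statistic` (D), `p_value`, `n_eff`, and
#'   `p_permutation` when requested.
#' @export
ks_two_sample <- function(a, b, permutations = 0) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    stop("samples must be non-empty", call. = FALSE)
  ks_d <- function(a, b) {
    pts <- sort(c(a, b))
    max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
  }
  d <- ks_d(a, b)
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  p <- kolmogorov_tail(sqrt(n_eff) * d)
  out <- list(statistic = d, p_value = p, n_eff = n_eff)
  if (permutations > 0) {
    pool <- c(a, b)
    na <- length(a)
    exceed <- vapply(seq_len(permutations), function(i) {
      idx <- sample.int(length(pool), na)
      ks_d(pool[idx], pool[-idx]) >= d
    }, logical(1))
    out$p_permutation <- (sum(exceed) + 1) / (permutations + 1)
  }
  out
}

#' Pool cluster and nearest-neighbor results across ROIs
#'
#' Pools the per-cluster radii, occupancies and nearest-neighbor distances
#' of all ROIs of a condition; when a second condition is supplied the
#' pooled radius and nearest-neighbor distributions are compared with the
#' two-sample Kolmogorov-Smirnov test.
#'
#' @param cluster_sets list of [detect_clusters()] results (one per ROI).
#' @param nn_results optional list of [nearest_neighbor_distances()]
#'   results.
#' @param cluster_sets_b,nn_results_b optional second condition.
#' @return A list with pooled vectors and summary statistics per condition
#'   and, when two conditions are given, `ks_radii` / `ks_nn`.
#' @export
summarize_rois <- function(cluster_sets, nn_results = NULL,
                           cluster_sets_b = NULL, nn_results_b = NULL) {
  if (length(cluster_sets) < 1) stop("need at least one ROI", call. = FALSE)
  pool <- function(cs, nn) {
    radii <- unlist(lapply(cs, function(x) x$clusters$radius_nm))
    occ <- unlist(lapply(cs, function(x) x$clusters$n_members))
    n_loc <- sum(vapply(cs, function(x) x$summary$n_localizations, 0))
    n_clust <- sum(vapply(cs, function(x) nrow(x$clusters), 0))
    n_in <- sum(vapply(cs, function(x)
      sum(x$assignments > 0), 0))
    area <- sum(vapply(cs, function(x) x$summary$area_um2, 0))
    list(radii_nm = radii, occupancy = occ,
         n_localizations = n_loc, n_clusters = n_clust,
         percent_clustered = 100 * n_in / n_loc,
         cluster_density_um2 = n_clust / area,
         blink_density_um2 = n_loc / area,
         nn_nm = if (is.null(nn)) NULL
         else unlist(lapply(nn, function(x) x$distances_nm)))
  }
  out <- list(condition_a = pool(cluster_sets, nn_results))
  if (!is.null(cluster_sets_b)) {
    out$condition_b <- pool(cluster_sets_b, nn_results_b)
    out$ks_radii <- ks_two_sample(out$condition_a$radii_nm,
                                  out$condition_b$radii_nm)
    if (!is.null(out$condition_a$nn_nm) && !is.null(out$condition_b$nn_nm))
      out$ks_nn <- ks_two_sample(out$condition_a$nn_nm,
                                 out$condition_b$nn_nm)
  }
  out
}
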