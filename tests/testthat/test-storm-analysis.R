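# Localization, drift correction, clustering, nearest-neighbor and KS
# analyses.

make_frame <- function(spots, nr = 64, nc = 64, bg = 50, amp = 300,
                       sig = 1.2, seed = 1) {
  set.seed(seed)
  img <- matrix(rpois(nr * nc, bg), nr, nc)
  for (s in spots) {
    for (dr in -5:5) for (dc in -5:5) {
      r <- s[1] + dr; c <- s[2] + dc
      if (r >= 1 && r <= nr && c >= 1 && c <= nc)
        img[r, c] <- img[r, c] + amp * exp(-(dr^2 + dc^2) / (2 * sig^2))
    }
  }
  img
}

test_that("frame localization finds isolated emitters and rejects pairs", {
  blank <- localize_frames(list(make_frame(list())), pixel_size_nm = 100)
  expect_equal(nrow(blank), 0)

  one <- localize_frames(list(make_frame(list(c(30, 40)))),
                         pixel_size_nm = 100)
  expect_equal(nrow(one), 1)
  # sub-pixel accuracy: emitter at pixel center (row 30, col 40)
  expect_lt(abs(one$x_nm - (40 - 0.5) * 100), 10)  # 0.1 px
  expect_lt(abs(one$y_nm - (30 - 0.5) * 100), 10)

  # two emitters 3 px apart share a 9-px window: both discarded
  pair <- localize_frames(list(make_frame(list(c(30, 30), c(30, 33)))),
                          pixel_size_nm = 100)
  expect_equal(nrow(pair), 0)

  expect_error(localize_frames(list(make_frame(list())), peak_mask = 8,
                               pixel_size_nm = 100), "odd")
})

test_that("movie pipeline recovers most isolated emitters accurately", {
  cfg <- loc_sim_config(field_size = c(6400, 6400), n_clusters = 0,
                        clustered_fraction = 0, background_density = 0.5,
                        loc_error_sd = 0,
                        blinks_per_molecule = list(mean = 1), seed = 31)
  mov <- simulate_blinking_movie(cfg, frames = 120, psf_sigma = 1.3,
                                 snr = 15, p_on = 0.15)
  tru <- attr(mov, "truth")
  loc <- localize_frames(mov)
  found <- 0; total <- 0; errs <- c()
  for (f in unique(tru$frame)) {
    tt <- tru[tru$frame == f, ]
    iso <- rep(TRUE, nrow(tt))
    if (nrow(tt) > 1) for (i in seq_len(nrow(tt))) {
      d <- sqrt((tt$x_nm - tt$x_nm[i])^2 + (tt$y_nm - tt$y_nm[i])^2)
      d[i] <- Inf
      if (min(d) < 1000) iso[i] <- FALSE
    }
    iso <- iso & tt$x_nm > 500 & tt$x_nm < 5900 &
      tt$y_nm > 500 & tt$y_nm < 5900
    lt <- loc[loc$frame == f, ]
    for (i in which(iso)) {
      total <- total + 1
      if (nrow(lt)) {
        d <- sqrt((lt$x_nm - tt$x_nm[i])^2 + (lt$y_nm - tt$y_nm[i])^2)
        if (min(d) < 150) { found <- found + 1; errs <- c(errs, min(d)) }
      }
    }
  }
  expect_gte(found / total, 0.9)
  expect_lt(mean(errs), 10)  # a tenth of a pixel
})

test_that("drift correction recovers linear drift and flags thin bins", {
  cfg <- loc_sim_config(field_size = c(3000, 3000), n_clusters = 200,
                        molecules_per_cluster = list(mean = 10, dispersion = 0),
                        cluster_radius = list(mean = 10, sd = 0),
                        clustered_fraction = 1, loc_error_sd = 10,
                        blinks_per_molecule = list(mean = 5),
                        n_frames = 1000, seed = 6)
  tab <- simulate_localization_pattern(cfg)

  # zero drift: estimated shifts within half a histogram pixel
  dc0 <- drift_correct(tab, n_bins = 4, bin_nm = 20)
  expect_true(all(abs(dc0$bin_shifts$dx_nm) <= 10))
  expect_true(all(abs(dc0$bin_shifts$dy_nm) <= 10))

  # 1 nm/frame in x: slope recovered within 10%
  drifted <- tab
  drifted$x_nm <- drifted$x_nm + 1 * drifted$frame
  dc <- drift_correct(drifted, n_bins = 5, bin_nm = 20)
  slope <- coef(lm(dx_nm ~ frame, data = dc$bin_shifts))[2]
  expect_lt(abs(slope - 1), 0.1)
  expect_true(all(abs(dc$bin_shifts$dy_nm) <= 10))

  expect_error(drift_correct(tab, n_bins = 1), "n_bins")
  expect_error(drift_correct(tab[1:30, ], n_bins = 5), "fewer bins")
})

test_that("density clustering recovers planted clusters and their labels", {
  # all points identical: one cluster of radius zero
  same <- data.frame(x_nm = rep(100, 50), y_nm = rep(200, 50))
  cs_same <- detect_clusters(same, eps = 20, min_pts = 3, area_um2 = 1)
  expect_equal(nrow(cs_same$clusters), 1)
  expect_equal(cs_same$clusters$radius_nm, 0)
  expect_equal(cs_same$summary$percent_clustered, 100)

  # two planted Gaussian clusters over sparse background
  set.seed(21)
  pts <- rbind(
    data.frame(x_nm = rnorm(50, 1000, 8), y_nm = rnorm(50, 1000, 8), lab = 1),
    data.frame(x_nm = rnorm(50, 1500, 8), y_nm = rnorm(50, 1000, 8), lab = 2),
    data.frame(x_nm = runif(20, 0, 3000), y_nm = runif(20, 0, 3000), lab = 0))
  cs <- detect_clusters(pts, eps = 20, min_pts = 3, area_um2 = 9)
  expect_equal(nrow(cs$clusters), 2)
  planted <- pts$lab > 0
  recall <- mean(cs$assignments[planted] > 0)
  expect_gte(recall, 0.95)

  # permutation invariance up to cluster-id relabelling
  perm <- sample(nrow(pts))
  cs_p <- detect_clusters(pts[perm, ], eps = 20, min_pts = 3, area_um2 = 9)
  a1 <- cs$assignments[perm]
  a2 <- cs_p$assignments
  expect_identical(a1 > 0, a2 > 0)
  for (id in unique(a1[a1 > 0]))
    expect_equal(length(unique(a2[a1 == id])), 1)

  empty <- detect_clusters(data.frame(x_nm = numeric(0), y_nm = numeric(0)),
                           area_um2 = 1)
  expect_equal(nrow(empty$clusters), 0)
})

test_that("nearest-neighbor distances match geometry and the brute force", {
  # square grid with spacing d: every distance equals d
  g <- expand.grid(x_nm = seq(0, 900, 100), y_nm = seq(0, 900, 100))
  nn_g <- nearest_neighbor_distances(g, bin_width = 2)
  expect_true(all(abs(nn_g$distances_nm - 100) < 1e-9))

  # exact agreement with the O(n^2) scan
  set.seed(22)
  u <- data.frame(x_nm = runif(200, 0, 2000), y_nm = runif(200, 0, 2000))
  nn_u <- nearest_neighbor_distances(u, bin_width = 2)
  expect_equal(nn_u$distances_nm, unname(brute_nn(u$x_nm, u$y_nm)),
               tolerance = 1e-12)
  # density integrates to one
  expect_equal(sum(nn_u$histogram$density) * nn_u$bin_width, 1,
               tolerance = 1e-9)

  expect_error(nearest_neighbor_distances(u[1, , drop = FALSE]), "2 points")

  # ROI restriction: neighbors may lie outside the ROI
  roi <- list(xmin = 500, xmax = 1500, ymin = 0, ymax = 2000)
  nn_roi <- nearest_neighbor_distances(u, bin_width = 2, roi = roi)
  inside <- u$x_nm >= 500 & u$x_nm < 1500
  expect_length(nn_roi$distances_nm, sum(inside))
  expect_equal(nn_roi$distances_nm, nn_u$distances_nm[inside])
})

test_that("KS statistic matches brute force and behaves under the null", {
  a <- c(1, 2, 3); b <- c(1.5, 2.5, 3.5)
  r <- ks_two_sample(a, b)
  expect_equal(r$statistic, 1 / 3)
  expect_equal(r$statistic, brute_ks_d(a, b))

  expect_equal(ks_two_sample(a, a)$statistic, 0)
  expect_equal(ks_two_sample(a, a)$p_value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)

  # agreement with the reference asymptotic test on random data
  set.seed(23)
  for (i in 1:5) {
    x <- rnorm(80 + i); y <- rnorm(100, 0.2)
    mine <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$statistic, brute_ks_d(x, y), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-3)
  }

  # p-values approximately uniform for equal-distribution samples
  set.seed(5)
  ps <- replicate(500, ks_two_sample(rnorm(800), rnorm(800))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)

  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")

  # permutation p agrees in order of magnitude with the asymptotic one
  set.seed(24)
  x <- rnorm(60); y <- rnorm(60, 0.8)
  r2 <- ks_two_sample(x, y, permutations = 200)
  expect_lt(r2$p_permutation, 0.05)
})

test_that("ROI summaries pool counts and compare conditions", {
  set.seed(25)
  mk_roi <- function(n) {
    tab <- data.frame(x_nm = c(rnorm(60, 500, 8), runif(n - 60, 0, 1000)),
                      y_nm = c(rnorm(60, 500, 8), runif(n - 60, 0, 1000)))
    list(cs = detect_clusters(tab, eps = 20, min_pts = 3, area_um2 = 1),
         nn = nearest_neighbor_distances(tab))
  }
  rois <- lapply(c(100, 120, 140), function(n) mk_roi(n))
  cs_list <- lapply(rois, `[[`, "cs")
  nn_list <- lapply(rois, `[[`, "nn")

  one <- summarize_rois(cs_list[1], nn_list[1])
  expect_equal(one$condition_a$n_localizations, 100)
  expect_equal(one$condition_a$radii_nm, cs_list[[1]]$clusters$radius_nm)

  pooled <- summarize_rois(cs_list, nn_list)
  expect_equal(pooled$condition_a$n_localizations, 100 + 120 + 140)
  expect_equal(pooled$condition_a$n_clusters,
               sum(vapply(cs_list, function(x) nrow(x$clusters), 0)))

  # a condition compared with itself: D = 0, p = 1
  self <- summarize_rois(cs_list, nn_list, cs_list, nn_list)
  expect_equal(self$ks_radii$statistic, 0)
  expect_equal(self$ks_radii$p_value, 1)
  expect_equal(self$ks_nn$statistic, 0)
})
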