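# PLA stack generator and quantification chain.

punctum_volume <- function(bg = 10, amp = 100, center = c(16, 16, 6),
                           dims = c(32, 32, 12), sigma = c(1.1, 1.1, 0.6)) {
  # dims/center given as (y, x, z)
  vol <- array(bg, dims)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[1]))
    for (x in seq_len(dims[2])) {
      vol[y, x, z] <- vol[y, x, z] + amp *
        exp(-((y - center[1])^2 / (2 * sigma[1]^2) +
                (x - center[2])^2 / (2 * sigma[2]^2) +
                (z - center[3])^2 / (2 * sigma[3]^2)))
    }
  vol
}

test_that("stack generator books every dot and respects its config", {
  cfg <- pla_sim_config(n_cells = 1, gfp_fraction = 1,
                        dots_per_cell = list(mean = 5, dispersion = 0),
                        seed = 41)
  st <- simulate_pla_stack(cfg)
  expect_equal(nrow(st$truth$dots), 5)
  expect_true(all(st$truth$dots$cell == 1))
  # all dots inside the stack volume
  d <- dim(st$pla)
  expect_true(all(st$truth$dots$y >= 1 & st$truth$dots$y <= d[1]))
  expect_true(all(st$truth$dots$x >= 1 & st$truth$dots$x <= d[2]))

  # no dots: PLA channel is pure Poisson background
  cfg0 <- pla_sim_config(dots_per_cell = list(mean = 0, dispersion = 0),
                         seed = 42)
  st0 <- simulate_pla_stack(cfg0)
  expect_equal(nrow(st0$truth$dots), 0)
  expect_lt(max(st0$pla), 20)  # Poisson(2) stays far below a punctum

  # mean rendered amplitude at punctum centers is the configured amplitude
  cfg2 <- pla_sim_config(n_cells = 4, dots_per_cell = list(mean = 15,
                                                           dispersion = 0),
                         dot_amplitude = 100, background_level = 10,
                         stack_shape = c(10, 160, 160), seed = 43)
  st2 <- simulate_pla_stack(cfg2)
  tru <- st2$truth$dots
  expect_gte(nrow(tru), 50)
  vals <- st2$pla[cbind(tru$y, tru$x, tru$z)]
  expect_lt(abs(mean(vals) - 110), 5)

  # overlapping-cell retry budget is a hard error
  expect_error(simulate_pla_stack(pla_sim_config(n_cells = 40, seed = 44)),
               "retry budget")
  # reproducibility
  expect_equal(simulate_pla_stack(cfg)$pla, st$pla)
})

test_that("triangle threshold separates a two-level volume exactly", {
  vol <- array(10, c(20, 20, 6))
  obj <- array(FALSE, dim(vol)); obj[8:12, 8:12, 3:4] <- TRUE
  vol[obj] <- 200
  mask <- segment_channel(vol, sigma = 0)  # no blur: clean levels
  expect_identical(as.vector(mask), as.vector(obj))

  expect_error(segment_channel(array(7, c(5, 5, 5))), "constant")
})

test_that("triangle threshold equals the exhaustive geometric scan", {
  counts <- c(0, 120, 400, 260, 130, 60, 30, 18, 10, 6, 4, 3, 2, 1, 1, 1)
  mids <- seq(0.5, 15.5, 1)
  expect_equal(triangle_threshold_hist(counts, mids),
               brute_triangle(counts, mids))
  # a second, skewed histogram
  counts2 <- c(5, 900, 500, 80, 40, 22, 14, 9, 6, 4, 3, 2, 2, 1, 1, 2)
  expect_equal(triangle_threshold_hist(counts2, mids),
               brute_triangle(counts2, mids))
  expect_error(triangle_threshold_hist(c(0, 10, 0), 1:3), "degenerate")
})

test_that("punctum detection keys on prominence over the local surround", {
  flat <- array(10, c(32, 32, 8))
  expect_equal(nrow(detect_pla_dots(flat, 15)), 0)

  one <- punctum_volume(bg = 10, amp = 100)
  dots <- detect_pla_dots(one, 15)
  expect_equal(nrow(dots), 1)
  expect_equal(unname(c(dots$y, dots$x, dots$z)), c(16, 16, 6))

  # amplitude below the noise tolerance is ignored
  dim12 <- punctum_volume(bg = 10, amp = 12)
  expect_equal(nrow(detect_pla_dots(dim12, 15)), 0)

  # counts invariant to a constant intensity offset
  expect_equal(nrow(detect_pla_dots(one + 7, 15)), 1)
})

test_that("signed nuclear distances agree exactly with the exhaustive scan", {
  # spherical nucleus, isotropic voxels
  mask <- array(FALSE, c(20, 20, 20))
  for (z in 1:20) for (y in 1:20) for (x in 1:20)
    mask[y, x, z] <- (y - 10)^2 + (x - 10)^2 + (z - 10)^2 <= 36
  vox <- c(1, 1, 1)

  center <- data.frame(z = 10, y = 10, x = 10)
  expect_equal(nuclear_distance(center, mask, vox), -6, tolerance = 1)

  set.seed(45)
  dots <- data.frame(z = sample(20, 25, TRUE), y = sample(20, 25, TRUE),
                     x = sample(20, 25, TRUE))
  expect_equal(nuclear_distance(dots, mask, vox),
               brute_signed_edt(dots, mask, vox), tolerance = 1e-12)

  # anisotropic voxels
  vox2 <- c(1, 0.25, 0.25)
  expect_equal(nuclear_distance(dots, mask, vox2),
               brute_signed_edt(dots, mask, vox2), tolerance = 1e-12)

  # boundary voxel sits within one voxel of zero
  bdry <- data.frame(z = 10, y = 10, x = 16)  # on the sphere surface
  expect_lt(abs(nuclear_distance(bdry, mask, vox)), 1.5)

  expect_warning(d_inf <- nuclear_distance(center, array(FALSE, c(5, 5, 5)),
                                           vox), "empty mask")
  expect_true(is.infinite(d_inf))
})

test_that("per-cell metrics assign dots to GFP components", {
  gfp <- array(FALSE, c(40, 40, 6))
  gfp[5:15, 5:15, 2:5] <- TRUE    # cell 1
  gfp[25:35, 25:35, 2:5] <- TRUE  # cell 2
  dots <- data.frame(z = c(3, 3, 4, 4, 3, 3, 2),
                     y = c(8, 10, 12, 9, 30, 28, 20),
                     x = c(8, 10, 12, 9, 30, 28, 20),
                     intensity = rep(100, 7))
  res <- per_cell_metrics(dots, gfp)
  expect_equal(res$summary$n_cells, 2)
  expect_equal(sort(res$per_cell$n_dots), c(2, 4))
  # the dot outside every component is retained but unassigned
  expect_equal(sum(is.na(res$dots$cell_id)), 1)
  expect_equal(nrow(res$dots), 7)

  expect_warning(per_cell_metrics(dots, array(FALSE, c(40, 40, 6))),
                 "no GFP-positive cell")
})

test_that("full pipeline detects planted puncta with high recall", {
  rec <- c(); fdr <- c(); cells <- c()
  for (s in 46:47) {
    st <- simulate_pla_stack(pla_sim_config(seed = s))
    res <- quantify_pla_stack(st)
    m <- match_dots(res$dots, st$truth$dots)
    rec <- c(rec, m$recall); fdr <- c(fdr, m$fdr)
    cells <- c(cells, res$summary$n_cells)
  }
  expect_gte(mean(rec), 0.95)
  expect_lte(mean(fdr), 0.05)
  expect_equal(cells, c(5, 5))
})

test_that("dot counts recover the planted per-cell rate", {
  # larger field with 20 cells, Poisson(8) dots per cell
  cfg <- pla_sim_config(stack_shape = c(10, 300, 300), n_cells = 20,
                        dots_per_cell = list(mean = 8, dispersion = 1),
                        seed = 48)
  st <- simulate_pla_stack(cfg)
  res <- quantify_pla_stack(st)
  expect_equal(res$summary$n_cells, 20)
  m <- res$summary$mean_dots_per_cell
  s <- res$summary$sem_dots_per_cell
  expect_lt(abs(m - 8), 2 * s + 0.5)
})

test_that("membrane-weighted placement shows up in the distance readout", {
  mb <- c(); mb_true <- c()
  for (s in 7:12) {
    st <- simulate_pla_stack(pla_sim_config(seed = s))
    res <- quantify_pla_stack(st)
    d_cell <- nuclear_distance(res$dots, res$gfp_mask, st$voxel_size)
    mb <- c(mb, abs(d_cell[res$dots$in_gfp]) <=
              2.5 * st$voxel_size[2])
    mb_true <- c(mb_true, st$truth$dots$membrane)
  }
  expect_lt(abs(mean(mb) - 0.7), 0.05)
  expect_lt(abs(mean(mb_true) - 0.7), 0.05)
})
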