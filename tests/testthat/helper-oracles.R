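# Independent brute-force oracles used to cross-check the implementation.

# first-nearest-neighbor distances by full pairwise scan
brute_nn <- function(x, y) {
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1, min)
}

# two-sample KS statistic by walking the merged order of both samples
brute_ks_d <- function(a, b) {
  vals <- sort(unique(c(a, b)))
  max(abs(vapply(vals, function(v) mean(a <= v) - mean(b <= v), 0)))
}

# triangle threshold by exhaustive point-to-line distance over all bins
brute_triangle <- function(counts, mids) {
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  end <- if ((hi - peak) >= (peak - lo)) hi else lo
  idx <- if (end > peak) peak:end else end:peak
  # normalized coordinates; line through (x1,y1)=(0,1) and (x2,y2)=(1,0)
  x <- (idx - peak) / (end - peak)
  y <- counts[idx] / counts[peak]
  x1 <- 0; y1 <- 1; x2 <- 1; y2 <- 0
  num <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1)
  den <- sqrt((y2 - y1)^2 + (x2 - x1)^2)
  mids[idx[which.max(num / den)]]
}

# signed EDT oracle scanning every voxel of the volume
brute_signed_edt <- function(dots, mask, voxel_size) {
  d <- dim(mask)
  all_idx <- arrayInd(seq_len(prod(d)), d)
  inside_set <- all_idx[as.vector(mask), , drop = FALSE]
  outside_set <- all_idx[!as.vector(mask), , drop = FALSE]
  vz <- voxel_size[1]; vy <- voxel_size[2]; vx <- voxel_size[3]
  dist_to <- function(y, x, z, set)
    min(sqrt(((set[, 1] - y) * vy)^2 + ((set[, 2] - x) * vx)^2 +
               ((set[, 3] - z) * vz)^2))
  vapply(seq_len(nrow(dots)), function(i) {
    if (mask[dots$y[i], dots$x[i], dots$z[i]])
      -dist_to(dots$y[i], dots$x[i], dots$z[i], outside_set)
    else
      dist_to(dots$y[i], dots$x[i], dots$z[i], inside_set)
  }, numeric(1))
}

# greedy matching of detected dots to ground-truth dots (2 voxels
# in-plane, 1 slice axially); returns recall and false-discovery rate
match_dots <- function(detected, truth) {
  matched <- rep(FALSE, nrow(truth))
  used <- rep(FALSE, nrow(detected))
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$y - truth$y[i])^2 + (detected$x - truth$x[i])^2
    ok <- which(!used & d2 <= 4 & abs(detected$z - truth$z[i]) <= 1)
    if (length(ok)) {
      matched[i] <- TRUE
      used[ok[1]] <- TRUE
    }
  }
  list(recall = mean(matched), fdr = mean(!used))
}

# midpoints of the top-n local maxima of an nn_result histogram
hist_modes <- function(nn, n = 2) {
  h <- nn$histogram
  dens <- h$density
  is_peak <- vapply(seq_along(dens), function(i) {
    left <- if (i > 1) dens[i - 1] else -Inf
    right <- if (i < length(dens)) dens[i + 1] else -Inf
    dens[i] > 0 & dens[i] >= left & dens[i] >= right
  }, logical(1))
  peaks <- h$mid_nm[is_peak][order(-dens[is_peak])]
  sort(head(peaks, n))
}

# minimal trace_set for unit tests
make_trace_set <- function(v, t, i, c_m = 10, kind = "activation") {
  sweeps <- do.call(rbind, lapply(seq_along(v), function(k)
    data.frame(sweep = k, v_mV = v[k], time_ms = t, i_pA = i[[k]])))
  structure(list(sweeps = sweeps, c_m = c_m,
                 protocol = list(kind = kind, v_hold = -120,
                                 dt_ms = if (length(t) > 1) t[2] - t[1] else 1)),
            class = "trace_set")
}
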