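# Synthetic three-channel 3D stacks for the proximity-ligation-assay
# quantification: ellipsoidal nuclei (DAPI), cytoplasmic volumes (GFP) and
# Gaussian puncta (PLA) over Poisson noise.
#
# Volumes are arrays indexed [y, x, z] (z-slices as pages); voxel sizes
# are given per axis in micrometers.

#' Configuration for synthetic PLA stacks
#'
#' @param stack_shape voxel grid as `(z, y, x)`.
#' @param voxel_size micrometers per voxel as `(z, y, x)`; confocal-like
#'   anisotropy by default (1 um z step, 0.25 um lateral).
#' @param n_cells number of cells.
#' @param nucleus_spec list `(mean, sd)` of nuclear ellipsoid lateral
#'   semi-axis in voxels; the axial semi-axis is scaled by the voxel
#'   anisotropy so nuclei are roundish in physical units.
#' @param cyto_extra cytoplasm extends this many lateral voxels beyond the
#'   nucleus.
#' @param gfp_fraction fraction of cells that are GFP positive in `[0, 1]`.
#' @param dots_per_cell list `(mean, dispersion)` of PLA puncta per
#'   GFP-positive cell.
#' @param dot_amplitude punctum peak intensity above background (> 0);
#'   intensities are on an 8-bit-like scale.
#' @param dot_sigma punctum Gaussian SD in voxels as `(z, y, x)`.
#' @param membrane_weight probability that a punctum is placed within
#'   `membrane_margin` voxels of the cell boundary rather than uniformly in
#'   the cytoplasm (plasma-membrane predominance of the signal).
#' @param membrane_margin boundary shell thickness (lateral voxels).
#' @param background_level mean background counts.
#' @param seed integer seed or `NULL`.
#' @return An object of class `pla_sim_config`.
#' @export
pla_sim_config <- function(stack_shape = c(10, 128, 128),
                           voxel_size = c(1, 0.25, 0.25),
                           n_cells = 5,
                           nucleus_spec = list(mean = 8, sd = 1),
                           cyto_extra = 6,
                           gfp_fraction = 1,
                           dots_per_cell = list(mean = 8, dispersion = 1),
                           dot_amplitude = 100,
                           dot_sigma = c(0.6, 1.1, 1.1),
                           membrane_weight = 0.7,
                           membrane_margin = 2,
                           background_level = 2,
                           seed = NULL) {
  check_that(length(stack_shape) == 3 && all(stack_shape >= 4),
             "stack_shape", "must be three positive voxel counts (z,y,x)")
  check_that(length(voxel_size) == 3 && all(voxel_size > 0),
             "voxel_size", "must be three positive sizes (z,y,x)")
  check_scalar(n_cells, "n_cells", lower = 1)
  check_scalar(gfp_fraction, "gfp_fraction", lower = 0, upper = 1)
  check_scalar(dot_amplitude, "dot_amplitude", lower = 0, strict_lower = TRUE)
  check_scalar(membrane_weight, "membrane_weight", lower = 0, upper = 1)
  check_scalar(background_level, "background_level", lower = 0)
  check_that(length(dot_sigma) == 3 && all(dot_sigma > 0), "dot_sigma",
             "must be three positive SDs (z,y,x)")
  structure(list(stack_shape = stack_shape, voxel_size = voxel_size,
                 n_cells = n_cells, nucleus_spec = nucleus_spec,
                 cyto_extra = cyto_extra, gfp_fraction = gfp_fraction,
                 dots_per_cell = dots_per_cell,
                 dot_amplitude = dot_amplitude, dot_sigma = dot_sigma,
                 membrane_weight = membrane_weight,
                 membrane_margin = membrane_margin,
                 background_level = background_level, seed = seed),
            class = "pla_sim_config")
}

# ellipsoid mask on the [y, x, z] grid centered at (cy, cx, cz) with
# semi-axes (ry, rx, rz) in voxels
ellipsoid_mask <- function(dims_yxz, cy, cx, cz, ry, rx, rz) {
  yy <- (seq_len(dims_yxz[1]) - cy) / ry
  xx <- (seq_len(dims_yxz[2]) - cx) / rx
  zz <- (seq_len(dims_yxz[3]) - cz) / rz
  o <- outer(outer(yy^2, xx^2, "+"), zz^2, "+")
  o <= 1
}

#' Simulate a three-channel PLA stack
#'
#' Places non-overlapping cells, each an ellipsoidal nucleus (DAPI
#' channel) surrounded by a cytoplasmic volume (GFP channel for
#' GFP-positive cells), then renders PLA puncta as 3D Gaussian spots at
#' recorded coordinates, preferentially near the cell boundary, over
#' Poisson background in all channels.
#'
#' @param cfg a [pla_sim_config()].
#' @param max_tries placement retries before giving up on non-overlapping
#'   cells.
#' @return A `pla_stack`: list with channel arrays `dapi`, `gfp`, `pla`
#'   (`[y, x, z]`), `voxel_size` and `truth` (per-cell table and per-dot
#'   table with voxel coordinates, cell id and membrane flag).
#' @export
simulate_pla_stack <- function(cfg, max_tries = 200) {
  stopifnot(inherits(cfg, "pla_sim_config"))
  nz <- cfg$stack_shape[1]; ny <- cfg$stack_shape[2]; nx <- cfg$stack_shape[3]
  dims <- c(ny, nx, nz)
  aniso <- cfg$voxel_size[2] / cfg$voxel_size[1]  # lateral/axial voxel ratio

  with_seed(cfg$seed, {
    cells <- list()
    tries <- 0
    while (length(cells) < cfg$n_cells) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place non-overlapping cells within the retry budget",
             call. = FALSE)
      r_nuc <- max(2, draw_positive(1, cfg$nucleus_spec))
      r_cell <- r_nuc + cfg$cyto_extra
      cx <- runif(1, r_cell + 1, nx - r_cell)
      cy <- runif(1, r_cell + 1, ny - r_cell)
      cz <- runif(1, 0.45 * nz, 0.55 * nz)
      ok <- all(vapply(cells, function(cl) {
        # 4-voxel margin keeps thresholded masks from bridging cells
        sqrt((cl$cx - cx)^2 + (cl$cy - cy)^2) > (cl$r_cell + r_cell + 4)
      }, logical(1)))
      if (!ok) next
      cells[[length(cells) + 1]] <- list(
        id = length(cells) + 1L, cx = cx, cy = cy, cz = cz,
        r_nuc = r_nuc, r_cell = r_cell,
        rz_nuc = max(1.2, r_nuc * aniso), rz_cell = max(2, r_cell * aniso))
    }
    gfp_pos <- runif(cfg$n_cells) < cfg$gfp_fraction

    dapi <- array(0, dims)
    gfp <- array(0, dims)
    pla <- array(0, dims)
    nuc_mask_all <- array(FALSE, dims)
    dot_rows <- list()

    for (i in seq_along(cells)) {
      cl <- cells[[i]]
      nuc <- ellipsoid_mask(dims, cl$cy, cl$cx, cl$cz, cl$r_nuc, cl$r_nuc,
                            cl$rz_nuc)
      cell <- ellipsoid_mask(dims, cl$cy, cl$cx, cl$cz, cl$r_cell, cl$r_cell,
                             cl$rz_cell)
      cyto <- cell & !nuc
      dapi[nuc] <- dapi[nuc] + 150
      nuc_mask_all <- nuc_mask_all | nuc
      if (!gfp_pos[i]) next
      gfp[cyto] <- gfp[cyto] + 120

      # PLA puncta inside the cytoplasm, preferentially near the boundary
      n_dots <- draw_counts(1, cfg$dots_per_cell)
      if (n_dots == 0) next
      inner <- ellipsoid_mask(dims, cl$cy, cl$cx, cl$cz,
                              cl$r_cell - cfg$membrane_margin,
                              cl$r_cell - cfg$membrane_margin,
                              max(1, cl$rz_cell - cfg$membrane_margin * aniso))
      shell_idx <- which(cyto & !inner)
      core_idx <- which(cyto & inner)
      if (length(shell_idx) == 0) shell_idx <- which(cyto)
      if (length(core_idx) == 0) core_idx <- which(cyto)
      for (d in seq_len(n_dots)) {
        at_membrane <- runif(1) < cfg$membrane_weight
        vox <- if (at_membrane) sample(shell_idx, 1) else sample(core_idx, 1)
        pos <- arrayInd(vox, dims)  # (y, x, z)
        dot_rows[[length(dot_rows) + 1]] <- data.frame(
          cell = cl$id, z = pos[3], y = pos[1], x = pos[2],
          membrane = at_membrane)
      }
    }

    # render puncta
    if (length(dot_rows)) {
      dots <- do.call(rbind, dot_rows)
      sz <- cfg$dot_sigma[1]; sy <- cfg$dot_sigma[2]; sx <- cfg$dot_sigma[3]
      rz <- ceiling(3 * sz); ry <- ceiling(3 * sy); rx <- ceiling(3 * sx)
      for (d in seq_len(nrow(dots))) {
        zi <- max(1, dots$z[d] - rz):min(nz, dots$z[d] + rz)
        yi <- max(1, dots$y[d] - ry):min(ny, dots$y[d] + ry)
        xi <- max(1, dots$x[d] - rx):min(nx, dots$x[d] + rx)
        gy <- exp(-((yi - dots$y[d])^2) / (2 * sy^2))
        gx <- exp(-((xi - dots$x[d])^2) / (2 * sx^2))
        gz <- exp(-((zi - dots$z[d])^2) / (2 * sz^2))
        blob <- cfg$dot_amplitude * outer(outer(gy, gx), gz)
        pla[yi, xi, zi] <- pla[yi, xi, zi] + blob
      }
    } else {
      dots <- data.frame(cell = integer(0), z = integer(0), y = integer(0),
                         x = integer(0), membrane = logical(0))
    }

    noisify <- function(a)
      array(rpois(length(a), lambda = cfg$background_level + a), dim(a))
    structure(list(dapi = noisify(dapi), gfp = noisify(gfp),
                   pla = noisify(pla),
                   voxel_size = cfg$voxel_size,
                   truth = list(
                     cells = do.call(rbind, lapply(cells, function(cl)
                       data.frame(cell = cl$id, cx = cl$cx, cy = cl$cy,
                                  cz = cl$cz, r_nuc = cl$r_nuc,
                                  r_cell = cl$r_cell))),
                     gfp_positive = gfp_pos,
                     dots = dots,
                     nucleus_mask = nuc_mask_all)),
              class = "pla_stack")
  })
}

#' @export
print.pla_stack <- function(x, ...) {
  d <- dim(x$dapi)
  cat(sprintf("pla_stack: %d x %d x %d voxels (y,x,z), %d ground-truth dots\n",
              d[1], d[2], d[3], nrow(x$truth$dots)))
  invisible(x)
}
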