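# Readers and writers for the interchange formats: localization CSV,
# long-format trace CSV with JSON sidecar, and multi-page TIFF for movies
# and stacks.  All writers emit plain comma/tab-separated text with LF
# endings; readers accept LF and CRLF.

loc_required_cols <- c("frame", "x_nm", "y_nm", "intensity", "precision_nm")

#' Write a localization table to CSV
#'
#' @param table a `localization_table` (extra columns are preserved).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' Validates the required header (`frame,x_nm,y_nm,intensity,precision_nm`);
#' vendor-specific extra columns are passed through.  Rows with
#' non-numeric coordinates are reported with their line numbers.
#'
#' @param path CSV path.
#' @return A `localization_table`.
#' @export
read_localizations <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(loc_required_cols, names(df))
  if (length(missing))
    stop("localization CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$x_nm) | !is.finite(df$y_nm))
  if (length(bad))
    stop("malformed localization rows (file lines ",
         paste(bad + 1L, collapse = ", "), ")", call. = FALSE)
  structure(df, class = c("localization_table", "data.frame"))
}

#' Write a trace family to CSV plus JSON sidecar
#'
#' The long-format CSV holds `sweep,v_mV,time_ms,i_pA`; capacitance and
#' protocol metadata go to `<path>.json`.
#'
#' @param ts a `trace_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  write.csv(ts$sweeps, path, row.names = FALSE)
  meta <- list(c_m = ts$c_m,
               protocol = ts$protocol[setdiff(names(ts$protocol), "windows")])
  if (!is.null(ts$protocol$windows))
    meta$protocol$windows <- ts$protocol$windows
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace family from CSV plus JSON sidecar
#'
#' Sweeps are reconstructed grouped by sweep id independently of row
#' order; a uniform time base within each sweep is validated.
#'
#' @param path CSV path (sidecar at `<path>.json`).
#' @return A `trace_set`.
#' @export
read_traces <- function(path) {
  df <- read.csv(path)
  need <- c("sweep", "v_mV", "time_ms", "i_pA")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trace CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[order(df$sweep, df$time_ms), ]
  rownames(df) <- NULL
  for (sw in split(df$time_ms, df$sweep)) {
    if (length(sw) > 2) {
      steps <- diff(sw)
      if (diff(range(steps)) > 1e-6 * max(abs(steps)))
        stop("non-uniform sampling within a sweep", call. = FALSE)
    }
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  else list(c_m = NA_real_, protocol = list(kind = "unknown"))
  proto <- as.list(meta$protocol)
  if (!is.null(proto$windows) && is.data.frame(proto$windows))
    proto$windows <- lapply(seq_len(nrow(proto$windows)), function(i)
      list(interval = proto$windows$interval[i],
           p1 = unlist(proto$windows$p1[i]),
           p2 = unlist(proto$windows$p2[i])))
  trace_set(df, c_m = meta$c_m, protocol = proto)
}

#' Write an image volume or movie as multi-page TIFF
#'
#' Pages are z-slices (stacks) or frames (movies); intensities are scaled
#' into 16 bits with the scale factor recorded in a JSON sidecar so that
#' reading restores the original values up to quantization.
#'
#' @param a 3D array `[y, x, pages]`.
#' @param path output TIFF path.
#' @param meta extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_tiff_volume <- function(a, path, meta = list()) {
  scale <- max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta$scale <- scale
  meta$n_pages <- dim(a)[3]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF volume written by [write_tiff_volume()]
#'
#' @param path TIFF path.
#' @return List with the array `data` (`[y, x, pages]`) and `meta`.
#' @export
read_tiff_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  else list(scale = 1)
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- pages[[k]] * meta$scale
  list(data = a, meta = meta)
}

#' Write a three-channel PLA stack as multi-page TIFF
#'
#' Pages are ordered z within channel (DAPI, then GFP, then PLA); the JSON
#' sidecar records channel order, slice count and voxel size.
#'
#' @param stack a `pla_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_pla_stack <- function(stack, path) {
  nz <- dim(stack$dapi)[3]
  a <- array(0, c(dim(stack$dapi)[1:2], 3 * nz))
  a[, , seq_len(nz)] <- stack$dapi
  a[, , nz + seq_len(nz)] <- stack$gfp
  a[, , 2 * nz + seq_len(nz)] <- stack$pla
  write_tiff_volume(a, path, meta = list(
    channels = c("dapi", "gfp", "pla"), n_z = nz,
    voxel_size_um = stack$voxel_size))
  invisible(path)
}

#' Read a three-channel PLA stack written by [write_pla_stack()]
#'
#' @param path TIFF path.
#' @return A `pla_stack` (without ground truth).
#' @export
read_pla_stack <- function(path) {
  v <- read_tiff_volume(path)
  nz <- v$meta$n_z
  structure(list(dapi = v$data[, , seq_len(nz), drop = FALSE],
                 gfp = v$data[, , nz + seq_len(nz), drop = FALSE],
                 pla = v$data[, , 2 * nz + seq_len(nz), drop = FALSE],
                 voxel_size = unlist(v$meta$voxel_size_um),
                 truth = NULL),
            class = "pla_stack")
}
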