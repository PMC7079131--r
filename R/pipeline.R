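# Seeded end-to-end pipeline driver.  Each command runs one stage on files
# in an output directory and writes a manifest sufficient to reproduce the
# run bit-identically: command, parameters, seed (and the upstream stage's
# seed when chaining), package version.

stage_seed <- function(seed, stage) {
  # derive independent per-stage substreams from one global seed
  offsets <- c("simulate-ephys" = 1L, "fit-ephys" = 2L,
               "simulate-storm" = 3L, "analyze-storm" = 4L,
               "simulate-pla" = 5L, "quantify-pla" = 6L)
  (as.integer(seed) + 1000003L * offsets[[stage]]) %% 2147483647L
}

write_manifest <- function(out_dir, command, seed, params, inputs = list(),
                           outputs = character(0)) {
  manifest <- list(command = command, seed = seed,
                   package = "navclust",
                   version = as.character(utils::packageVersion("navclust")),
                   params = params, inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

#' Run one pipeline stage
#'
#' Commands: `simulate-ephys` (activation/inactivation/recovery families as
#' trace CSVs + ground-truth JSON), `fit-ephys` (gating fit JSON and a
#' per-cell gating table TSV), `simulate-storm` (localization CSV +
#' ground-truth JSON), `analyze-storm` (cluster TSV, nearest-neighbor TSV,
#' summary JSON), `simulate-pla` (three-channel TIFF + ground-truth JSON),
#' `quantify-pla` (dots TSV, per-cell TSV, summary JSON).  Every run
#' writes a `manifest.json` recording the command, parameters and seed;
#' stages that read a directory produced by an upstream stage chain the
#' upstream seed into their manifest.
#'
#' @param command stage name, see Details.
#' @param config named list of stage parameters (defaults used where
#'   omitted); for the analysis stages, `input` names the directory written
#'   by the upstream simulate stage.
#' @param seed integer global seed; expanded into per-stage substreams.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(command, config = list(), seed = 1,
                         out_dir = ".") {
  known <- c("simulate-ephys", "fit-ephys", "simulate-storm",
             "analyze-storm", "simulate-pla", "quantify-pla")
  if (!command %in% known)
    stop("unknown command '", command, "'; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sseed <- stage_seed(seed, command)
  inputs <- list()
  if (!is.null(config$input)) {
    up <- read_manifest(config$input)
    inputs <- list(dir = config$input,
                   upstream_seed = if (is.null(up)) NA else up$seed,
                   upstream_command = if (is.null(up)) NA else up$command)
  }

  outputs <- switch(command,
    "simulate-ephys" = {
      cfg_args <- config[intersect(names(config),
                                   names(formals(ephys_sim_config)))]
      cfg <- do.call(ephys_sim_config, c(cfg_args, list(seed = sseed)))
      act <- simulate_activation_family(cfg)
      inact <- simulate_inactivation_family(cfg)
      tau_rec <- if (is.null(config$tau_rec)) 7.64 else config$tau_rec
      rec <- simulate_recovery_family(cfg, tau_rec = tau_rec)
      write_traces(act, file.path(out_dir, "activation.csv"))
      write_traces(inact, file.path(out_dir, "inactivation.csv"))
      write_traces(rec, file.path(out_dir, "recovery.csv"))
      truth <- list(act_vhalf = cfg$act_vhalf, act_k = cfg$act_k,
                    inact_vhalf = cfg$inact_vhalf, inact_k = cfg$inact_k,
                    e_na = cfg$e_na, gmax = cfg$gmax, c_m = cfg$c_m,
                    tau_rec = tau_rec)
      jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      c("activation.csv", "inactivation.csv", "recovery.csv", "truth.json")
    },
    "fit-ephys" = {
      src <- if (is.null(config$input)) out_dir else config$input
      act <- read_traces(file.path(src, "activation.csv"))
      inact <- read_traces(file.path(src, "inactivation.csv"))
      rec_path <- file.path(src, "recovery.csv")
      rec <- if (file.exists(rec_path)) read_traces(rec_path) else NULL
      fit <- analyze_ephys_cell(act, inact, rec)
      res <- list(act_vhalf_mV = fit$act$vhalf, act_k_mV = fit$act$k,
                  inact_vhalf_mV = fit$inact$vhalf,
                  inact_k_mV = fit$inact$k,
                  e_na_mV = fit$e_na_mV, gmax_nS = fit$gmax_nS,
                  peak_density_pA_pF = fit$peak_density_pA_pF,
                  recovery_tau_ms = fit$recovery_tau_ms,
                  t_half_ms = fit$t_half_ms,
                  z_act = fit$z_act, z_inact = fit$z_inact)
      jsonlite::write_json(res, file.path(out_dir, "gating_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      tab <- data.frame(parameter = names(res),
                        value = unlist(res, use.names = FALSE))
      write.table(tab, file.path(out_dir, "gating_fit.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      c("gating_fit.json", "gating_fit.tsv")
    },
    "simulate-storm" = {
      cfg_args <- config[intersect(names(config),
                                   names(formals(loc_sim_config)))]
      cfg <- do.call(loc_sim_config, c(cfg_args, list(seed = sseed)))
      tab <- simulate_localization_pattern(cfg)
      write_localizations(tab, file.path(out_dir, "localizations.csv"))
      truth <- attr(tab, "truth")
      jsonlite::write_json(list(clustered_fraction = cfg$clustered_fraction,
                                n_clusters = cfg$n_clusters,
                                n_molecules = nrow(truth$molecules),
                                n_blinks = nrow(tab),
                                field_size_nm = cfg$field_size),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      c("localizations.csv", "truth.json")
    },
    "analyze-storm" = {
      src <- if (is.null(config$input)) out_dir else config$input
      tab <- read_localizations(file.path(src, "localizations.csv"))
      eps <- if (is.null(config$eps)) 20 else config$eps
      min_pts <- if (is.null(config$min_pts)) 3 else config$min_pts
      cs <- detect_clusters(tab, eps = eps, min_pts = min_pts,
                            area_um2 = config$area_um2)
      nn <- nearest_neighbor_distances(tab)
      write.table(cs$clusters, file.path(out_dir, "clusters.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(data.frame(nn_nm = nn$distances_nm),
                  file.path(out_dir, "nearest_neighbors.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(c(cs$summary, list(nn_mode_nm = nn$mode_nm)),
                           file.path(out_dir, "storm_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      c("clusters.tsv", "nearest_neighbors.tsv", "storm_summary.json")
    },
    "simulate-pla" = {
      cfg_args <- config[intersect(names(config),
                                   names(formals(pla_sim_config)))]
      cfg <- do.call(pla_sim_config, c(cfg_args, list(seed = sseed)))
      stack <- simulate_pla_stack(cfg)
      write_pla_stack(stack, file.path(out_dir, "stack.tif"))
      jsonlite::write_json(list(n_cells = cfg$n_cells,
                                dots = stack$truth$dots),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      c("stack.tif", "stack.tif.json", "truth.json")
    },
    "quantify-pla" = {
      src <- if (is.null(config$input)) out_dir else config$input
      stack <- read_pla_stack(file.path(src, "stack.tif"))
      tol <- if (is.null(config$noise_tolerance)) 15
      else config$noise_tolerance
      res <- quantify_pla_stack(stack, noise_tolerance = tol)
      write.table(res$dots, file.path(out_dir, "dots.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(res$per_cell, file.path(out_dir, "per_cell.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(res$summary,
                           file.path(out_dir, "pla_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      c("dots.tsv", "per_cell.tsv", "pla_summary.json")
    })

  invisible(write_manifest(out_dir, command, seed, config, inputs, outputs))
}
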