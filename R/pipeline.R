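# Configuration and end-to-end pipeline: preprocess -> ensemble -> inference
# (-> optional time-dependent reconstruction), with all tabular I/O as CSV and
# a run manifest recording seeds and counts.

#' Read a run configuration file
#'
#' YAML with sections \code{paths} (samples, carbonate, crustal_reference,
#' hypsometry — empty paths fall back to synthetic data / bundled tables),
#' \code{grid} (n, f_min, f_max), \code{runs_per_scenario}, \code{seed},
#' \code{filter} (mode, n_bins), \code{timeseries} (enabled, t_start, t_end,
#' dt, n_bins), \code{riverine_multiplier}, \code{ranges} (Table-style
#' min/max overrides) and \code{output_dir}. Missing fields take defaults.
#'
#' @param path YAML file path; \code{NULL} for all-defaults.
#' @return a \code{run_config} list.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    paths = list(samples = "", carbonate = "", crustal_reference = "",
                 hypsometry = ""),
    grid = list(n = 31, f_min = 0.001, f_max = 1.0),
    runs_per_scenario = 1000,
    seed = 1L,
    filter = list(mode = "range", n_bins = 10),
    timeseries = list(enabled = FALSE, t_start = 444.7, t_end = 440.8,
                      dt = 0.02, n_bins = 10),
    riverine_multiplier = 1,
    ranges = list(),
    output_dir = "paleoredox_run"
  )
  cfg <- modifyList(cfg, user)
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (nzchar(p) && !file.exists(p)) stop("configured file not found: ", p)
  }
  range_overrides <- lapply(cfg$ranges, function(r) c(r$min, r$max))
  cfg$param_ranges <- mb_param_ranges(cfg$riverine_multiplier, range_overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Read a carbonate d238U record table
#'
#' CSV with columns \code{age_ma}, \code{d238u} and optional \code{d238u_2se}.
#'
#' @param path CSV path.
#' @return a \code{\link{measured_record}} for proxy \code{d238u_carb}.
#' @export
read_carbonate_record <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!all(c("age_ma", "d238u") %in% names(df))) {
    stop("carbonate table needs columns age_ma and d238u")
  }
  measured_record("d238u_carb", df$d238u,
                  sigma2 = if ("d238u_2se" %in% names(df)) df$d238u_2se,
                  age_ma = df$age_ma, archive = path)
}

#' Run the full analysis pipeline
#'
#' Preprocesses the shale table (detrital corrections, screening), builds the
#' Monte Carlo ensemble over the scenario grid, filters it against the
#' authigenic shale records and the carbonate record (jointly and
#' carbonate-only), optionally reconstructs the time-dependent f_eux
#' envelope, and writes all outputs plus a manifest into
#' \code{config$output_dir}. Input files are never modified.
#'
#' @param config a \code{\link{read_run_config}} result.
#' @return invisibly, a list with the augmented samples, ensemble, the two
#'   filter results, the optional timeseries and the manifest.
#' @export
run_pipeline <- function(config = read_run_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- if (nzchar(config$paths$crustal_reference)) {
    crustal_reference(config$paths$crustal_reference)
  } else crustal_reference()

  # --- preprocess ---------------------------------------------------------
  samples <- if (nzchar(config$paths$samples)) {
    read_samples(config$paths$samples)
  } else synth_shale_record(synth_config(seed = config$seed), ref)
  aug <- augment_samples(samples, ref, seed = config$seed)
  write.csv(aug, file.path(config$output_dir, "samples_augmented.csv"),
            row.names = FALSE)

  shale_age <- age_model(data.frame(depth_m = range(samples$depth_m),
                                    age_ma = c(440.8, 443.8)))
  keep_eux <- aug$redox_valid & aug$water_column %in%
    c("euxinic", "possibly_euxinic")
  mo_ok <- keep_eux & aug$mo_auth_valid
  u_ok <- keep_eux & aug$u_auth_valid
  rec_mo <- measured_record("d98mo_eux", aug$d98mo_auth[mo_ok],
                            sigma2 = aug$d98mo_auth_2sd[mo_ok],
                            depth_m = aug$depth_m[mo_ok], archive = "shale")
  rec_u <- measured_record("d238u_eux", aug$d238u_auth[u_ok],
                           sigma2 = aug$d238u_auth_2sd[u_ok],
                           depth_m = aug$depth_m[u_ok], archive = "shale")
  rec_carb <- if (nzchar(config$paths$carbonate)) {
    read_carbonate_record(config$paths$carbonate)
  } else synth_carbonate_record(synth_config(seed = config$seed))

  # --- ensemble -----------------------------------------------------------
  hyps <- if (nzchar(config$paths$hypsometry)) {
    read.csv(config$paths$hypsometry, comment.char = "#")
  } else {
    read.csv(system.file("extdata", "global_hypsometry.csv",
                         package = "paleoredox"), comment.char = "#")
  }
  curve <- fit_depth_area(hyps)
  grid <- scenario_grid(config$grid$n, config$grid$f_min, config$grid$f_max)
  ens <- run_ensemble(curve, grid, config$runs_per_scenario,
                      config$param_ranges, mb_constants(),
                      master_seed = config$seed)
  write.csv(ens, file.path(config$output_dir, "ensemble.csv"),
            row.names = FALSE)

  # --- inference ----------------------------------------------------------
  combined <- range_filter(ens, list(rec_mo, rec_u, rec_carb),
                           mode = config$filter$mode,
                           n_bins = config$filter$n_bins)
  carb_only <- range_filter(ens, list(rec_carb), mode = config$filter$mode,
                            n_bins = config$filter$n_bins)
  summary_df <- do.call(rbind, lapply(
    list(combined = combined, carbonate_only = carb_only), function(fr) {
      if (fr$empty) {
        data.frame(mean = NA, median = NA, p5 = NA, p95 = NA, n_retained = 0)
      } else as.data.frame(fr$summary)
    }))
  summary_df <- cbind(filter = rownames(summary_df), summary_df)
  write.csv(summary_df, file.path(config$output_dir, "feux_summary.csv"),
            row.names = FALSE)

  # --- optional time-dependent reconstruction -----------------------------
  ts <- NULL
  if (isTRUE(config$timeseries$enabled)) {
    ts <- reconstruct_timeseries(
      ens, list(rec_mo, rec_u, rec_carb),
      models = list(d98mo_eux = shale_age, d238u_eux = shale_age),
      t_start = config$timeseries$t_start, t_end = config$timeseries$t_end,
      dt = config$timeseries$dt, n_bins = config$timeseries$n_bins)
    write.csv(ts$timesteps, file.path(config$output_dir, "feux_timesteps.csv"),
              row.names = FALSE)
    write.csv(ts$envelope, file.path(config$output_dir, "feux_envelope.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("paleoredox")),
    master_seed = config$seed,
    runs_per_scenario = config$runs_per_scenario,
    grid = config$grid,
    filter = config$filter,
    n_ensemble_rows = nrow(ens),
    n_convergence_failures = attr(ens, "n_failed"),
    n_oxic_clamped = sum(ens$oxic_clamped),
    n_samples = nrow(samples),
    n_euxinic_samples = sum(keep_eux),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(samples = aug, ensemble = ens, combined = combined,
                 carbonate_only = carb_only, timeseries = ts,
                 manifest = manifest))
}
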