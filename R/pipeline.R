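# End-to-end pipeline: validated config in, result files + manifest out.

#' Build and validate a pipeline run configuration
#'
#' Accepts a YAML file path or an equivalent nested list and validates it
#' fully before any stage runs (fail-fast: an invalid config produces no
#' outputs).  Two modes are supported:
#'
#' \describe{
#'   \item{`simulate_decay`}{generate a synthetic decay experiment
#'     ([generateDecaySeries()]), normalize, integrate AUCs, aggregate
#'     across experiments and fit the grand-mean decay.  Fields under
#'     `simulate` mirror [decaySeriesSpec()] arguments (snake_case).}
#'   \item{`stack`}{read a TIFF stack ([readStack()]), build per-frame
#'     organelle masks and measure the sensor enrichment time course.
#'     Fields: `input` (TIFF path), `marker_channel`, `sensor_channel`,
#'     `profile` (`"ER"`/`"mitochondria"`), and optional `airy`
#'     (`wavelength_nm`, `na`, `pixel_size_nm`).}
#' }
#'
#' Common fields: `mode`, `seed`, `output_dir`, optional `auc`
#' (`t_start`, `t_end`), optional `kinetics` (`fix_plateau`).
#'
#' @param config YAML path or list.
#' @return validated config list (class `"contactquantConfig"`).
#' @seealso [runPipeline()]
#' @export
runConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  problems <- character()
  if (is.null(config$mode) || !config$mode %in% c("simulate_decay", "stack"))
    problems <- c(problems, "mode must be 'simulate_decay' or 'stack'")
  if (is.null(config$output_dir))
    problems <- c(problems, "output_dir is required")
  if (is.null(config$seed)) config$seed <- 1L
  if (identical(config$mode, "simulate_decay")) {
    sim <- config$simulate
    spec <- tryCatch(do.call(decaySeriesSpec, c(
      snakeToSpecArgs(sim), list(seed = config$seed))),
      error = function(e) conditionMessage(e))
    if (is.character(spec)) problems <- c(problems, spec)
    else config$simulateSpec <- spec
  } else if (identical(config$mode, "stack")) {
    if (is.null(config$input) || !file.exists(config$input %||% ""))
      problems <- c(problems, "stack mode requires an existing `input` TIFF")
    if (is.null(config$marker_channel) || is.null(config$sensor_channel))
      problems <- c(problems, "stack mode requires marker_channel and sensor_channel")
  }
  if (length(problems))
    stop(paste(c("invalid configuration:", paste(" -", problems)),
               collapse = "\n"))
  class(config) <- c("contactquantConfig", class(config))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# map snake_case YAML keys onto decaySeriesSpec() arguments
snakeToSpecArgs <- function(sim) {
  if (is.null(sim)) return(list())
  map <- c(n_pre_frames = "nPreFrames", n_post_frames = "nPostFrames",
           frame_interval_s = "frameIntervalS",
           baseline_intensity = "baselineIntensity",
           rate_constant_per_s = "rateConstantPerS",
           plateau_fraction = "plateauFraction",
           noise_sd_fraction = "noiseSdFraction",
           background = "background", n_cells = "nCells",
           n_experiments = "nExperiments",
           baseline_jitter_sdlog = "baselineJitterSdlog")
  known <- intersect(names(sim), names(map))
  unknown <- setdiff(names(sim), c(names(map), "seed"))
  if (length(unknown))
    stop(sprintf("unknown simulate field(s): %s", paste(unknown, collapse = ", ")))
  stats::setNames(sim[known], map[known])
}

configHash <- function(config) {
  keep <- config[setdiff(names(config), c("simulateSpec", "output_dir"))]
  keep <- keep[order(names(keep))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

writeTidyCsv <- function(df, path, unitComment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", unitComment), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Validates the config ([runConfig()]), executes the configured stages,
#' writes all result files into `output_dir`, and returns the run manifest
#' (also written as `manifest.json`).  Given the same config and seed the
#' result files are byte-identical; only the manifest timestamp differs
#' between runs, and the manifest's `config_hash` is timestamp-free.
#'
#' In `simulate_decay` mode the outputs are `traces.csv` (tidy normalized
#' traces), `auc_per_cell.csv`, `aggregate.json` (superplot summary of the
#' AUCs), `grand_mean_trace.csv`, and `fit.json` (mono-exponential fit of
#' the post-treatment grand mean).  In `stack` mode the output is
#' `enrichment.csv` (per-frame enrichment measurements).
#'
#' @param config YAML path, list, or validated config from [runConfig()].
#' @return manifest list, invisibly.
#' @examples
#' cfg <- list(mode = "simulate_decay", seed = 2, output_dir = tempfile(),
#'             simulate = list(n_cells = 4, n_experiments = 2))
#' mf <- runPipeline(cfg)
#' mf$n_cells
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "contactquantConfig")) config <- runConfig(config)
  outDir <- config$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ContactQuant")),
    config_hash = configHash(config),
    mode = config$mode,
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (config$mode == "simulate_decay") {
    spec <- config$simulateSpec
    traces <- generateDecaySeries(spec)
    tab <- traceMatrix(traces)
    writeTidyCsv(tab, file.path(outDir, "traces.csv"),
                 "time_s in seconds; normalized is F/F_pre (dimensionless)")

    tEnd <- config$auc$t_end %||% max(traces[[1]]@timesS)
    tStart <- config$auc$t_start %||% 0
    aucs <- vapply(traces, function(tr)
      areaUnderCurve(tr@normalized, tr@timesS, tStart, tEnd), numeric(1))
    aucTab <- data.frame(
      cell = vapply(traces, function(tr) tr@cellId, ""),
      experiment = vapply(traces, function(tr) tr@experimentId, ""),
      auc_s = aucs)
    writeTidyCsv(aucTab, file.path(outDir, "auc_per_cell.csv"),
                 "auc_s: baseline-subtracted area under F/F_pre, in seconds")

    agg <- superplotAggregate(aucTab$auc_s, aucTab$experiment)
    jsonlite::write_json(agg, file.path(outDir, "aggregate.json"),
                         auto_unbox = TRUE, digits = NA)

    gm <- aggregateTraces(tab)
    writeTidyCsv(gm, file.path(outDir, "grand_mean_trace.csv"),
                 "grand_mean/sem: across-experiment mean of per-experiment means of F/F_pre")

    post <- gm$time_s >= 0
    fit <- fitMonoexponential(gm$time_s[post], gm$grand_mean[post],
                              fixPlateau = config$kinetics$fix_plateau)
    jsonlite::write_json(
      list(k_per_s = fit@kFit, f0 = fit@f0, plateau = fit@plateau,
           plateau_fixed = fit@plateauFixed,
           half_life_s = if (fit@kFit > 0) log(2) / fit@kFit else NA,
           residual_rms = fit@residualRms, n_points = fit@nPoints),
      file.path(outDir, "fit.json"), auto_unbox = TRUE, digits = NA)

    manifest$n_cells <- length(traces)
    manifest$n_experiments <- agg$nExperiments
    manifest$outputs <- c("traces.csv", "auc_per_cell.csv", "aggregate.json",
                          "grand_mean_trace.csv", "fit.json")
  } else {
    stk <- readStack(config$input)
    manifest$input_md5 <- unname(tools::md5sum(config$input))
    airy <- if (!is.null(config$airy))
      airyDisc(config$airy$wavelength_nm %||% 670,
               config$airy$na %||% 1.45,
               config$airy$pixel_size_nm %||% stk@pixelSizeNm)
    else airyDisc(pixelSizeNm = stk@pixelSizeNm)
    profile <- scaleProfile(config$profile %||% "mitochondria")
    tc <- enrichmentTimecourse(stk, config$marker_channel,
                               config$sensor_channel, profile, airy)
    writeTidyCsv(tc, file.path(outDir, "enrichment.csv"),
                 "time_s in seconds; enrichment = mean_inside/mean_outside (dimensionless)")
    manifest$n_frames <- nrow(tc)
    manifest$outputs <- "enrichment.csv"
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
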