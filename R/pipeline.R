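.STAGE_KEYS <- list(
  equilibrium = c("fkbp12_uM", "fkbp12_6_uM", "form"),
  dose_response = c("ligand", "grid_uM", "fixed_other_uM", "mode",
    "n_trials", "duration_s", "window_s", "fit_ec50", "form"),
  competition = c("fkbp12_uM", "grid_uM", "mode", "n_trials", "duration_s",
    "window_s", "form"),
  simulate = c("protocol_file", "duration_s", "n_trials", "window_s",
    "form"),
  synth_trace = c("duration_s", "sample_rate_hz", "filter_cutoff_hz",
    "open_current_pa", "closed_current_pa", "noise_sd_pa"),
  idealize = c("trace_file", "levels_pa", "window_s"),
  fit_dwells = c("events_file", "state", "max_components", "cutoff_ms",
    "min_duration_ms"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
      paste(bad, collapse = ", "))
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages against a parameter file and writes
#' versioned outputs plus a manifest to \code{output_dir}. The
#' configuration is a YAML or JSON file (or an equivalent R list) with
#' top-level keys \code{params_file} (optional; packaged defaults when
#' absent), \code{output_dir}, \code{seed} and \code{stages}. All physical
#' quantities carry unit suffixes in their keys (e.g. \code{grid_uM},
#' \code{duration_s}). Unknown keys anywhere are rejected, by name, before
#' any computation. Per-stage seeds are derived deterministically from the
#' master seed, so identical configurations produce byte-identical numeric
#' outputs.
#'
#' Available stages: \code{equilibrium} (closed-form occupancy/Po table),
#' \code{dose_response} (curve + optional Hill/EC50 fit),
#' \code{competition}, \code{simulate} (protocol simulation, windowed Po),
#' \code{synth_trace} (simulate + render a recording), \code{idealize}
#' (threshold idealization of a trace CSV) and \code{fit_dwells}
#' (component-count selection on an event CSV).
#'
#' @param config path to a YAML/JSON config file, or a named list.
#' @return (invisibly) the manifest, as a list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- .read_config(config)
  }
  .check_keys(config, c("params_file", "output_dir", "seed", "stages"),
    "top level")
  if (is.null(config$output_dir)) stop("config requires output_dir")
  if (is.null(config$seed)) stop("config requires an explicit seed")
  if (is.null(config$stages) || !length(config$stages))
    stop("config requires a non-empty stages block")
  .check_keys(config$stages, names(.STAGE_KEYS), "stages")

  params <- if (is.null(config$params_file)) defaultParameters()
    else readKineticParameters(config$params_file)
  for (st in names(config$stages))
    .check_keys(config$stages[[st]], .STAGE_KEYS[[st]],
      paste0("stages$", st))

  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seed <- as.integer(config$seed)
  set.seed(master_seed)
  stage_seed <- setNames(sample.int(2147483646L, length(.STAGE_KEYS)),
    names(.STAGE_KEYS))
  files <- character(0)
  put <- function(f) files[length(files) + 1L] <<- f

  sg <- config$stages
  if (!is.null(sg$equilibrium)) {
    s <- sg$equilibrium
    tab <- equilibriumTable(params, as.numeric(s$fkbp12_uM),
      as.numeric(s$fkbp12_6_uM %||% 0), form = s$form %||% "saturating")
    f <- file.path(out_dir, "equilibrium.csv")
    write.csv(tab, f, row.names = FALSE); put(f)
  }
  if (!is.null(sg$dose_response)) {
    s <- sg$dose_response
    cur <- doseResponseCurve(params, s$ligand %||% "fkbp12",
      as.numeric(s$grid_uM), fixedOther = s$fixed_other_uM %||% 0,
      mode = s$mode %||% "analytic", nTrials = s$n_trials %||% 100,
      duration = s$duration_s %||% 60, window = s$window_s %||% 10,
      seed = stage_seed[["dose_response"]],
      form = s$form %||% "saturating")
    f <- file.path(out_dir, "dose_response.csv")
    write.csv(curveAsDataFrame(cur), f, row.names = FALSE); put(f)
    if (isTRUE(s$fit_ec50 %||% TRUE)) {
      fe <- file.path(out_dir, "ec50.json")
      writeEc50Fit(estimateEc50(cur), fe); put(fe)
    }
  }
  if (!is.null(sg$competition)) {
    s <- sg$competition
    cur <- competitionCurve(params, s$fkbp12_uM %||% 3,
      as.numeric(s$grid_uM), mode = s$mode %||% "analytic",
      nTrials = s$n_trials %||% 100, duration = s$duration_s %||% 60,
      window = s$window_s %||% 10, seed = stage_seed[["competition"]],
      form = s$form %||% "saturating")
    f <- file.path(out_dir, "competition.csv")
    write.csv(curveAsDataFrame(cur), f, row.names = FALSE); put(f)
  }
  if (!is.null(sg$simulate)) {
    s <- sg$simulate
    if (is.null(s$protocol_file)) stop("simulate stage needs protocol_file")
    protocol <- readProtocol(s$protocol_file)
    pts <- trialAveragePo(params, protocol, s$duration_s %||% 600,
      nTrials = s$n_trials %||% 1, window = s$window_s %||% 10,
      seed = stage_seed[["simulate"]], form = s$form %||% "saturating")
    f <- file.path(out_dir, "simulate_po.csv")
    write.csv(asDataFrame(pts), f, row.names = FALSE); put(f)
  }
  if (!is.null(sg$synth_trace)) {
    s <- sg$synth_trace
    set.seed(stage_seed[["synth_trace"]])
    path <- simulatePath(params, constantProtocol(), s$duration_s %||% 10)
    spec <- AcquisitionSpec(
      sampleRate = s$sample_rate_hz %||% 20000,
      filterCutoff = s$filter_cutoff_hz %||% 800,
      openCurrent = s$open_current_pa %||% 30,
      closedCurrent = s$closed_current_pa %||% 0,
      noiseSd = s$noise_sd_pa %||% 3)
    tr <- synthesizeTrace(path, spec)
    f <- file.path(out_dir, "trace.csv")
    writeTrace(tr, f); put(f); put(paste0(f, ".json"))
  }
  if (!is.null(sg$idealize)) {
    s <- sg$idealize
    if (is.null(s$trace_file)) stop("idealize stage needs trace_file")
    tr <- readTrace(s$trace_file)
    rec <- idealizeThreshold50(tr,
      levels = if (is.null(s$levels_pa)) NULL else as.numeric(s$levels_pa))
    f <- file.path(out_dir, "events.csv")
    writeEvents(rec, f); put(f)
    po <- computePo(rec, warnShort = FALSE)
    fp <- file.path(out_dir, "po.json")
    jsonlite::write_json(list(po = po,
      total_duration_s = rec@totalDuration), fp, auto_unbox = TRUE,
      digits = NA)
    put(fp)
  }
  if (!is.null(sg$fit_dwells)) {
    s <- sg$fit_dwells
    if (is.null(s$events_file)) stop("fit_dwells stage needs events_file")
    rec <- readEvents(s$events_file)
    dwells <- extractDwells(rec, s$state %||% "O",
      minDuration = s$min_duration_ms %||% 1)
    fit <- selectNComponents(dwells,
      maxComponents = s$max_components %||% 4,
      cutoff = s$cutoff_ms %||% (s$min_duration_ms %||% 1))
    f <- file.path(out_dir, "dwell_fit.json")
    writeDwellFit(fit, f); put(f)
  }

  manifest <- list(package = "RyRgate",
    version = as.character(packageVersion("RyRgate")),
    seed = master_seed,
    stage_seeds = as.list(stage_seed[names(sg)]),
    params = as.list(parameterVector(params)),
    stages = sg, files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
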