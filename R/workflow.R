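# cli_app: one entry point chaining the modules into the study workflows
# (simulate, calibrate, preprocess, cop, metrics, validity, reliability,
# psd), with a reproducible run manifest next to every output set.
# Exit codes: 0 ok, 1 computational degeneracy, 2 usage/file error.

.usage_classes <- c("coptools_format_error", "coptools_config_error",
                    "coptools_parameter_error")

.require_args <- function(args, keys) {
  missing_keys <- setdiff(keys, names(args))
  if (length(missing_keys) > 0L) {
    stop_coptools(sprintf("missing argument(s): %s", paste(missing_keys, collapse = ", ")),
                  "config_error")
  }
}

.load_cfg <- function(args) {
  if (!is.null(args$config)) load_config(args$config) else run_config()
}

.digest_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.write_manifest <- function(dir, workflow, args, cfg, inputs, outputs, warnings,
                            seed = NULL) {
  manifest <- list(
    workflow = workflow,
    software = paste0("coptools ", as.character(utils::packageVersion("coptools"))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(cfg),
    arguments = args[vapply(args, function(a) is.atomic(a) && length(a) == 1, logical(1))],
    inputs = .digest_files(inputs),
    outputs = .digest_files(outputs),
    warnings = as.list(warnings)
  )
  path <- file.path(dir, paste0("manifest_", workflow, ".json"))
  write_report_json(manifest, path)
  path
}

.wf_simulate <- function(args) {
  .require_args(args, "out_dir")
  dir.create(args$out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sway_sim_config,
                  args[intersect(names(args), names(formals(sway_sim_config)))])
  trial <- simulate_trial(scfg, seed = args$seed)
  out <- c(index = file.path(args$out_dir, "index_board.csv"),
           reference = file.path(args$out_dir, "reference_plate.csv"),
           truth = file.path(args$out_dir, "truth_cop.csv"),
           ground_truth = file.path(args$out_dir, "ground_truth.json"))
  write_recording(out[["index"]], trial$index)
  write_recording(out[["reference"]], trial$reference)
  write_cop(out[["truth"]], trial$truth)
  write_report_json(list(sim_config = unclass(scfg), seed = args$seed,
                         master_rate_hz = trial$truth$rate), out[["ground_truth"]])
  out
}

.wf_calibrate <- function(args) {
  .require_args(args, c("zero", "load", "mass", "out"))
  zero <- read_recording(args$zero, "corner_board", args$rate %||% 5)
  load <- read_recording(args$load, "corner_board", args$rate %||% 5)
  cal <- fit_linear_calibration(zero, load, as.numeric(args$mass),
                                g = args$g %||% 9.81)
  write_calibration(cal, args$out)
  c(calibration = args$out)
}

.wf_preprocess <- function(args, cfg) {
  .require_args(args, c("index", "reference", "task", "out_dir"))
  dir.create(args$out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- read_recording(args$index, "corner_board", args$rate_index %||% 40)
  ref <- read_recording(args$reference, "wrench_plate", args$rate_reference %||% 100)
  if (!is.null(args$calibration)) {
    idx <- apply_calibration(idx, read_calibration(args$calibration))
  }
  pp <- preprocess_recordings(idx, ref, args$task, cfg)
  out <- c(index = file.path(args$out_dir, "index_segment.csv"),
           reference = file.path(args$out_dir, "reference_segment.csv"),
           report = file.path(args$out_dir, "preprocess_report.json"))
  write_recording(out[["index"]], pp$index)
  write_recording(out[["reference"]], pp$reference)
  write_report_json(list(
    task = args$task, lag_s = pp$lag_s,
    jitter = list(sd_ms = pp$jitter$sd_ms, mean_ms = pp$jitter$mean_ms,
                  ci95_ms = pp$jitter$ci95_ms),
    segment_index = unclass(pp$segment_index),
    segment_reference = unclass(pp$segment_reference)), out[["report"]])
  out
}

.wf_cop <- function(args, cfg) {
  .require_args(args, c("input", "device", "out"))
  device <- match.arg(args$device, c("corner_board", "wrench_plate"))
  rate_default <- if (device == "corner_board") 40 else 100
  rec <- read_recording(args$input, device, args$rate %||% rate_default)
  write_cop(args$out, compute_cop(rec, cfg))
  c(cop = args$out)
}

.wf_metrics <- function(args, cfg) {
  .require_args(args, c("cop", "out"))
  traj <- read_cop(args$cop, rate = args$rate)
  metrics <- compute_sway_metrics(traj, seg = NULL, cfg = cfg)
  write_report_json(as.list(metrics), args$out)
  c(metrics = args$out)
}

.read_metric_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, as.numeric)
}

.wf_validity <- function(args) {
  .require_args(args, c("index", "reference", "out"))
  rep <- validity_report(.read_metric_table(args$index),
                         .read_metric_table(args$reference))
  out <- lapply(rep, function(r) {
    list(icc_a1 = .icc_to_list(r$icc_a1), agreement = unclass(r$agreement),
         n = r$n, n_dropped = r$n_dropped)
  })
  write_report_json(list(schema = "coptools/validity/v1", metrics = out), args$out)
  c(report = args$out)
}

.wf_reliability <- function(args) {
  .require_args(args, c("session1", "session2", "out"))
  s1 <- .read_metric_table(args$session1)
  s2 <- .read_metric_table(args$session2)
  shared <- intersect(names(s1), names(s2))
  if (length(shared) == 0L) stop_coptools("no shared metric names", "format_error")
  mats <- lapply(setNames(shared, shared), function(nm) cbind(s1[[nm]], s2[[nm]]))
  rep <- reliability_report(mats)
  out <- lapply(rep, function(r) {
    list(icc = lapply(r$icc, .icc_to_list),
         reported_form = r$primary_kind, bias_flag = r$gate$bias_flag,
         max_icc_difference = r$gate$max_difference,
         pooled_sd = r$pooled_sd, sd_source = r$sd_source,
         sem = r$sem, mdc = r$mdc, n = r$n, n_dropped = r$n_dropped)
  })
  write_report_json(list(schema = "coptools/reliability/v1", metrics = out), args$out)
  c(report = args$out)
}

.wf_psd <- function(args, cfg) {
  .require_args(args, c("cop_files", "out"))
  psds_ml <- list(); psds_ap <- list()
  for (path in args$cop_files) {
    traj <- read_cop(path, rate = args$rate)
    psds_ml[[path]] <- psd_welch(traj$ml, traj$rate)
    psds_ap[[path]] <- psd_welch(traj$ap, traj$rate)
  }
  avg_ml <- psd_group_average(psds_ml)
  avg_ap <- psd_group_average(psds_ap)
  write_report_json(list(schema = "coptools/psd/v1",
                         freqs_hz = avg_ml$freqs,
                         power_ml_cm2_hz = avg_ml$power,
                         power_ap_cm2_hz = avg_ap$power,
                         n_participants = length(args$cop_files)), args$out)
  c(spectra = args$out)
}

#' Run a named workflow
#'
#' Single programmatic entry point behind the command-line tool. Arguments
#' are a named list mirroring the CLI flags of each workflow; outputs and a
#' run manifest (config snapshot, input/output digests, seed, warnings) are
#' written to `out` / `out_dir`. Inputs are never mutated.
#'
#' @param name One of `"simulate"`, `"calibrate"`, `"preprocess"`, `"cop"`,
#'   `"metrics"`, `"validity"`, `"reliability"`, `"psd"`.
#' @param args Named list of workflow arguments (file paths, `task`,
#'   `seed`, `config` = path to a YAML [run_config()] file, ...).
#' @return List with `status` (0 ok, 1 computational error, 2 usage/file
#'   error), `outputs` (named paths), `manifest`, `warnings`, and
#'   `error` (message, when status > 0).
#' @export
run_workflow <- function(name, args = list()) {
  warnings_seen <- character(0)
  result <- withCallingHandlers(
    tryCatch({
      known <- c("simulate", "calibrate", "preprocess", "cop", "metrics",
                 "validity", "reliability", "psd")
      if (!name %in% known) {
        stop_coptools(sprintf("unknown workflow '%s' (expected one of: %s)",
                              name, paste(known, collapse = ", ")), "config_error")
      }
      cfg <- .load_cfg(args)
      outputs <- switch(name,
        simulate = .wf_simulate(args),
        calibrate = .wf_calibrate(args),
        preprocess = .wf_preprocess(args, cfg),
        cop = .wf_cop(args, cfg),
        metrics = .wf_metrics(args, cfg),
        validity = .wf_validity(args),
        reliability = .wf_reliability(args),
        psd = .wf_psd(args, cfg)
      )
      in_keys <- c("index", "reference", "zero", "load", "cop", "input",
                   "session1", "session2", "config", "calibration")
      inputs <- unlist(args[intersect(in_keys, names(args))], use.names = FALSE)
      inputs <- c(inputs, unlist(args$cop_files, use.names = FALSE))
      man_dir <- args$out_dir %||% dirname(args$out %||% ".")
      manifest <- .write_manifest(man_dir, name, args, cfg,
                                  inputs %||% character(0), outputs,
                                  warnings_seen, seed = args$seed)
      list(status = 0L, outputs = as.list(outputs), manifest = manifest,
           warnings = warnings_seen, error = NULL)
    }, coptools_error = function(e) {
      status <- if (any(class(e) %in% .usage_classes)) 2L else 1L
      list(status = status, outputs = list(), manifest = NULL,
           warnings = warnings_seen,
           error = sprintf("[%s] %s", name, conditionMessage(e)))
    }),
    coptools_warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  result
}
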