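#' Read / write a waveform CSV
#'
#' Two-column CSV with header `time_ms,pressure_mmHg`. Values are written at
#' full float precision, so a write/read round trip reproduces the samples
#' bitwise; sampling uniformity is validated on read.
#'
#' @param path file path.
#' @return a `pressure_waveform` (read) or `path` invisibly (write).
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  if (file.size(path) == 0) stop("empty waveform file: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("time_ms", "pressure_mmHg") %in% names(df)))
    stop("waveform CSV must have header columns time_ms, pressure_mmHg")
  pressure_waveform(df$time_ms, df$pressure_mmHg)
}

#' @rdname read_waveform_csv
#' @param w a `pressure_waveform`.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "pressure_waveform"))
  df <- data.frame(time_ms = sprintf("%.17g", w$time_ms),
                   pressure_mmHg = sprintf("%.17g", w$pressure_mmHg))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles everything a pipeline run needs: the tree file, solver numerics,
#' fitting settings, population spec, optional fistula spec, output
#' directory and the global seed from which all per-stage seeds derive.
#' Can be loaded from a YAML/JSON file with [read_run_config()].
#'
#' @param tree_file path to a tree definition (default: packaged nominal
#'   55-vessel tree).
#' @param numerics a [numerics_config()].
#' @param fit a [fit_config()].
#' @param population a [population_spec()].
#' @param fistula optional [fistula_spec()].
#' @param out_dir output directory for artifacts.
#' @param seed global integer seed.
#' @export
run_config <- function(tree_file = NULL, numerics = numerics_config(),
                       fit = fit_config(), population = population_spec(),
                       fistula = NULL, out_dir = tempfile("pulsewave_run_"),
                       seed = 1) {
  tree_file <- tree_file %||% system.file("extdata",
                                          "arterial_tree_55.json",
                                          package = "pulsewave",
                                          mustWork = TRUE)
  if (!file.exists(tree_file)) stop("tree file not found: ", tree_file)
  structure(list(tree_file = tree_file, numerics = numerics, fit = fit,
                 population = population, fistula = fistula,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' Any omitted block falls back to the package default. Recognised blocks:
#' `tree_file`, `numerics` (`dx_cm`, `cfl`, `tol_mmHg`, `max_cycles`,
#' `junction_mode`), `fit` (`particles`, `iterations`, `seed`, `norm`),
#' `population` (`missingness`, `device_rate_hz`, `noise_frac`),
#' `fistula` (`site`, `resistance`), `out_dir`, `seed`.
#'
#' @param path config file path (.yaml/.yml/.json).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  num <- do.call(numerics_config, raw$numerics %||% list())
  fit <- do.call(fit_config, raw$fit %||% list())
  pop <- do.call(population_spec, raw$population %||% list())
  fist <- if (!is.null(raw$fistula)) do.call(fistula_spec, raw$fistula)
  run_config(tree_file = raw$tree_file, numerics = num, fit = fit,
             population = pop, fistula = fist,
             out_dir = raw$out_dir %||% tempfile("pulsewave_run_"),
             seed = raw$seed %||% 1)
}

write_manifest <- function(cfg, command, extra = list()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(list(command = command, seed = cfg$seed,
                     config_hash = config_hash(cfg),
                     package_version =
                       as.character(utils::packageVersion("pulsewave")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC")),
                extra)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run a pipeline command
#'
#' The programmatic entry point mirroring the study workflow. Commands:
#' \describe{
#'   \item{simulate}{forward run at given parameters; writes per-site
#'     waveform CSVs (`radial_distal`, `aortic_root`) and returns the
#'     `sim_result`.}
#'   \item{fit}{fit a waveform (`waveform_file` + `meta`); writes the
#'     fit result JSON.}
#'   \item{indices}{pulse wave analysis of a waveform file.}
#'   \item{pwv}{forward run + aortic-arch-to-femoral pulse wave velocity.}
#'   \item{synth}{generate a virtual cohort dataset (`n_hd`, `n_control`)
#'     into the output directory.}
#'   \item{cohort-stats}{summary statistics of a generated dataset
#'     (`dataset_dir`): group comparison of covariates and the
#'     repeated-measures test on the truth k3 trajectory.}
#'   \item{fistula-experiment}{fistula-free refitting experiment on
#'     `n_subjects` virtual controls.}
#' }
#' Every run writes `manifest.json` (command, seed, config hash, versions)
#' into the output directory.
#'
#' @param command one of the commands above.
#' @param config a [run_config()].
#' @param ... command-specific arguments (see Details).
#' @return command result, invisibly where large.
#' @export
run_pipeline <- function(command, config = run_config(), ...) {
  cmds <- c("simulate", "fit", "indices", "pwv", "synth", "cohort-stats",
            "fistula-experiment")
  if (!command %in% cmds)
    stop("unknown command '", command, "'; available: ",
         paste(cmds, collapse = ", "))
  args <- list(...)
  tree <- load_tree(config$tree_file)
  if (!is.null(config$fistula)) tree <- add_fistula(tree, config$fistula)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (command %in% c("simulate", "pwv")) {
    pars <- args$params %||% patient_parameters(
      k1 = 2.28e7, k3 = 14.51e5, CO = 3.56, tau = 101.08, S_R = 1.34,
      S_C = 13.57, HR = 60)
    if (!is.null(args$height_cm))
      tree <- scale_tree_to_height(tree, args$height_cm)
    sim <- simulate_cycle(tree, pars, numerics = config$numerics)
    if (command == "simulate") {
      for (site in c("radial_distal", "aortic_root"))
        write_waveform_csv(site_waveform(sim, site),
                           file.path(config$out_dir, paste0(site, ".csv")))
      write_manifest(config, command,
                     list(cycles = sim$cycles, converged = sim$converged))
      return(invisible(sim))
    }
    pwv <- pulse_wave_velocity(sim, args$site_a %||% "aortic_arch",
                               args$site_b %||% "femoral")
    write_manifest(config, command, list(pwv_m_s = pwv))
    return(pwv)
  }

  if (command == "fit") {
    w <- if (!is.null(args[["waveform"]])) args[["waveform"]]
    else read_waveform_csv(args[["waveform_file"]])
    meta <- args$meta %||% list()
    if (!is.null(meta$brachial_SP) && !w$calibrated)
      w <- calibrate_waveform(w, meta$brachial_SP, meta$brachial_DP)
    else w$calibrated <- TRUE
    cfg_fit <- config$fit
    cfg_fit$seed <- derive_seed(config$seed, 2L)
    fit <- fit_patient(w, meta, tree = tree, config = cfg_fit)
    out <- list(estimates = as.list(fit$estimates),
                rel_error = fit$rel_error, seed = fit$seed,
                config_hash = fit$config_hash, converged = fit$converged)
    jsonlite::write_json(out, file.path(config$out_dir, "fit_result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(config, command, list(rel_error = fit$rel_error))
    return(invisible(fit))
  }

  if (command == "indices") {
    w <- if (!is.null(args[["waveform"]])) args[["waveform"]]
    else read_waveform_csv(args[["waveform_file"]])
    if (!is.null(args$brachial_SP))
      w <- calibrate_waveform(w, args$brachial_SP, args$brachial_DP)
    else w$calibrated <- TRUE
    idx <- pwa_indices(w)
    jsonlite::write_json(unclass(idx),
                         file.path(config$out_dir, "pwa_indices.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(config, command, list(AI = idx$AI, SEVR = idx$SEVR))
    return(idx)
  }

  if (command == "synth") {
    ds <- generate_cohort_dataset(
      n_hd = args$n_hd %||% 2, n_control = args$n_control %||% 2,
      spec = config$population, seed = derive_seed(config$seed, 3L),
      waveforms = args$waveforms %||% "simulate",
      tree = tree, numerics = config$numerics)
    write_cohort_dataset(ds, file.path(config$out_dir, "dataset"))
    write_manifest(config, command,
                   list(n_recordings = length(ds$recordings),
                        n_missing = sum(vapply(ds$recordings,
                                               function(r) r$missing, TRUE))))
    return(invisible(ds))
  }

  if (command == "cohort-stats") {
    ds <- if (!is.null(args$dataset)) args$dataset
    else read_cohort_dataset(args$dataset_dir)
    age_t <- two_group_tests(ds$subjects$age[ds$subjects$group == "hd"],
                             ds$subjects$age[ds$subjects$group == "control"])
    k3_tab <- cohort_parameter_table(ds, "k3")
    wt <- tryCatch(wittkowski_test(k3_tab), error = function(e) NULL)
    res <- list(age_comparison = age_t,
                k3_repeated_measures = wt,
                pairwise = if (!is.null(wt)) scheffe_pairwise(k3_tab))
    jsonlite::write_json(res, file.path(config$out_dir, "cohort_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    write_manifest(config, command, list())
    return(invisible(res))
  }

  ## fistula-experiment
  n_sub <- args$n_subjects %||% 3
  subjects <- lapply(seq_len(n_sub), function(i)
    sample_virtual_patient(config$population, "control",
                           seed = derive_seed(config$seed, 500L + i), id = i))
  cfg_fit <- config$fit
  cfg_fit$seed <- derive_seed(config$seed, 4L)
  res <- fistula_free_refit_experiment(
    subjects, fspec = config$fistula %||% fistula_spec(),
    config = cfg_fit, spec = config$population)
  write.csv(res, file.path(config$out_dir, "fistula_refit.csv"),
            row.names = FALSE)
  write_manifest(config, command, list(n_subjects = n_sub))
  invisible(res)
}
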