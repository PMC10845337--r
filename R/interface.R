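# Run configuration, provenance, and the thin entry points behind the
# command-line wrapper (inst/cli/layoutstudy.R).

#' Run configuration
#'
#' Everything needed to reproduce a simulate/analyze run: the study design,
#' the cohort preset, the filter thresholds, the inference settings, the
#' output directory and the seed.
#'
#' @param study A [study_config()].
#' @param preset Cohort preset name for [preset_cohorts()] (`"mturk"` or
#'   `"expert"`).
#' @param rt_cutoff Response-time outlier cutoff in seconds.
#' @param consistency_threshold Participant exclusion bound.
#' @param alpha Significance level.
#' @param adjust_method Multiple-testing adjustment method.
#' @param output_dir Directory for report output.
#' @param seed Integer seed for the simulation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(study = study_config(), preset = "mturk",
                       rt_cutoff = 5000, consistency_threshold = 0.20,
                       alpha = 0.05, adjust_method = "bh",
                       output_dir = "layoutstudy_output", seed = 1L) {
  stopifnot(inherits(study, "study_config"))
  structure(list(study = study, preset = preset, rt_cutoff = rt_cutoff,
                 consistency_threshold = consistency_threshold,
                 alpha = alpha, adjust_method = adjust_method,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Every [run_config()] field (including the nested study design) round
#' trips through a plain YAML key-value file.
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return A `run_config` (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  study_fields <- raw$study
  study <- do.call(study_config, study_fields[!vapply(study_fields, is.null,
                                                      logical(1))])
  args <- raw[setdiff(names(raw), "study")]
  do.call(run_config, c(list(study = study), args))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- unclass(config)
  raw$study <- unclass(config$study)
  yaml::write_yaml(raw, path)
  invisible(path)
}

.write_provenance <- function(config, path, extra = list()) {
  raw <- unclass(config)
  raw$study <- unclass(config$study)
  yaml::write_yaml(c(raw, extra), path)
  invisible(path)
}

#' Simulate a study from a run configuration
#'
#' Simulates the configured cohort preset and writes the response table as
#' CSV with a YAML provenance sidecar (config echo plus seed) next to it.
#'
#' @param config A [run_config()].
#' @param out_csv Output CSV path.
#' @return The path of the written CSV, invisibly.
#' @export
cli_simulate <- function(config, out_csv) {
  stopifnot(inherits(config, "run_config"))
  tab <- simulate_study(preset_cohorts(config$preset), config$study,
                        seed = config$seed)
  write_responses(tab, out_csv)
  .write_provenance(config, paste0(out_csv, ".provenance.yaml"),
                    list(n_records = nrow(tab)))
  message(sprintf("wrote %d responses to %s", nrow(tab), out_csv))
  invisible(out_csv)
}

#' Analyze a response table from a run configuration
#'
#' Reads and validates the CSV, runs [analyze_study()], and writes the full
#' report bundle plus a run log recording filter removals and test counts.
#'
#' @param table_path Response-table CSV path.
#' @param config A [run_config()].
#' @param out_dir Report directory; defaults to `config$output_dir`.
#' @return The `layout_study` object, invisibly.
#' @export
cli_analyze <- function(table_path, config = run_config(), out_dir = NULL) {
  tab <- read_responses(table_path)
  fit <- analyze_study(tab, config$study, rt_cutoff = config$rt_cutoff,
                       consistency_threshold = config$consistency_threshold,
                       alpha = config$alpha,
                       adjust_method = config$adjust_method)
  dir <- if (is.null(out_dir)) config$output_dir else out_dir
  write_report(fit, dir)
  n_tests <- sum(vapply(
    list(fit$consistency_test$pairwise, fit$accuracy_test,
         fit$rt_test$pairwise, fit$learning_test$pairwise,
         fit$inversion_share_test,
         if (is.null(fit$intersegment_test)) NULL
         else fit$intersegment_test$pairwise,
         fit$min_distance_test$pairwise),
    function(x) if (is.null(x)) 0L else nrow(x), integer(1)))
  log_lines <- c(
    sprintf("input: %s (%d rows)", table_path, nrow(tab)),
    sprintf("responses removed by rt filter (> %.0f s): %d", config$rt_cutoff,
            nrow(fit$filter_log$removed_responses)),
    sprintf("participants excluded (consistency <= %.2f): %d",
            config$consistency_threshold,
            nrow(fit$filter_log$excluded_participants)),
    sprintf("pairwise tests run: %d (alpha = %.2f, adjustment = %s)",
            n_tests, config$alpha, config$adjust_method))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  .write_provenance(config, file.path(dir, "provenance.yaml"),
                    list(input = table_path))
  invisible(fit)
}

#' Render one layout as SVG
#'
#' @param contact_str Contact as a string `"a-b"`, e.g. `"2-5"`.
#' @param layout `"circular"`, `"half_matrix"` or `"matrix"`.
#' @param n_segments Chain length.
#' @param out Output SVG path.
#' @return `out`, invisibly.
#' @export
cli_render <- function(contact_str, layout, n_segments = 8L, out) {
  parts <- suppressWarnings(as.integer(strsplit(contact_str, "-")[[1]]))
  if (length(parts) != 2L || any(is.na(parts)))
    stop("contact must be of the form 'a-b' with integer segments",
         call. = FALSE)
  if (parts[1] >= parts[2])
    stop("invalid contact: need a < b", call. = FALSE)
  ct <- contact(parts[1], parts[2], n_segments)
  write_svg(layout_geometry(layout, ct, n_segments), out)
  invisible(out)
}
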