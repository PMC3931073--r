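#' Run the full simulate-fit-analyze-report pipeline
#'
#' File-based wrapper around [battery()]: validates a configuration,
#' runs the synthetic study, and writes a parameter report (delimited text
#' and JSON) plus the per-fit records into an artifacts directory. Every
#' number in the report is recomputable from the persisted fit records.
#'
#' @param config a named list, or path to a JSON file, with fields:
#'   `params_ref` / `params_alt` (either `"WT"` / `"R453C"` to use the
#'   built-in reference sets, a source-qualified string like
#'   `"R453C:figures"`, or paths to a directory containing `scheme1.json`
#'   and `scheme2.json` written by [write_params()]); `seed` (default 42);
#'   `out_dir` (default `"myokin-out"`); `n_prep` (default 3); `noise_sd`
#'   (% of pre-mix fluorescence, default 0.5); optional `designs` subset.
#' @return the `myokin_battery` object, invisibly; artifacts are written to
#'   `out_dir` (`report.tsv`, `report.json`, `fits.tsv`, `truth.json`).
#' @examples
#' \donttest{
#' out <- run_battery(list(params_ref = "WT", params_alt = "R453C",
#'                         seed = 42, n_prep = 2, noise_sd = 0.3,
#'                         out_dir = tempfile("battery")))
#' out$report
#' }
#' @export
run_battery <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file '%s' not found.", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config) || is.null(config$params_ref) || is.null(config$params_alt)) {
    abort("config must be a list (or JSON file) with at least `params_ref` and `params_alt`.")
  }
  seed <- as.integer(config$seed %||% 42)
  n_prep <- as.integer(config$n_prep %||% 3)
  noise_sd <- as.numeric(config$noise_sd %||% 0.5)
  out_dir <- config$out_dir %||% "myokin-out"
  designs <- config$designs %||% c("trp_atp_titration", "pyrene_atp_dissociation",
                                   "adp_competition", "adp_displacement",
                                   "actin_titration")
  load_construct <- function(x) {
    if (is.list(x)) return(x)
    if (x %in% c("WT", "R453C")) return(reference_params(x))
    if (grepl("^(WT|R453C):(table|figures)$", x)) {
      parts <- strsplit(x, ":", fixed = TRUE)[[1]]
      return(reference_params(parts[1], parts[2]))
    }
    if (dir.exists(x)) {
      return(list(scheme1 = read_params(file.path(x, "scheme1.json")),
                  scheme2 = read_params(file.path(x, "scheme2.json"))))
    }
    abort(sprintf("cannot resolve construct parameters from '%s'.", x))
  }
  p_ref <- load_construct(config$params_ref)
  p_alt <- load_construct(config$params_alt)
  inst <- instrument_model(noise_sd = noise_sd)
  res <- battery(p_ref, p_alt, seed = seed, n_prep = n_prep,
                 instrument = inst, designs = designs)
  if (!all(is.finite(res$fits$value))) {
    warn("some fits did not produce finite estimates; report has gaps.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$fits, file.path(out_dir, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$report, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(seed = seed, n_prep = n_prep, noise_sd = noise_sd,
                            designs = designs),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Fit exponential phases to a trace file
#'
#' Reads a trace in the package's delimited text format (see
#' [write_trace()]), selects the phase count by the extra-sum-of-squares
#' F-test unless `n_phases` is given, and returns the fit.
#'
#' @param path trace file path.
#' @param n_phases `NULL` (automatic), 1 or 2.
#' @return an `exp_fit` object; its `tidy()` rows are the per-phase record.
#' @export
fit_file <- function(path, n_phases = NULL) {
  if (!file.exists(path)) abort(sprintf("trace file '%s' not found.", path))
  trace <- read_trace(path)
  validate_trace(trace)
  if (is.null(n_phases)) {
    n_phases <- as.integer(select_phase_count(trace))
  }
  fit_exponentials(trace, n_phases)
}
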