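# Orchestration: run the self-association, binding and CSP stages for
# each compound in a run configuration and emit a combined report.

#' Build or read a run configuration
#'
#' A run configuration names the input files and options for each
#' compound.  `run_config()` builds one in code; `read_run_config()`
#' reads the same structure from JSON.  Each compound entry is a list
#' with any of the fields `dilution` (path, wide CSV), `exclude`
#' (protons excluded from the mean ka), `dosy` (path, long diffusion
#' CSV with species `ligand_free`/`dna_free`/`ligand_obs`/`dna_obs`),
#' `c_ligand`, `c_dna` (mM), and `shifts` (path(s) to shift CSVs).
#'
#' @param compounds Named list of compound entries (see above).
#' @param threshold CSP significance threshold, ppm (> 0).
#' @param rounding_slack CSP rounding slack (see [flag_significant()]).
#' @param nick Path to a nick-map JSON, or `NULL` for [nick_map()].
#' @param out_dir Directory for the JSON report and text summary, or
#'   `NULL` to skip writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(compounds, threshold = 0.02, rounding_slack = TRUE,
                       nick = NULL, out_dir = NULL) {
  if (length(compounds) == 0 || is.null(names(compounds))) {
    abort("`compounds` must be a non-empty named list")
  }
  if (!is.numeric(threshold) || threshold <= 0) abort("`threshold` must be > 0")
  paths <- unlist(lapply(compounds, function(e) {
    c(e$dilution, e$dosy, e$shifts)
  }), use.names = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  structure(list(compounds = compounds, threshold = threshold,
                 rounding_slack = isTRUE(rounding_slack),
                 nick = nick, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path Path to a JSON run configuration.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  run_config(compounds = x$compounds,
             threshold = x$threshold %||% 0.02,
             rounding_slack = x$rounding_slack %||% TRUE,
             nick = x$nick, out_dir = x$out_dir)
}

#' Run the full analysis pipeline
#'
#' Executes, for every compound in the configuration, the stages whose
#' inputs are present: isodesmic self-association fitting of the
#' dilution series (per-proton fits plus the mean ka with the stated
#' exclusions), the DOSY fast-exchange binding analysis, and CSP
#' computation with significance flagging and nick localisation.  A
#' failing stage is recorded and the remaining stages are still
#' attempted.  The report is self-describing: units, sign conventions
#' and the model assumptions are embedded.
#'
#' @param config A [run_config()].
#' @return A list of class `nmrbind_report` with elements `metadata`,
#'   `compounds` (per-compound stage results, as tibbles), `errors`
#'   (character vector of stage failures) and `ok` (no stage failed).
#'   If `config$out_dir` is set, `report.json` and `summary.txt` are
#'   written there.
#' @examples
#' cfg <- run_config(list(
#'   "1" = list(dilution = nmrbind_example("dilution_compound1.csv"),
#'              exclude = "H12",
#'              dosy = nmrbind_example("dosy_binding_compound1.csv"),
#'              c_ligand = 0.6, c_dna = 0.6,
#'              shifts = nmrbind_example("dna_shifts_compound1.csv"))))
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  nick <- if (is.null(config$nick)) nick_map() else read_nick_map(config$nick)
  log <- list()
  note <- function(compound, stage, e) {
    log[[length(log) + 1]] <<- sprintf("%s/%s: %s", compound, stage,
                                       conditionMessage(e))
  }
  compounds <- purrr::imap(config$compounds, function(entry, id) {
    res <- list()
    if (!is.null(entry$dilution)) {
      res$self_association <- tryCatch({
        fits <- fit_isodesmic_each(
          read_dilution_table(entry$dilution, compound_id = id))
        list(fits = dplyr::select(fits, -"fit"),
             summary_all = summarize_ka(fits),
             summary_excluded = if (length(entry$exclude))
               summarize_ka(fits, exclude = unlist(entry$exclude)) else NULL)
      }, error = function(e) { note(id, "selfassoc", e); NULL })
    }
    if (!is.null(entry$dosy)) {
      res$binding <- tryCatch({
        exp <- as_binding_experiment(read_diffusion_table(entry$dosy),
                                     c_ligand = entry$c_ligand,
                                     c_dna = entry$c_dna)
        analyze_binding(exp)
      }, error = function(e) { note(id, "binding", e); NULL })
    }
    if (!is.null(entry$shifts)) {
      res$csp <- tryCatch({
        recs <- dplyr::bind_rows(lapply(unlist(entry$shifts), read_shift_table))
        flagged <- flag_significant(compute_csp(recs),
                                    threshold = config$threshold,
                                    rounding_slack = config$rounding_slack)
        list(records = flagged,
             localization = localize_to_nick(flagged, nick))
      }, error = function(e) { note(id, "csp", e); NULL })
    }
    res
  })
  report <- structure(list(
    metadata = list(
      units = list(concentration = "mM", dilution_shift = "Hz",
                   csp_shift = "ppm", diffusion = "1e-10 m^2/s",
                   ka_self = "mM^-1", ka_binding = "mM^-1"),
      conventions = c(
        "dilution shift changes are referenced to the lowest-concentration sample",
        "positive shift change = low-frequency (upfield) shift",
        "CSP = shift(free) - shift(complexed), ppm"),
      assumptions = c("isodesmic (equal-K) self-association",
                      binding_assumptions()),
      csp_threshold_ppm = config$threshold,
      csp_rounding_slack = config$rounding_slack),
    compounds = compounds,
    errors = unlist(log) %||% character(),
    ok = length(log) == 0), class = "nmrbind_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass_deep(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' @export
print.nmrbind_report <- function(x, ...) {
  cat("nmrbind pipeline report\n")
  cat("  assumptions: ", paste(x$metadata$assumptions, collapse = "; "),
      "\n", sep = "")
  for (id in names(x$compounds)) {
    cat("compound ", id, "\n", sep = "")
    c_ <- x$compounds[[id]]
    if (!is.null(c_$self_association)) {
      s <- c_$self_association
      cat(sprintf("  self-association: mean ka = %.2f +/- %.2f mM^-1 over %d protons\n",
                  s$summary_all$mean_ka, s$summary_all$sd_ka, s$summary_all$n_used))
      if (!is.null(s$summary_excluded)) {
        cat(sprintf("    excluding %s: %.2f +/- %.2f mM^-1\n",
                    s$summary_excluded$excluded, s$summary_excluded$mean_ka,
                    s$summary_excluded$sd_ka))
      }
    }
    if (!is.null(c_$binding)) {
      b <- c_$binding
      cat(sprintf("  binding: mf_bound = %.2f, [DNA.L] = %.3f mM, ka = %.0f +/- %.0f mM^-1\n",
                  b$mf_bound, b$complex_conc, b$ka, b$ka_sigma))
    }
    if (!is.null(c_$csp)) {
      l <- c_$csp$localization
      cat(sprintf("  csp: %d flagged, %d nick-adjacent (%s)\n",
                  l$n_flagged, l$n_flagged_near_nick, l$conclusion))
    }
  }
  if (length(x$errors)) {
    cat("stage errors:\n", paste("  -", x$errors, collapse = "\n"), "\n")
  }
  invisible(x)
}
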