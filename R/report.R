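# Run-level entry points: simulate a cohort to CSV, evaluate pathways into
# Table-style CSV/JSON reports, and run decision-curve analysis. These are
# the functions behind the inst/cli wrapper script.

#' Resolve a cohort from a run configuration
#'
#' Exactly one source must be given: a cohort CSV `path`, or
#' `synthetic = "fixture"` / `"sample"` with a seed (and `n` for sampling).
#'
#' @param path Cohort CSV path, or `NULL`.
#' @param synthetic `NULL`, `"fixture"` or `"sample"`.
#' @param spec A `cohort_spec` for synthetic sources.
#' @param seed,n Seed and (for sampling) cohort size.
#' @return A validated cohort tibble.
#' @export
resolve_cohort <- function(path = NULL, synthetic = NULL,
                           spec = default_cohort_spec(), seed = 20230101,
                           n = NULL) {
  if (is.null(path) == is.null(synthetic)) {
    rlang::abort("Give exactly one cohort source: `path` or `synthetic`.",
                 class = "psadpathways_config_error")
  }
  if (!is.null(path)) return(read_cohort_csv(path))
  switch(synthetic,
         fixture = fixture_cohort(spec, seed = seed),
         sample = sample_cohort(spec, n = n %||% sum(spec$cells$n), seed = seed),
         rlang::abort("`synthetic` must be \"fixture\" or \"sample\".",
                      class = "psadpathways_config_error"))
}

resolve_pathways <- function(pathways = NULL) {
  if (is.null(pathways)) return(builtin_pathways())
  builtin <- builtin_pathways()
  out <- lapply(pathways, function(p) {
    if (inherits(p, "biopsy_pathway")) return(p)
    if (rlang::is_string(p) && p %in% names(builtin)) return(builtin[[p]])
    if (rlang::is_string(p) && file.exists(p)) {
      return(parse_pathway_config(paste(readLines(p, warn = FALSE),
                                        collapse = "\n")))
    }
    rlang::abort(sprintf("Unknown pathway '%s' (not a builtin name or config file).",
                         as.character(p)[1]),
                 class = "psadpathways_config_error")
  })
  stats::setNames(out, vapply(out, function(p) p$name, character(1)))
}

#' Simulate a cohort and write it to CSV
#'
#' Writes the cohort CSV plus a JSON provenance sidecar
#' (`<stem>.provenance.json`: source, seed, n, package version). Identical
#' arguments produce byte-identical CSV output.
#'
#' @param out_csv Output CSV path.
#' @param kind `"fixture"` (deterministic calibrated expansion) or
#'   `"sample"` (stochastic).
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @param n Cohort size for `kind = "sample"`; default the spec total.
#' @return The cohort tibble, invisibly.
#' @export
run_simulate <- function(out_csv, kind = c("fixture", "sample"),
                         spec = default_cohort_spec(), seed = 20230101,
                         n = NULL) {
  kind <- match.arg(kind)
  cohort <- resolve_cohort(synthetic = kind, spec = spec, seed = seed, n = n)
  write_cohort_csv(cohort, out_csv)
  sidecar <- sub("\\.csv$", "", out_csv)
  jsonlite::write_json(
    list(source = kind, seed = seed, n = nrow(cohort),
         n_cspca = sum(disease_status(cohort) == "cspca"),
         package = "psadpathways",
         version = as.character(utils::packageVersion("psadpathways"))),
    paste0(sidecar, ".provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

#' Evaluate pathways on a cohort and write reports
#'
#' Emits the prevalence cross-tabulation (`crosstab.csv`) and the pathway
#' outcome table (`outcomes.csv`, `outcomes.json`) into `out_dir`, and
#' checks the outcome conservation identities (biopsied + avoided = N;
#' detected + missed = total csPCa; detected + avoided iPCa = total iPCa).
#'
#' @param cohort A cohort tibble (or use `cohort_csv`).
#' @param out_dir Output directory (created if missing).
#' @param pathways Pathway list: `biopsy_pathway` objects, builtin names,
#'   or YAML config paths. Default: the four builtins.
#' @param cohort_csv Alternative cohort source: path to a cohort CSV.
#' @return List with `crosstab` and `outcomes`, invisibly.
#' @export
run_evaluate <- function(cohort = NULL, out_dir, pathways = NULL,
                         cohort_csv = NULL) {
  if (is.null(cohort)) cohort <- resolve_cohort(path = cohort_csv)
  cohort <- validate_cohort(cohort)
  defs <- resolve_pathways(pathways)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  xtab <- cross_tabulate(cohort)
  outcomes <- outcome_table(cohort, defs)

  stopifnot(
    all(outcomes$n_biopsied + outcomes$n_avoided == outcomes$n_total),
    all(outcomes$cspca_detected + outcomes$cspca_missed == xtab$n_cspca_total),
    all(outcomes$ipca_detected + outcomes$ipca_avoided ==
          sum(disease_status(cohort) == "ipca")))

  readr::write_csv(xtab$cells, file.path(out_dir, "crosstab.csv"))
  readr::write_csv(outcomes, file.path(out_dir, "outcomes.csv"))
  jsonlite::write_json(outcomes, file.path(out_dir, "outcomes.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(list(crosstab = xtab, outcomes = outcomes))
}

#' Decision-curve analysis with file output
#'
#' Writes the net-benefit curve (`dca_curves.csv`: threshold plus one
#' column per strategy) and the dominance report (`dca_dominance.json`)
#' into `out_dir`; optionally a plot.
#'
#' @param cohort A cohort tibble (or use `cohort_csv`).
#' @param out_dir Output directory.
#' @param pathways As in [run_evaluate()].
#' @param grid Threshold grid; default [threshold_grid()].
#' @param fp_convention Passed to [strategy_counts_from_outcome()].
#' @param plot_file Optional path for a PDF/PNG of the curves.
#' @param cohort_csv Alternative cohort source: path to a cohort CSV.
#' @return List with `curve` and `dominance`, invisibly.
#' @export
run_dca <- function(cohort = NULL, out_dir, pathways = NULL,
                    grid = threshold_grid(),
                    fp_convention = "biopsied_non_cspca",
                    plot_file = NULL, cohort_csv = NULL) {
  if (is.null(cohort)) cohort <- resolve_cohort(path = cohort_csv)
  cohort <- validate_cohort(cohort)
  defs <- resolve_pathways(pathways)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outcomes <- outcome_table(cohort, defs)
  strategies <- purrr::map_dfr(seq_len(nrow(outcomes)), function(i) {
    strategy_counts_from_outcome(outcomes[i, ], fp_convention = fp_convention)
  })
  prevalence <- sum(disease_status(cohort) == "cspca") / nrow(cohort)
  curve <- decision_curves(strategies, grid = grid, prevalence = prevalence)
  dom <- dominance_intervals(curve)
  readr::write_csv(curve_to_wide(curve), file.path(out_dir, "dca_curves.csv"))
  jsonlite::write_json(
    list(intervals = dom$intervals, crossovers = dom$crossovers,
         grid_step = dom$grid_step),
    file.path(out_dir, "dca_dominance.json"), auto_unbox = FALSE, digits = NA,
    pretty = TRUE)
  if (!is.null(plot_file)) {
    ggplot2::ggsave(plot_file, plot_decision_curves(curve),
                    width = 7, height = 5)
  }
  invisible(list(curve = curve, dominance = dom))
}
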