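# Cross-tabulation of csPCa prevalence by PI-RADS group x PSAD band,
# per-pathway outcome summaries, and Pearson chi-square comparisons.

#' Cross-tabulate csPCa prevalence by PI-RADS group and PSAD band
#'
#' Counts patients and clinically significant cancers in each of the twelve
#' cells (PI-RADS group 1-2 / 3 / 4-5 by PSAD band), the classic
#' risk-stratification contingency table.
#'
#' @param cohort A cohort tibble.
#' @return An object of class `cspca_crosstab`: a list with `cells` (tibble
#'   with `pirads_group`, `band`, `n`, `n_cspca`, `prevalence`), `row_margins`,
#'   `col_margins`, and totals `n_total`, `n_cspca_total`.
#' @export
cross_tabulate <- function(cohort) {
  cohort <- validate_cohort(cohort)
  status <- disease_status(cohort)
  df <- tibble::tibble(
    pirads_group = pirads_group(cohort$pirads),
    band = assign_psad_band(cohort$psad),
    cspca = status == "cspca")
  cells <- df |>
    dplyr::group_by(.data$pirads_group, .data$band, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), n_cspca = sum(.data$cspca),
                     .groups = "drop") |>
    dplyr::mutate(prevalence = ifelse(.data$n > 0, .data$n_cspca / .data$n, NA_real_))
  row_margins <- cells |>
    dplyr::group_by(.data$pirads_group) |>
    dplyr::summarise(n = sum(.data$n), n_cspca = sum(.data$n_cspca),
                     .groups = "drop")
  col_margins <- cells |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(n = sum(.data$n), n_cspca = sum(.data$n_cspca),
                     .groups = "drop")
  structure(list(cells = cells, row_margins = row_margins,
                 col_margins = col_margins,
                 n_total = nrow(cohort),
                 n_cspca_total = sum(df$cspca)),
            class = "cspca_crosstab")
}

#' @export
print.cspca_crosstab <- function(x, ...) {
  cat(sprintf("<cspca_crosstab> %d patients, %d csPCa (%.1f%%)\n",
              x$n_total, x$n_cspca_total, 100 * x$n_cspca_total / x$n_total))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$cells,
                  cell = sprintf("%d/%d (%.1f%%)", .data$n_cspca, .data$n,
                                 100 * .data$prevalence)),
    id_cols = "pirads_group", names_from = "band", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Look up one cross-tab cell
#'
#' @param xtab A `cspca_crosstab`.
#' @param pirads_group `"1-2"`, `"3"` or `"4-5"`.
#' @param band A PSAD band name.
#' @return One-row tibble with `n`, `n_cspca`, `prevalence`.
#' @export
crosstab_cell <- function(xtab, pirads_group, band) {
  stopifnot(inherits(xtab, "cspca_crosstab"))
  dplyr::filter(xtab$cells, .data$pirads_group == !!pirads_group,
                .data$band == !!band)
}

#' Outcome summary of a pathway on a cohort
#'
#' Intersects the pathway's biopsy decisions with ground-truth disease
#' status. All primary rates use the full cohort size as denominator (the
#' usual reporting convention for pathway comparisons); per-biopsy rates
#' are available as `*_per_biopsy` columns.
#'
#' Two accountings of a "negative" biopsy are reported: `negative_biopsies`
#' counts biopsied men with no cancer of any grade (fully benign), while
#' `fp_non_cspca` counts biopsied men without clinically significant cancer
#' (benign plus insignificant cancer) — the false positives of the default
#' decision-curve convention.
#'
#' @param cohort A cohort tibble.
#' @param decisions A decision tibble from [apply_pathway()] covering
#'   exactly the cohort's patient ids.
#' @return One-row tibble with counts `n_total`, `n_biopsied`, `n_avoided`,
#'   `cspca_detected`, `cspca_missed`, `ipca_detected`, `ipca_avoided`,
#'   `negative_biopsies`, `fp_non_cspca` and corresponding `rate_*` columns
#'   (fractions of `n_total`).
#' @export
pathway_outcomes <- function(cohort, decisions) {
  cohort <- validate_cohort(cohort)
  if (!all(c("patient_id", "decision") %in% names(decisions))) {
    rlang::abort("`decisions` must have `patient_id` and `decision` columns.",
                 class = "psadpathways_validation_error")
  }
  if (!setequal(decisions$patient_id, cohort$patient_id) ||
      nrow(decisions) != nrow(cohort)) {
    rlang::abort("`decisions` must cover exactly the cohort's patient ids.",
                 class = "psadpathways_validation_error")
  }
  status <- disease_status(cohort)
  biopsy <- decisions$decision[match(cohort$patient_id, decisions$patient_id)] == "biopsy"
  n <- nrow(cohort)
  counts <- tibble::tibble(
    pathway = attr(decisions, "pathway") %||% "unnamed",
    n_total = n,
    n_biopsied = sum(biopsy),
    n_avoided = sum(!biopsy),
    cspca_detected = sum(biopsy & status == "cspca"),
    cspca_missed = sum(!biopsy & status == "cspca"),
    ipca_detected = sum(biopsy & status == "ipca"),
    ipca_avoided = sum(!biopsy & status == "ipca"),
    negative_biopsies = sum(biopsy & status == "negative"))
  counts$fp_non_cspca <- counts$ipca_detected + counts$negative_biopsies
  rated <- c("n_biopsied", "n_avoided", "cspca_detected", "cspca_missed",
             "ipca_detected", "ipca_avoided", "negative_biopsies",
             "fp_non_cspca")
  for (col in rated) counts[[paste0("rate_", col)]] <- counts[[col]] / n
  counts$cspca_detected_per_biopsy <-
    ifelse(counts$n_biopsied > 0, counts$cspca_detected / counts$n_biopsied, NA_real_)
  counts$negative_per_biopsy <-
    ifelse(counts$n_biopsied > 0, counts$negative_biopsies / counts$n_biopsied, NA_real_)
  counts
}

#' Outcome table for several pathways
#'
#' @param cohort A cohort tibble.
#' @param pathways A list of `biopsy_pathway` objects (e.g.
#'   [builtin_pathways()]).
#' @return Tibble with one [pathway_outcomes()] row per pathway, input order
#'   preserved.
#' @export
outcome_table <- function(cohort, pathways) {
  if (length(pathways) == 0) {
    rlang::abort("`pathways` must contain at least one pathway definition.",
                 class = "psadpathways_validation_error")
  }
  cohort <- validate_cohort(cohort)
  purrr::map_dfr(pathways, function(p) {
    pathway_outcomes(cohort, apply_pathway(p, cohort))
  })
}

#' Pearson chi-square comparison of two pathway outcomes
#'
#' Compares one count metric between two pathways evaluated on cohorts of
#' the same size, as a 2 x 2 Pearson chi-square on
#' `[count, n_total - count]` per pathway. No continuity correction by
#' default (the conventional Pearson test at large N); Yates' correction is
#' available via `correct = TRUE`.
#'
#' @param a,b One-row outcome tibbles from [pathway_outcomes()].
#' @param metric One of `"cspca_detected"`, `"ipca_detected"`,
#'   `"cspca_missed"`, `"n_avoided"`, `"negative_biopsies"`,
#'   `"fp_non_cspca"`.
#' @param correct Apply Yates' continuity correction? Default `FALSE`.
#' @return A list of class `chisq_compare` with `statistic`, `df`,
#'   `p_value`, and the 2 x 2 `table` used.
#' @export
compare_chi_square <- function(a, b,
                               metric = c("cspca_detected", "ipca_detected",
                                          "cspca_missed", "n_avoided",
                                          "negative_biopsies", "fp_non_cspca"),
                               correct = FALSE) {
  metric <- match.arg(metric)
  if (a$n_total != b$n_total) {
    rlang::abort("Outcomes being compared must share the same n_total.",
                 class = "psadpathways_validation_error")
  }
  tab <- rbind(c(a[[metric]], a$n_total - a[[metric]]),
               c(b[[metric]], b$n_total - b[[metric]]))
  dimnames(tab) <- list(pathway = c(a$pathway, b$pathway),
                        outcome = c(metric, "rest"))
  chi_square_2x2(tab, correct = correct)
}

#' Pearson chi-square on a 2 x 2 table
#'
#' @param tab A 2 x 2 matrix of non-negative counts.
#' @param correct Apply Yates' continuity correction? Default `FALSE`.
#' @return A list of class `chisq_compare` with `statistic`, `df`,
#'   `p_value`, `table`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("Chi-square is undefined on a table with a zero margin.",
                 class = "psadpathways_validation_error")
  }
  if (all(tab[1, ] == tab[2, ])) {
    # chisq.test is exact here too, but make the degenerate case explicit
    res <- list(statistic = 0, df = 1L, p_value = 1, table = tab)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    res <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p_value = unname(ct$p.value), table = tab)
  }
  structure(res, class = "chisq_compare")
}

#' @export
print.chisq_compare <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}
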