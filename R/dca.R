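# Decision-curve analysis for fixed biopsy strategies: net benefit over a
# threshold-probability grid, treat-all / treat-none references, closed-form
# crossovers and dominance intervals.

#' Net benefit of a strategy at threshold probability
#'
#' Net benefit weighs true positives (significant cancers detected) against
#' false positives (unnecessary biopsies), with the harm of a false
#' positive priced at the odds of the threshold probability:
#' \deqn{NB(p_t) = \frac{TP}{N} - \frac{FP}{N} \cdot \frac{p_t}{1 - p_t}.}
#' May be negative. At \eqn{p_t = 0} it reduces to \eqn{TP/N}.
#'
#' @param tp True positives.
#' @param fp False positives.
#' @param n Total subjects.
#' @param p_t Threshold probability / probabilities in \[0, 1).
#' @return Net benefit, vectorised over `p_t`.
#' @examples
#' net_benefit(tp = 623, fp = 1432, n = 2055, p_t = 0)     # prevalence
#' net_benefit(tp = 589, fp = 353, n = 2055, p_t = 0.10)
#' @export
net_benefit <- function(tp, fp, n, p_t) {
  if (any(p_t < 0) || any(p_t >= 1)) {
    rlang::abort("`p_t` must lie in [0, 1).", class = "psadpathways_validation_error")
  }
  stopifnot(n > 0, tp >= 0, fp >= 0, tp + fp <= n)
  tp / n - (fp / n) * p_t / (1 - p_t)
}

#' Strategy counts for decision-curve analysis
#'
#' @param name Strategy name.
#' @param tp,fp,n True positives, false positives, total subjects.
#' @return One-row tibble (`name`, `n`, `tp`, `fp`) of class
#'   `strategy_counts`-compatible input for [decision_curves()].
#' @export
strategy_counts <- function(name, tp, fp, n) {
  stopifnot(n > 0, tp >= 0, fp >= 0, tp + fp <= n)
  tibble::tibble(name = name, n = n, tp = tp, fp = fp)
}

#' Strategy counts from a pathway outcome summary
#'
#' True positives are the clinically significant cancers the pathway
#' detects. Which biopsies count as false positives is a convention:
#' `"biopsied_non_cspca"` (default) treats every biopsy that does not find
#' significant cancer as harm — detection of insignificant cancer is
#' overdiagnosis, hence a false positive; `"benign_only"` counts only fully
#' benign biopsies.
#'
#' @param summary One-row tibble from [pathway_outcomes()].
#' @param fp_convention `"biopsied_non_cspca"` or `"benign_only"`.
#' @return One-row strategy-counts tibble.
#' @export
strategy_counts_from_outcome <- function(summary,
                                         fp_convention = c("biopsied_non_cspca",
                                                           "benign_only")) {
  fp_convention <- match.arg(fp_convention)
  fp <- switch(fp_convention,
               biopsied_non_cspca = summary$fp_non_cspca,
               benign_only = summary$negative_biopsies)
  strategy_counts(summary$pathway, tp = summary$cspca_detected, fp = fp,
                  n = summary$n_total)
}

#' Default threshold-probability grid
#'
#' 0 to 0.6 in steps of 0.001, the range conventionally plotted for
#' biopsy decisions.
#'
#' @param from,to,by Grid limits and step; `to` must be < 1.
#' @return Numeric vector of thresholds.
#' @export
threshold_grid <- function(from = 0, to = 0.6, by = 0.001) {
  grid <- seq(from, to, by = by)
  if (length(grid) == 0) {
    rlang::abort("Threshold grid is empty.", class = "psadpathways_validation_error")
  }
  if (any(grid < 0) || any(grid >= 1)) {
    rlang::abort("Threshold grid must lie within [0, 1).",
                 class = "psadpathways_validation_error")
  }
  grid
}

#' Net-benefit curves over a threshold grid
#'
#' Evaluates [net_benefit()] for each strategy at each grid point and adds
#' the two reference strategies: `treat_all` (biopsy everyone:
#' `tp` = all true cases, `fp` = all others) and `treat_none` (never biopsy;
#' identically zero). If a supplied strategy already biopsies everyone
#' (tp + fp = n), `treat_all` coincides with it.
#'
#' @param strategies Strategy-counts tibble (one row per strategy), e.g.
#'   built with [strategy_counts()] or [strategy_counts_from_outcome()];
#'   all rows must share `n`, and `tp + fp = n` must hold for none or more
#'   rows — the references are derived from the first row's `n` and the
#'   cohort prevalence `prevalence` (taken as `max(tp)` when it equals the
#'   full-cohort true-positive count of a treat-all row, otherwise supplied).
#' @param grid Threshold grid from [threshold_grid()].
#' @param prevalence Cohort prevalence of the target condition (fraction of
#'   `n`); needed for the `treat_all` reference when no supplied strategy
#'   biopsies everyone. Defaults to `max(strategies$tp) / n`, which equals
#'   the prevalence whenever a biopsy-all strategy is included.
#' @return An object of class `net_benefit_curve`: list with `thresholds`,
#'   `curves` (long tibble `threshold`, `strategy`, `net_benefit`) and
#'   `strategies` (the counts used, references included).
#' @export
decision_curves <- function(strategies, grid = threshold_grid(),
                            prevalence = NULL) {
  strategies <- tibble::as_tibble(strategies)
  if (nrow(strategies) == 0) {
    rlang::abort("Need at least one strategy.", class = "psadpathways_validation_error")
  }
  if (length(unique(strategies$n)) != 1) {
    rlang::abort("All strategies must share the same n.",
                 class = "psadpathways_validation_error")
  }
  if (any(grid < 0) || any(grid >= 1) || length(grid) == 0) {
    rlang::abort("Threshold grid must be non-empty and lie within [0, 1).",
                 class = "psadpathways_validation_error")
  }
  n <- strategies$n[1]
  if (is.null(prevalence)) prevalence <- max(strategies$tp) / n
  n_pos <- round(prevalence * n)
  refs <- dplyr::bind_rows(
    strategy_counts("treat_all", tp = n_pos, fp = n - n_pos, n = n),
    strategy_counts("treat_none", tp = 0, fp = 0, n = n))
  refs <- refs[!(refs$name %in% strategies$name), ]
  all_strats <- dplyr::bind_rows(strategies, refs)
  curves <- tidyr::crossing(threshold = grid,
                            strategy = factor(all_strats$name,
                                              levels = all_strats$name)) |>
    dplyr::arrange(.data$strategy, .data$threshold)
  idx <- match(as.character(curves$strategy), all_strats$name)
  curves$net_benefit <- net_benefit(all_strats$tp[idx], all_strats$fp[idx],
                                    n, curves$threshold)
  structure(list(thresholds = grid, curves = curves,
                 strategies = all_strats),
            class = "net_benefit_curve")
}

#' @export
print.net_benefit_curve <- function(x, ...) {
  cat(sprintf("<net_benefit_curve> %d strategies on [%g, %g], %d grid points\n",
              nrow(x$strategies), min(x$thresholds), max(x$thresholds),
              length(x$thresholds)))
  print(x$strategies)
  invisible(x)
}

#' Closed-form crossover threshold between two strategies
#'
#' Two net-benefit hyperbolas with counts (TP_a, FP_a) and (TP_b, FP_b)
#' intersect at odds \eqn{p/(1-p) = \Delta TP / \Delta FP}, i.e.
#' \eqn{p_t^* = \Delta TP / (\Delta TP + \Delta FP)}. Returns `NA` when the
#' curves are parallel (equal FP) or the intersection falls outside \[0, 1).
#'
#' @param a,b One-row strategy-counts tibbles.
#' @return Crossover threshold in \[0, 1), or `NA_real_`.
#' @export
crossover_threshold <- function(a, b) {
  dtp <- a$tp - b$tp
  dfp <- a$fp - b$fp
  if (dfp == 0) return(NA_real_)
  p <- dtp / (dtp + dfp)
  if (is.na(p) || p < 0 || p >= 1) NA_real_ else p
}

#' Dominance intervals of a net-benefit curve
#'
#' Finds, at every grid point, the strategy with maximal net benefit, and
#' merges runs into maximal intervals. Pairwise crossovers between adjacent
#' dominating strategies are solved in closed form
#' (\eqn{p_t^* = \Delta TP/(\Delta TP + \Delta FP)}) and reported alongside;
#' ties at a grid point are reported explicitly as comma-joined names.
#'
#' @param curve A `net_benefit_curve`.
#' @param include_references Include `treat_all` / `treat_none` in the
#'   argmax? Default `FALSE`: dominance is usually reported among the
#'   compared pathways, with references as context.
#' @param tie_tol Absolute tolerance for calling a tie at a grid point.
#' @return A list of class `dominance_report`: `intervals` (tibble
#'   `from`, `to`, `strategy`) partitioning the grid range, and `crossovers`
#'   (tibble `strategy_a`, `strategy_b`, `threshold`) with the closed-form
#'   crossings between consecutive dominating strategies.
#' @export
dominance_intervals <- function(curve, include_references = FALSE,
                                tie_tol = 1e-12) {
  stopifnot(inherits(curve, "net_benefit_curve"))
  strats <- curve$strategies
  if (!include_references) {
    keep <- !(strats$name %in% c("treat_all", "treat_none")) |
      duplicated(strats$name)  # keep user strategies that shadow references
    if (sum(keep) >= 2) strats <- strats[keep, ]
  }
  if (nrow(strats) < 2) {
    rlang::abort("Dominance needs at least two strategies.",
                 class = "psadpathways_validation_error")
  }
  grid <- curve$thresholds
  nb <- sapply(seq_len(nrow(strats)), function(i) {
    net_benefit(strats$tp[i], strats$fp[i], strats$n[i], grid)
  })
  if (is.null(dim(nb))) nb <- matrix(nb, nrow = 1)
  best <- apply(nb, 1, function(row) {
    winners <- strats$name[row >= max(row) - tie_tol]
    paste(winners, collapse = ",")
  })
  runs <- rle(best)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  intervals <- tibble::tibble(from = grid[starts], to = grid[ends],
                              strategy = runs$values)
  crossovers <- NULL
  if (length(runs$values) > 1) {
    crossovers <- purrr::map_dfr(seq_len(length(runs$values) - 1), function(i) {
      a <- strsplit(runs$values[i], ",")[[1]][1]
      b <- strsplit(runs$values[i + 1], ",")[[1]][1]
      tibble::tibble(
        strategy_a = a, strategy_b = b,
        threshold = crossover_threshold(strats[strats$name == a, ],
                                        strats[strats$name == b, ]))
    })
  } else {
    crossovers <- tibble::tibble(strategy_a = character(),
                                 strategy_b = character(),
                                 threshold = numeric())
  }
  structure(list(intervals = intervals, crossovers = crossovers,
                 grid_step = if (length(grid) > 1) grid[2] - grid[1] else NA_real_),
            class = "dominance_report")
}

#' @export
print.dominance_report <- function(x, ...) {
  cat("<dominance_report>\n")
  for (i in seq_len(nrow(x$intervals))) {
    cat(sprintf("  [%.3f, %.3f] %s\n", x$intervals$from[i], x$intervals$to[i],
                x$intervals$strategy[i]))
  }
  if (nrow(x$crossovers) > 0) {
    cat("  crossovers:\n")
    for (i in seq_len(nrow(x$crossovers))) {
      cat(sprintf("    %s / %s at p_t = %.4f\n", x$crossovers$strategy_a[i],
                  x$crossovers$strategy_b[i], x$crossovers$threshold[i]))
    }
  }
  invisible(x)
}

#' Export a net-benefit curve as a wide data frame
#'
#' @param curve A `net_benefit_curve`.
#' @return Tibble with a `threshold` column and one column per strategy.
#' @export
curve_to_wide <- function(curve) {
  stopifnot(inherits(curve, "net_benefit_curve"))
  tidyr::pivot_wider(curve$curves, id_cols = "threshold",
                     names_from = "strategy", values_from = "net_benefit")
}

#' Plot net-benefit curves
#'
#' @param curve A `net_benefit_curve`.
#' @param ylim_min Lower clip for the y axis (net benefit below this is
#'   rarely informative). Default -0.05.
#' @return A ggplot object.
#' @export
plot_decision_curves <- function(curve, ylim_min = -0.05) {
  stopifnot(inherits(curve, "net_benefit_curve"))
  ggplot2::ggplot(curve$curves,
                  ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(ylim_min, NA)) +
    ggplot2::labs(x = "Threshold probability",
                  y = "Net benefit", colour = "Strategy") +
    ggplot2::theme_minimal()
}
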