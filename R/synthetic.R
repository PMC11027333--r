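# Calibrated synthetic-cohort generation. The default spec encodes a
# published 2055-patient contingency structure (patient and csPCa counts in
# twelve PI-RADS-group x PSAD-band cells); fixture_cohort() expands it into
# a deterministic patient-level cohort reproducing every cell exactly, and
# sample_cohort() draws stochastic cohorts with the same cell probabilities.

#' Default cohort specification
#'
#' Encodes the calibration targets of the generator: per-cell patient and
#' csPCa counts for the 3 x 4 grid of PI-RADS group (1-2, 3, 4-5) by PSAD
#' band, the PI-RADS score split within the grouped rows, the total count
#' of insignificant cancer (ISUP 1), the ISUP grade-group distribution
#' within significant cancer, and median/IQR parameters for the continuous
#' attributes (age in years, PSA in ng/mL, volume in mL).
#'
#' Totals: N = 2055 patients, 623 csPCa, 196 iPCa.
#'
#' @return A list of class `cohort_spec` with elements `cells` (tibble
#'   `pirads_group`, `band`, `n`, `n_cspca`), `pirads_counts`, `ipca_total`,
#'   `cspca_grade_groups`, `continuous`, and `ipca_constraints` (the
#'   pathway-level iPCa detection totals used by
#'   [solve_ipca_allocation()]).
#' @export
default_cohort_spec <- function() {
  cells <- tibble::tibble(
    pirads_group = rep(c("1-2", "3", "4-5"), each = 4),
    band = rep(psad_band_levels, times = 3),
    n = c(602, 341, 100, 70,
          76, 63, 40, 27,
          112, 172, 129, 323),
    n_cspca = c(7, 9, 9, 9,
                8, 9, 10, 9,
                50, 115, 99, 289))
  structure(list(
    cells = cells,
    pirads_counts = c(`1` = 15, `2` = 1098, `3` = 206, `4` = 238, `5` = 498),
    ipca_total = 196,
    cspca_grade_groups = c(`2` = 339, `3` = 124, `4` = 47, `5` = 113),
    continuous = list(
      age = list(median = 65, iqr = c(59, 69)),
      psa = list(median = 6.31, iqr = c(4.65, 9.12)),
      volume = list(median = 54.7, iqr = c(38, 79)),
      psad = list(median = 0.11, iqr = c(0.08, 0.17))),
    ipca_constraints = list(mri_detected = 150, risk_low_detected = 151,
                            risk_high_detected = 120, total = 196)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> N = %d, csPCa = %d, iPCa = %d\n",
              sum(x$cells$n), sum(x$cells$n_cspca), x$ipca_total))
  print(x$cells, n = nrow(x$cells))
  invisible(x)
}

# Apportion `total` integer units over `weights` by largest remainder
# (Hamilton). Deterministic; ties broken by first index.
largest_remainder <- function(total, weights) {
  if (total == 0) return(rep(0L, length(weights)))
  stopifnot(all(weights >= 0), sum(weights) > 0)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Solve the insignificant-cancer allocation
#'
#' Per-cell iPCa counts are not part of the calibration targets; only four
#' aggregate constraints are: the iPCa detected by the MRI-focused pathway
#' (all iPCa at PI-RADS >= 3), by the risk-based low-threshold pathway, by
#' the risk-based high-threshold pathway, and the cohort total. Over six
#' aggregated strata the system is underdetermined by two degrees of
#' freedom, fixed by the `free` arguments (iPCa among PI-RADS 3 low-band
#' and PI-RADS 3 very-high-band patients; both default 0).
#'
#' Closed form, with `m` = MRI total, `l` = low-threshold total, `h` =
#' high-threshold total, `t` = grand total, `f1` = PI-RADS 3 low, `f2` =
#' PI-RADS 3 very-high:
#' pr45 = h - f2; pr3_mid_high = m - h - f1; pr12_very_high = l - m + f1;
#' pr12_other = t - l - f1.
#'
#' @param spec A `cohort_spec` (capacities are checked against its cells).
#' @param constraints List with `mri_detected`, `risk_low_detected`,
#'   `risk_high_detected`, `total`; defaults to the spec's.
#' @param free List with `pr3_low` and `pr3_very_high`; default both 0.
#' @return Named integer vector over the six strata `pr12_other`,
#'   `pr12_very_high`, `pr3_low`, `pr3_mid_high`, `pr3_very_high`, `pr45`.
#' @export
solve_ipca_allocation <- function(spec = default_cohort_spec(),
                                  constraints = spec$ipca_constraints,
                                  free = list(pr3_low = 0, pr3_very_high = 0)) {
  m <- constraints$mri_detected
  l <- constraints$risk_low_detected
  h <- constraints$risk_high_detected
  t <- constraints$total
  f1 <- free$pr3_low
  f2 <- free$pr3_very_high
  alloc <- c(pr12_other = t - l - f1,
             pr12_very_high = l - m + f1,
             pr3_low = f1,
             pr3_mid_high = m - h - f1,
             pr3_very_high = f2,
             pr45 = h - f2)
  if (any(alloc < 0)) {
    bad <- names(alloc)[alloc < 0][1]
    rlang::abort(sprintf(
      "Infeasible iPCa constraints: stratum `%s` would need %d patients.",
      bad, alloc[[bad]]), class = "psadpathways_validation_error")
  }
  caps <- ipca_stratum_capacities(spec)
  over <- names(alloc)[alloc > caps[names(alloc)]]
  if (length(over) > 0) {
    rlang::abort(sprintf(
      "Infeasible iPCa constraints: stratum `%s` needs %d but only %d non-csPCa patients are available.",
      over[1], alloc[[over[1]]], caps[[over[1]]]),
      class = "psadpathways_validation_error")
  }
  storage.mode(alloc) <- "integer"
  alloc
}

# Non-csPCa capacity of each iPCa stratum.
ipca_stratum_capacities <- function(spec) {
  cells <- spec$cells
  cap <- function(group, bands) {
    sel <- cells$pirads_group %in% group & cells$band %in% bands
    sum(cells$n[sel] - cells$n_cspca[sel])
  }
  c(pr12_other = cap("1-2", c("low", "intermediate", "high")),
    pr12_very_high = cap("1-2", "very_high"),
    pr3_low = cap("3", "low"),
    pr3_mid_high = cap("3", c("intermediate", "high")),
    pr3_very_high = cap("3", "very_high"),
    pr45 = cap("4-5", psad_band_levels))
}

# Spread the six-stratum iPCa allocation over the twelve cells, largest
# remainder proportional to each cell's non-csPCa capacity.
ipca_per_cell <- function(spec, alloc = solve_ipca_allocation(spec)) {
  cells <- spec$cells
  strata <- list(
    pr12_other = which(cells$pirads_group == "1-2" & cells$band != "very_high"),
    pr12_very_high = which(cells$pirads_group == "1-2" & cells$band == "very_high"),
    pr3_low = which(cells$pirads_group == "3" & cells$band == "low"),
    pr3_mid_high = which(cells$pirads_group == "3" &
                           cells$band %in% c("intermediate", "high")),
    pr3_very_high = which(cells$pirads_group == "3" & cells$band == "very_high"),
    pr45 = which(cells$pirads_group == "4-5"))
  ipca <- integer(nrow(cells))
  for (s in names(strata)) {
    idx <- strata[[s]]
    capacity <- cells$n[idx] - cells$n_cspca[idx]
    ipca[idx] <- largest_remainder(alloc[[s]], capacity)
  }
  ipca
}

# ISUP grade groups for csPCa patients, cell by cell. Global grade-group
# totals are spent greedily from the highest-risk cells downwards (higher
# grades concentrate in higher PI-RADS / PSAD cells) — a labelled heuristic,
# not a calibration target.
cspca_grades_per_cell <- function(spec) {
  cells <- spec$cells
  risk_order <- order(match(cells$pirads_group, c("4-5", "3", "1-2")),
                      match(cells$band, rev(psad_band_levels)))
  pool <- rep(as.integer(names(spec$cspca_grade_groups)),
              times = spec$cspca_grade_groups)
  pool <- sort(pool, decreasing = TRUE)  # grade 5 first
  grades <- vector("list", nrow(cells))
  used <- 0
  for (i in risk_order) {
    k <- cells$n_cspca[i]
    grades[[i]] <- pool[seq_len(k) + used]
    used <- used + k
  }
  grades
}

# Run `expr` under a private RNG stream; the caller's RNG state is restored.
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# sdlog such that a lognormal has the given quartiles (ratio-of-IQR fit).
lognormal_sdlog <- function(iqr) (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75))

# Draw n PSAD values strictly inside a band from a truncated lognormal
# matched to the cohort PSAD median/IQR.
draw_psad_in_band <- function(n, band, params) {
  bounds <- switch(band,
                   low = c(0.01, psad_band_breaks[["low"]]),
                   intermediate = c(psad_band_breaks[["low"]],
                                    psad_band_breaks[["intermediate"]]),
                   high = c(psad_band_breaks[["intermediate"]],
                            psad_band_breaks[["high"]]),
                   very_high = c(psad_band_breaks[["high"]], 1.5))
  meanlog <- log(params$median)
  sdlog <- lognormal_sdlog(params$iqr)
  p <- stats::runif(n, stats::plnorm(bounds[1], meanlog, sdlog),
                    stats::plnorm(bounds[2], meanlog, sdlog))
  x <- stats::qlnorm(p, meanlog, sdlog)
  # guard the open interval against floating-point landing on a boundary
  pmin(pmax(x, bounds[1] + 1e-6), bounds[2] - 1e-6)
}

# Attribute generation shared by fixture_cohort and sample_cohort: takes a
# skeleton (pirads, band, status, isup) and fills id, age, psad, volume,
# psa, biopsied, followup and study_date. psad = psa / volume holds exactly
# because psa is derived as psad * volume.
finish_cohort <- function(skeleton, spec) {
  n <- nrow(skeleton)
  cont <- spec$continuous
  age_sd <- diff(cont$age$iqr) / (2 * stats::qnorm(0.75))
  age <- as.integer(pmin(pmax(round(stats::rnorm(n, cont$age$median, age_sd)), 40L), 90L))
  psad <- numeric(n)
  for (b in psad_band_levels) {
    idx <- which(skeleton$band == b)
    if (length(idx) > 0) psad[idx] <- draw_psad_in_band(length(idx), b, cont$psad)
  }
  volume <- round(stats::qlnorm(stats::runif(n, 0.005, 0.995),
                                log(cont$volume$median),
                                lognormal_sdlog(cont$volume$iqr)), 1)
  psa <- psad * volume
  biopsied <- skeleton$pirads >= 3 | skeleton$status != "negative"
  isup <- ifelse(biopsied,
                 ifelse(skeleton$status == "negative", 0L, skeleton$isup),
                 NA_integer_)
  followup <- ifelse(biopsied, NA_real_, round(stats::runif(n, 6, 60), 1))
  study_date <- as.character(
    as.Date("2015-11-01") + floor(stats::runif(n, 0, 2160)))
  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, psa = psa, prostate_volume = volume, psad = psad,
    pirads = as.integer(skeleton$pirads), biopsied = biopsied,
    isup_grade_group = as.integer(isup), followup_months = followup,
    study_date = study_date)
}

# Split the grouped PI-RADS rows into individual scores, matching the
# spec's per-score totals (largest remainder across the four band cells).
# Within a cell, lower scores go to the patients listed last (the
# negatives), so cancers concentrate at higher scores.
split_pirads_scores <- function(cells, spec, cell_sizes) {
  pirads <- integer(sum(cell_sizes))
  offsets <- cumsum(c(0, utils::head(cell_sizes, -1)))
  for (grp in list(c("1-2", 1L, 2L), c("4-5", 4L, 5L))) {
    idx <- which(cells$pirads_group == grp[1])
    lo_total <- spec$pirads_counts[[grp[2]]]
    lo_per_cell <- largest_remainder(lo_total, cell_sizes[idx])
    for (j in seq_along(idx)) {
      i <- idx[j]
      k <- cell_sizes[i]
      lo <- lo_per_cell[j]
      # high score first (cancers are listed first within a cell)
      pirads[offsets[i] + seq_len(k)] <-
        c(rep(as.integer(grp[3]), k - lo), rep(as.integer(grp[2]), lo))
    }
  }
  idx3 <- which(cells$pirads_group == "3")
  for (i in idx3) pirads[offsets[i] + seq_len(cell_sizes[i])] <- 3L
  pirads
}

#' Deterministic fixture cohort
#'
#' Expands a cohort spec into a patient-level cohort that reproduces the
#' spec's contingency structure exactly: every (PI-RADS group, PSAD band)
#' cell contains precisely the specified number of patients and csPCa
#' cases, iPCa follows [solve_ipca_allocation()], ISUP grade groups within
#' csPCa match the spec's totals, and every PSAD value lies strictly inside
#' its band with `psad = psa / prostate_volume` holding exactly. Continuous
#' attributes are seeded random draws; cell membership and disease labels
#' are deterministic regardless of seed.
#'
#' Biopsy status: all PI-RADS 3-5 patients and all PI-RADS 1-2 patients
#' with cancer are biopsied; remaining PI-RADS 1-2 patients are
#' non-biopsied with >= 6 months follow-up (presumed negative).
#'
#' @param spec A `cohort_spec`; default [default_cohort_spec()].
#' @param seed Integer seed for the continuous-attribute draws.
#' @return A validated cohort tibble with a `generation` attribute
#'   (`list(source = "fixture", seed = seed)`).
#' @export
fixture_cohort <- function(spec = default_cohort_spec(), seed = 20230101) {
  cells <- spec$cells
  if (any(cells$n_cspca > cells$n)) {
    rlang::abort("Spec invalid: cell csPCa count exceeds cell size.",
                 class = "psadpathways_validation_error")
  }
  ipca <- ipca_per_cell(spec)
  if (any(cells$n_cspca + ipca > cells$n)) {
    rlang::abort("Spec invalid: cell csPCa + iPCa exceeds cell size.",
                 class = "psadpathways_validation_error")
  }
  grades <- cspca_grades_per_cell(spec)
  # per-cell patient order: csPCa (graded), iPCa, negative
  skeleton <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    k <- cells$n[i]
    status <- c(rep("cspca", cells$n_cspca[i]), rep("ipca", ipca[i]),
                rep("negative", k - cells$n_cspca[i] - ipca[i]))
    isup <- c(grades[[i]], rep(1L, ipca[i]),
              rep(0L, k - cells$n_cspca[i] - ipca[i]))
    tibble::tibble(pirads_group = cells$pirads_group[i], band = cells$band[i],
                   status = status, isup = isup)
  })
  skeleton$pirads <- split_pirads_scores(cells, spec, cells$n)
  cohort <- with_private_seed(seed, finish_cohort(skeleton, spec))
  cohort <- validate_cohort(cohort)
  attr(cohort, "generation") <- list(source = "fixture", seed = seed)
  cohort
}

#' Stochastic cohort sampler
#'
#' Draws `n` patients with cell membership multinomial in the spec's cell
#' proportions, disease status per-cell binomial in the spec's csPCa and
#' iPCa fractions, PI-RADS scores split within grouped rows in the spec's
#' proportions, and continuous attributes as in [fixture_cohort()]. Fully
#' reproducible given `(spec, n, seed)`.
#'
#' @param spec A `cohort_spec`.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return A validated cohort tibble with a `generation` attribute.
#' @export
sample_cohort <- function(spec = default_cohort_spec(), n, seed) {
  stopifnot(n >= 1)
  cells <- spec$cells
  ipca <- ipca_per_cell(spec)
  cohort <- with_private_seed(seed, {
    cell_idx <- sample.int(nrow(cells), n, replace = TRUE,
                           prob = cells$n / sum(cells$n))
    p_cs <- cells$n_cspca[cell_idx] / cells$n[cell_idx]
    p_ip <- ipca[cell_idx] / cells$n[cell_idx]
    u <- stats::runif(n)
    status <- ifelse(u < p_cs, "cspca",
                     ifelse(u < p_cs + p_ip, "ipca", "negative"))
    grp <- cells$pirads_group[cell_idx]
    pc <- spec$pirads_counts
    pirads <- dplyr::case_when(
      grp == "3" ~ 3L,
      grp == "1-2" ~ ifelse(stats::runif(n) < pc[["1"]] / (pc[["1"]] + pc[["2"]]), 1L, 2L),
      TRUE ~ ifelse(stats::runif(n) < pc[["4"]] / (pc[["4"]] + pc[["5"]]), 4L, 5L))
    gg <- as.integer(names(spec$cspca_grade_groups))
    isup <- rep(NA_integer_, n)
    isup[status == "cspca"] <- sample(gg, sum(status == "cspca"), replace = TRUE,
                                      prob = spec$cspca_grade_groups)
    isup[status == "ipca"] <- 1L
    skeleton <- tibble::tibble(pirads_group = grp, band = cells$band[cell_idx],
                               status = status, isup = isup, pirads = pirads)
    finish_cohort(skeleton, spec)
  })
  cohort <- validate_cohort(cohort)
  attr(cohort, "generation") <- list(source = "sample", seed = seed, n = n)
  cohort
}
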