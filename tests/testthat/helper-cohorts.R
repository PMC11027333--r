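# Shared fixtures: the calibrated fixture cohort is expensive enough to
# build once per test run.

the_fixture <- fixture_cohort(default_cohort_spec(), seed = 20230101)
the_builtins <- builtin_pathways()
the_outcomes <- outcome_table(the_fixture, the_builtins)

# Small random-but-valid cohort for property tests.
random_cohort <- function(n, seed) {
  sample_cohort(default_cohort_spec(), n = n, seed = seed)
}

# Brute-force rule-engine oracle: per-patient loop over the pathway's rule
# list, first match wins — independent of pathway_grid().
oracle_decide <- function(pathway, pirads, psad) {
  band <- as.character(assign_psad_band(psad))
  for (r in pathway$rules) {
    if (pirads %in% r$pirads && band %in% r$bands) return(r$decision)
  }
  pathway$default_decision
}

# Closed-form Pearson chi-square on a 2x2 table, independent of
# stats::chisq.test.
oracle_chisq_2x2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
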