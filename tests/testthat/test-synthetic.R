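test_that("default spec encodes the calibration contingency table", {
  spec <- default_cohort_spec()
  expect_equal(sum(spec$cells$n), 2055)
  expect_equal(sum(spec$cells$n_cspca), 623)
  expect_equal(spec$ipca_total, 196)
  cell <- spec$cells[spec$cells$pirads_group == "3" & spec$cells$band == "high", ]
  expect_equal(c(cell$n_cspca, cell$n), c(10, 40))
  expect_equal(sum(spec$pirads_counts), 2055)
  expect_equal(sum(spec$cspca_grade_groups), 623)
})

test_that("iPCa allocation solves the pathway constraints in closed form", {
  alloc <- solve_ipca_allocation()
  expect_equal(unname(alloc), c(45L, 1L, 0L, 30L, 0L, 120L))
  expect_equal(sum(alloc), 196)
  # the three pathway-level iPCa detection totals reproduce
  expect_equal(sum(alloc[c("pr3_low", "pr3_mid_high", "pr3_very_high", "pr45")]),
               150)  # MRI-focused: all PI-RADS >= 3
  expect_equal(sum(alloc[c("pr12_very_high", "pr3_mid_high", "pr3_very_high",
                           "pr45")]), 151)  # risk-based low threshold
  expect_equal(sum(alloc[c("pr3_very_high", "pr45")]), 120)  # high threshold

  spec <- default_cohort_spec()
  expect_error(
    solve_ipca_allocation(spec, constraints = list(
      mri_detected = 150, risk_low_detected = 151,
      risk_high_detected = 120, total = 140)),
    "Infeasible", class = "psadpathways_validation_error")
  zero <- solve_ipca_allocation(spec, constraints = list(
    mri_detected = 0, risk_low_detected = 0, risk_high_detected = 0,
    total = 0))
  expect_equal(unname(zero), rep(0L, 6))
  # capacity violation: more iPCa than non-csPCa patients in a stratum
  expect_error(
    solve_ipca_allocation(spec, constraints = list(
      mri_detected = 150, risk_low_detected = 151,
      risk_high_detected = 120, total = 196),
      free = list(pr3_low = 0, pr3_very_high = 40)),
    class = "psadpathways_validation_error")
})

test_that("fixture cohort is exactly calibrated, independent of seed", {
  for (seed in c(20230101, 7)) {
    fx <- if (seed == 20230101) the_fixture else fixture_cohort(seed = seed)
    xt <- cross_tabulate(fx)
    expect_equal(xt$cells$n,
                 c(602, 341, 100, 70, 76, 63, 40, 27, 112, 172, 129, 323))
    expect_equal(xt$cells$n_cspca,
                 c(7, 9, 9, 9, 8, 9, 10, 9, 50, 115, 99, 289))
    status <- table(disease_status(fx))
    expect_equal(as.integer(status), c(623L, 196L, 1236L))
  }
  # ISUP grade-group totals within csPCa match the spec
  isup <- the_fixture$isup_grade_group
  expect_equal(as.integer(table(isup[!is.na(isup) & isup >= 2])),
               c(339L, 124L, 47L, 113L))
  # PI-RADS score split matches
  expect_equal(as.integer(table(the_fixture$pirads)),
               c(15L, 1098L, 206L, 238L, 498L))
})

test_that("fixture generation is deterministic and band-interior", {
  a <- fixture_cohort(seed = 123)
  b <- fixture_cohort(seed = 123)
  expect_identical(a, b)
  # every PSAD strictly inside its band (no boundary ambiguity)
  expect_true(all(abs(a$psad - 0.10) > 1e-9 & abs(a$psad - 0.15) > 1e-9 &
                    abs(a$psad - 0.20) > 1e-9))
  expect_equal(a$psad, a$psa / a$prostate_volume, tolerance = 1e-12)
  # biopsy pattern: PI-RADS 3-5 all biopsied; PI-RADS 1-2 cancers biopsied,
  # remaining non-biopsied with >= 6 months follow-up
  expect_true(all(a$biopsied[a$pirads >= 3]))
  status <- disease_status(a)
  expect_true(all(a$biopsied[status != "negative"]))
  nb <- !a$biopsied
  expect_true(all(a$pirads[nb] <= 2))
  expect_true(all(a$followup_months[nb] >= 6))
})

test_that("stochastic sampler is reproducible and valid at the margins", {
  s1 <- sample_cohort(n = 500, seed = 11)
  s2 <- sample_cohort(n = 500, seed = 11)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_cohort(n = 500, seed = 12)))
  one <- sample_cohort(n = 1, seed = 4)
  expect_equal(nrow(one), 1)
  expect_s3_class(validate_cohort(one), "tbl_df")
})

test_that("sampler cell fractions concentrate around the spec proportions", {
  spec <- default_cohort_spec()
  p <- spec$cells$n / sum(spec$cells$n)
  n <- 2055
  counts <- matrix(0, nrow = 20, ncol = 12)
  for (s in 1:20) {
    co <- sample_cohort(spec, n = n, seed = 5000 + s)
    xt <- cross_tabulate(co)
    counts[s, ] <- xt$cells$n
  }
  mean_frac <- colMeans(counts) / n
  se <- sqrt(p * (1 - p) / (n * 20))
  expect_true(mean(abs(mean_frac - p) <= 3 * se) >= 0.95)
})

test_that("pipeline on large samples recovers spec prevalences within Monte-Carlo error", {
  spec <- default_cohort_spec()
  co <- sample_cohort(spec, n = 20000, seed = 77)
  xt <- cross_tabulate(co)
  prev_hat <- xt$n_cspca_total / xt$n_total
  prev <- sum(spec$cells$n_cspca) / sum(spec$cells$n)
  expect_lt(abs(prev_hat - prev), 3 * sqrt(prev * (1 - prev) / 20000))
  ot <- outcome_table(co, the_builtins)
  expect_equal(ot$rate_n_avoided[3], 1119 / 2055, tolerance = 0.05)
  expect_equal(ot$rate_cspca_detected[4], 562 / 2055, tolerance = 0.1)
})
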