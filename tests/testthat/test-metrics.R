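test_that("fixture cross-tabulation reproduces every published cell", {
  xt <- cross_tabulate(the_fixture)
  expect_equal(xt$cells$n,
               c(602, 341, 100, 70, 76, 63, 40, 27, 112, 172, 129, 323))
  expect_equal(xt$cells$n_cspca,
               c(7, 9, 9, 9, 8, 9, 10, 9, 50, 115, 99, 289))
  expect_equal(xt$n_total, 2055)
  expect_equal(xt$n_cspca_total, 623)
  expect_equal(crosstab_cell(xt, "3", "low")$prevalence, 8 / 76)
  expect_equal(crosstab_cell(xt, "4-5", "very_high")$prevalence, 289 / 323)
  # margins equal cell sums
  expect_equal(sum(xt$row_margins$n), xt$n_total)
  expect_equal(xt$row_margins$n_cspca, c(34, 36, 553))
  expect_equal(xt$col_margins$n, c(790, 576, 269, 420))
})

test_that("cross-tab margins and totals are consistent on random cohorts", {
  for (seed in 1:3) {
    co <- random_cohort(300, seed = seed)
    xt <- cross_tabulate(co)
    expect_equal(sum(xt$cells$n), nrow(co))
    expect_equal(sum(xt$cells$n_cspca), sum(disease_status(co) == "cspca"))
    expect_true(all(xt$cells$n_cspca <= xt$cells$n))
    expect_equal(xt$row_margins$n,
                 tapply(xt$cells$n, xt$cells$pirads_group, sum) |> unname() |> as.integer())
  }
})

test_that("cross-tab over a partition of the cohort sums cell-wise to the whole", {
  co <- random_cohort(400, seed = 21)
  half <- seq_len(200)
  a <- cross_tabulate(co[half, ])
  b <- cross_tabulate(co[-half, ])
  whole <- cross_tabulate(co)
  expect_equal(a$cells$n + b$cells$n, whole$cells$n)
  expect_equal(a$cells$n_cspca + b$cells$n_cspca, whole$cells$n_cspca)
})

test_that("single-patient cohort cross-tabulates to one occupied cell", {
  co <- random_cohort(1, seed = 3)
  xt <- cross_tabulate(co)
  expect_equal(sum(xt$cells$n), 1)
  expect_equal(xt$n_total, 1)
})

test_that("fixture outcome table matches the published pathway outcomes", {
  ot <- the_outcomes
  expect_equal(ot$pathway, c("biopsy_all", "mri_focused", "risk_low", "risk_high"))
  expect_equal(ot$n_avoided, c(0L, 1113L, 1119L, 1292L))
  expect_equal(ot$cspca_detected, c(623L, 589L, 590L, 562L))
  expect_equal(ot$cspca_missed, c(0L, 34L, 33L, 61L))
  expect_equal(ot$ipca_detected, c(196L, 150L, 151L, 120L))
  expect_equal(ot$ipca_avoided, c(0L, 46L, 45L, 76L))
  # the published "negative biopsy" column: benign-only for biopsy-all,
  # biopsied-without-csPCa for the selective pathways
  expect_equal(ot$negative_biopsies[1], 1236L)
  expect_equal(ot$fp_non_cspca, c(1432L, 353L, 346L, 201L))
  expect_equal(ot$rate_n_avoided, c(0, 1113, 1119, 1292) / 2055)
  expect_equal(ot$rate_cspca_missed[3], 33 / 2055)
})

test_that("outcome conservation identities hold on random cohort-pathway pairs", {
  for (seed in 1:4) {
    co <- random_cohort(350, seed = seed)
    status <- disease_status(co)
    for (p in the_builtins) {
      s <- pathway_outcomes(co, apply_pathway(p, co))
      expect_equal(s$n_biopsied + s$n_avoided, s$n_total)
      expect_equal(s$cspca_detected + s$cspca_missed, sum(status == "cspca"))
      expect_equal(s$ipca_detected + s$ipca_avoided, sum(status == "ipca"))
      expect_equal(s$fp_non_cspca, s$ipca_detected + s$negative_biopsies)
      expect_equal(s$n_biopsied,
                   s$cspca_detected + s$ipca_detected + s$negative_biopsies)
    }
  }
})

test_that("nested biopsied sets give monotone detection and avoidance", {
  for (seed in 1:3) {
    co <- random_cohort(300, seed = seed + 100)
    ot <- outcome_table(co, the_builtins)
    # risk_high subset risk_low subset biopsy_all
    ord <- match(c("risk_high", "risk_low", "biopsy_all"), ot$pathway)
    expect_true(all(diff(ot$cspca_detected[ord]) >= 0))
    expect_true(all(diff(ot$n_avoided[ord]) <= 0))
  }
})

test_that("outcome_table validates inputs and preserves order", {
  expect_error(outcome_table(the_fixture, list()),
               class = "psadpathways_validation_error")
  dup <- outcome_table(random_cohort(50, seed = 2),
                       list(the_builtins$risk_low, the_builtins$risk_low))
  expect_equal(dup[1, ], dup[2, ])
  co <- random_cohort(20, seed = 2)
  dec <- apply_pathway(the_builtins$risk_low, co)
  expect_error(pathway_outcomes(co, dec[-1, ]),
               class = "psadpathways_validation_error")
})

test_that("Pearson chi-square agrees with the closed-form oracle", {
  res <- compare_chi_square(the_outcomes[1, ], the_outcomes[3, ],
                            metric = "cspca_detected")
  expect_equal(res$statistic, 1.27368, tolerance = 1e-4)
  expect_equal(res$p_value, 0.2591, tolerance = 1e-3)
  expect_equal(res$df, 1L)

  withr::with_seed(99, {
    for (i in 1:100) {
      tab <- matrix(stats::rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1,
                    nrow = 2)
      got <- chi_square_2x2(tab)
      want <- oracle_chisq_2x2(tab)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
    }
  })
})

test_that("chi-square degenerate and error cases", {
  same <- compare_chi_square(the_outcomes[2, ], the_outcomes[2, ],
                             metric = "cspca_detected")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(chi_square_2x2(rbind(c(0, 10), c(0, 10))), "zero margin",
               class = "psadpathways_validation_error")
  a <- the_outcomes[1, ]; b <- the_outcomes[2, ]; b$n_total <- 99L
  expect_error(compare_chi_square(a, b, metric = "cspca_detected"),
               class = "psadpathways_validation_error")
})
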