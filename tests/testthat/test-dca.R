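test_that("net benefit evaluates the TP/FP odds-weighted formula", {
  # biopsy-all counts: at p_t = 0 net benefit is the prevalence
  expect_equal(net_benefit(tp = 623, fp = 1432, n = 2055, p_t = 0), 623 / 2055)
  # MRI-focused counts at p_t = 0.10, direct arithmetic oracle
  expect_equal(net_benefit(tp = 589, fp = 353, n = 2055, p_t = 0.10),
               589 / 2055 - (353 / 2055) * (0.10 / 0.90))
  expect_equal(net_benefit(589, 353, 2055, 0.10), 0.26753, tolerance = 1e-4)
  # treat-none is identically zero
  expect_equal(net_benefit(0, 0, 2055, c(0, 0.3, 0.9)), c(0, 0, 0))
  expect_error(net_benefit(10, 5, 100, 1.0),
               class = "psadpathways_validation_error")
})

test_that("net benefit is strictly decreasing in p_t when fp > 0", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- 500
      tp <- sample.int(200, 1)
      fp <- sample.int(250, 1)
      grid <- sort(stats::runif(50, 0, 0.95))
      nb <- net_benefit(tp, fp, n, grid)
      expect_true(all(diff(nb) < 0))
    }
  })
})

test_that("treat-all matches its prevalence closed form", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- 1000
      prev <- stats::runif(1, 0.05, 0.8)
      tp <- round(prev * n)
      grid <- seq(0, 0.9, by = 0.05)
      expect_equal(net_benefit(tp, n - tp, n, grid),
                   tp / n - (1 - tp / n) * grid / (1 - grid))
    }
  })
})

test_that("strategy counts derive from outcomes under both FP conventions", {
  s <- strategy_counts_from_outcome(the_outcomes[3, ])  # risk_low
  expect_equal(c(s$tp, s$fp), c(590, 346))
  s <- strategy_counts_from_outcome(the_outcomes[1, ])  # biopsy_all
  expect_equal(c(s$tp, s$fp), c(623, 2055 - 623))
  s <- strategy_counts_from_outcome(the_outcomes[2, ], "benign_only")
  expect_equal(c(s$tp, s$fp), c(589, 942 - 589 - 150))
  expect_error(strategy_counts_from_outcome(the_outcomes[1, ], "bogus"))
  none <- strategy_counts("treat_none", tp = 0, fp = 0, n = 2055)
  expect_equal(net_benefit(none$tp, none$fp, none$n, 0.3), 0)
})

test_that("decision curves evaluate pointwise and carry references", {
  strategies <- purrr::map_dfr(seq_len(nrow(the_outcomes)), function(i) {
    strategy_counts_from_outcome(the_outcomes[i, ])
  })
  cv <- decision_curves(strategies)
  wide <- curve_to_wide(cv)
  # treat-none reference identically zero; treat_all coincides with biopsy_all
  expect_true(all(wide$treat_none == 0))
  expect_equal(wide$treat_all, wide$biopsy_all)
  # single-strategy curve equals pointwise net_benefit
  one <- decision_curves(strategies[2, ], grid = c(0, 0.1, 0.2))
  got <- one$curves[one$curves$strategy == "mri_focused", ]
  expect_equal(got$net_benefit,
               net_benefit(589, 353, 2055, c(0, 0.1, 0.2)))
  # at p_t = 0 every curve equals TP/N
  at0 <- cv$curves[cv$curves$threshold == 0, ]
  expect_equal(at0$net_benefit[match(cv$strategies$name, at0$strategy)],
               cv$strategies$tp / cv$strategies$n)
  # biopsy-all is maximal among pathways at the smallest positive threshold
  row <- wide[wide$threshold == 0.001, c("biopsy_all", "mri_focused",
                                         "risk_low", "risk_high")]
  expect_equal(names(row)[which.max(unlist(row))], "biopsy_all")
  expect_error(decision_curves(strategies, grid = numeric()),
               class = "psadpathways_validation_error")
  expect_error(decision_curves(strategies, grid = c(0.5, 1.0)),
               class = "psadpathways_validation_error")
  expect_error(decision_curves(strategies[0, ]),
               class = "psadpathways_validation_error")
})

test_that("dominance intervals partition the grid and match closed-form crossovers", {
  strategies <- purrr::map_dfr(seq_len(nrow(the_outcomes)), function(i) {
    strategy_counts_from_outcome(the_outcomes[i, ])
  })
  cv <- decision_curves(strategies)
  dom <- dominance_intervals(cv)
  expect_equal(dom$intervals$from[1], min(cv$thresholds))
  expect_equal(dom$intervals$to[nrow(dom$intervals)], max(cv$thresholds))
  expect_true(all(dom$intervals$from[-1] >
                    dom$intervals$to[-nrow(dom$intervals)]))
  expect_equal(dom$intervals$strategy,
               c("biopsy_all", "risk_low", "risk_high"))
  # closed-form crossover biopsy-all / risk-low is Delta TP / (Delta TP + Delta FP)
  expect_equal(dom$crossovers$threshold[1], 33 / 1119)
  expect_equal(dom$crossovers$threshold[2], 28 / (28 + 145))
  # crossovers agree with the grid argmax switch points within one step
  for (i in seq_len(nrow(dom$crossovers))) {
    expect_lte(abs(dom$crossovers$threshold[i] - dom$intervals$to[i]),
               dom$grid_step + 1e-12)
  }
})

test_that("crossovers match grid argmax within one step on random strategy sets", {
  withr::with_seed(53, {
    for (rep in 1:15) {
      n <- 1000
      k <- 3
      tp <- sort(sample.int(400, k))
      fp <- sort(sample.int(550, k))  # sorted with tp: higher tp, higher fp
      strategies <- tibble::tibble(name = paste0("s", 1:k), n = n,
                                   tp = tp, fp = fp)
      cv <- decision_curves(strategies, grid = threshold_grid(0, 0.8, 0.001))
      dom <- dominance_intervals(cv)
      for (i in seq_len(nrow(dom$crossovers))) {
        a <- strategies[strategies$name == dom$crossovers$strategy_a[i], ]
        b <- strategies[strategies$name == dom$crossovers$strategy_b[i], ]
        closed <- crossover_threshold(a, b)
        if (!is.na(closed) && closed <= 0.8) {
          expect_lte(abs(closed - dom$intervals$to[i]), 0.001 + 1e-12)
        }
      }
    }
  })
})

test_that("identical strategies tie across the whole grid", {
  strategies <- tibble::tibble(name = c("a", "b"), n = 1000,
                               tp = c(200, 200), fp = c(300, 300))
  cv <- decision_curves(strategies, grid = threshold_grid(0, 0.5, 0.01))
  dom <- dominance_intervals(cv)
  expect_equal(nrow(dom$intervals), 1)
  expect_equal(dom$intervals$strategy, "a,b")
})
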