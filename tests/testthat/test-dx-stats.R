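test_that("confusion_table counts cells and reports skipped records", {
  co <- make_cohort(b_type = c("B1", "B2", "B2", "B3"),
                    depth = c("EP", "SM2", "MM", "SM3"),
                    suv_max = c(0, 5, NA, NA))
  tab <- confusion_table(add_np_risk(co), np_risk == "high",
                         is_deep(depth))
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 2, fp = 0, fn = 0, tn = 1))
  skipped <- attr(tab, "skipped")
  expect_equal(nrow(skipped), 1)
  expect_equal(skipped$lesion_id, "L003")

  empty <- confusion_table(co[0, ], b_type == "B3", is_deep(depth))
  expect_equal(unlist(unclass(empty)), c(tp = 0, fp = 0, fn = 0, tn = 0))

  ident <- confusion_table(co, is_deep(depth), is_deep(depth))
  expect_equal(ident$fp + ident$fn, 0)
})

test_that("diagnostic metrics reproduce the published 2x2 summaries", {
  np <- dx_metrics(contingency_2x2(tp = 44, fp = 9, fn = 9, tn = 75))
  expect_equal(np$pct, c(83.0, 89.3, 83.0, 89.3, 86.9))
  b3 <- dx_metrics(contingency_2x2(tp = 22, fp = 2, fn = 31, tn = 82))
  expect_equal(b3$pct, c(41.5, 97.6, 91.7, 72.6, 75.9))
  perfect <- dx_metrics(contingency_2x2(1, 0, 0, 1))
  expect_equal(perfect$estimate, rep(1, 5))
})

test_that("metrics with zero denominators are undefined, not zero", {
  no_pos <- dx_metrics(contingency_2x2(0, 3, 0, 7))
  expect_true(is.na(no_pos$estimate[no_pos$metric == "sensitivity"]))
  expect_false(is.na(no_pos$estimate[no_pos$metric == "specificity"]))
  all_zero <- dx_metrics(contingency_2x2(0, 0, 0, 0))
  expect_true(all(is.na(all_zero$estimate)))
})

test_that("metrics satisfy the Bayes and accuracy identities on random tables", {
  set.seed(601)
  for (i in 1:100) {
    cells <- as.list(rpois(4, 8) + 1)
    m <- dx_metrics(contingency_2x2(cells[[1]], cells[[2]], cells[[3]],
                                    cells[[4]]))
    est <- setNames(m$estimate, m$metric)
    n <- sum(unlist(cells))
    prev <- (cells[[1]] + cells[[3]]) / n
    expect_equal(
      est["ppv"],
      unname(prev * est["sensitivity"] /
               (prev * est["sensitivity"] +
                  (1 - prev) * (1 - est["specificity"]))),
      tolerance = 1e-12, ignore_attr = TRUE
    )
    expect_equal(est[["accuracy"]],
                 prev * est[["sensitivity"]] +
                   (1 - prev) * est[["specificity"]],
                 tolerance = 1e-12)
    # exact binomial CI brackets the estimate
    expect_true(all(m$conf.low <= m$estimate & m$estimate <= m$conf.high))
  }
})

table1_counts <- matrix(
  c(49, 8, 0, 6, 19, 2, 1, 30, 22), nrow = 3,
  dimnames = list(c("B1", "B2", "B3"),
                  c("EP_LPM", "MM_SM1", "SM2_SM3"))
)

test_that("one-vs-rest collapse reproduces the per-class rows of the JES table", {
  b1 <- one_vs_rest_metrics(table1_counts, "B1", "EP_LPM")
  expect_equal(b1$pct[b1$metric == "accuracy"], 89.1)
  b2 <- one_vs_rest_metrics(table1_counts, "B2", "MM_SM1")
  expect_equal(b2$pct[b2$metric == "ppv"], 33.3)
  expect_equal(b2$pct[b2$metric == "accuracy"], 66.4)
  # each call uses every lesion exactly once
  for (b in rownames(table1_counts)) {
    m <- one_vs_rest_metrics(table1_counts, b, "SM2_SM3")
    expect_equal(m$denominator[m$metric == "accuracy"],
                 sum(table1_counts))
  }
  # degenerate: all mass in the target cell of the positive row -- every
  # defined metric is 1, the zero-denominator ones are undefined
  pure <- matrix(0, 3, 3)
  pure[3, 3] <- 10
  m <- one_vs_rest_metrics(pure, "B3", "SM2_SM3")
  expect_equal(m$estimate[m$metric %in% c("sensitivity", "ppv", "accuracy")],
               rep(1, 3))
  expect_true(all(is.na(
    m$estimate[m$metric %in% c("specificity", "npv")]
  )))
})

test_that("jes_performance matches one_vs_rest_metrics on the raw cohort", {
  co <- reconstructed_cohort()
  expect_equal(jes_table(co), table1_counts, ignore_attr = TRUE)
  perf <- jes_performance(co)
  b3 <- perf[perf$b_type == "B3", ]
  expect_equal(b3$pct, c(41.5, 97.6, 91.7, 72.6, 75.9))
})

test_that("Fisher p matches enumeration, conventions and symmetries", {
  expect_lt(fisher_exact(contingency_2x2(44, 9, 9, 75)), 0.001)
  expect_equal(fisher_exact(contingency_2x2(3, 1, 1, 3)), 34 / 70)
  expect_equal(fisher_exact(contingency_2x2(0, 0, 5, 7)), 1.0)
  set.seed(602)
  for (i in 1:50) {
    cells <- rpois(4, 5)
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    p <- fisher_exact(tab)
    expect_equal(p, fisher_enum_oracle(cells[1], cells[2], cells[3],
                                       cells[4]),
                 tolerance = 1e-10)
    # transposition and simultaneous row/column swap leave p unchanged
    expect_equal(p, fisher_exact(t(as.matrix(tab))), tolerance = 1e-12)
    expect_equal(p, fisher_exact(contingency_2x2(cells[4], cells[3],
                                                 cells[2], cells[1])),
                 tolerance = 1e-12)
  }
})

test_that("odds ratio uses the cross-product with Wald interval and zero-cell correction", {
  or <- odds_ratio(contingency_2x2(44, 9, 9, 75))
  expect_equal(or$estimate, 3300 / 81, tolerance = 1e-12)
  expect_false(or$corrected)
  expect_true(or$conf.low <= or$estimate & or$estimate <= or$conf.high)

  expect_equal(odds_ratio(contingency_2x2(1, 1, 1, 1))$estimate, 1.0)

  z <- odds_ratio(contingency_2x2(2, 0, 1, 3))
  expect_true(z$corrected)
  expect_equal(z$estimate, (2.5 * 3.5) / (0.5 * 1.5), tolerance = 1e-12)
})

test_that("rank-sum comparison is exact for small samples including ties", {
  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)
  expect_equal(same$method, "exact enumeration")

  sep <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(sep$p_value, 1 / 3)

  # complement identity U(a,b) + U(b,a) = n_a * n_b
  set.seed(603)
  for (i in 1:20) {
    a <- round(rexp(sample(2:8, 1)), 1)
    b <- round(rexp(sample(2:8, 1)), 1)
    expect_equal(rank_sum_compare(a, b)$u + rank_sum_compare(b, a)$u,
                 length(a) * length(b))
  }
})

test_that("rank-sum agrees with wilcox.test where both are exact or approximate", {
  set.seed(604)
  for (i in 1:10) {
    a <- rnorm(7)
    b <- rnorm(6) + 0.5 # continuous: no ties
    expect_equal(rank_sum_compare(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  a <- round(rlnorm(40, 1, 0.6), 1)
  b <- round(rlnorm(35, 0.6, 0.6), 1) # ties after rounding
  rs <- rank_sum_compare(a, b)
  expect_equal(rs$method, "normal approximation with tie correction")
  expect_equal(rs$p_value,
               wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("rank-sum summaries report median and quartiles per group", {
  rs <- rank_sum_compare(c(0, 0, 0, 3.2, 5), c(0, 0, 1))
  expect_equal(rs$summary$median, c(0, 0))
  expect_equal(rs$summary$n, c(5, 3))
  expect_error(rank_sum_compare(numeric(0), 1), "non-empty")
})
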