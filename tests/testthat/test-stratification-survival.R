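# TP53 status, strata, crosstab, Kaplan-Meier and log-rank from first
# principles, plus the two-sample score comparisons.

test_that("TP53 status and null flag follow the variant-class contract", {
  mut <- data.frame(sample_id = c("S1", "S2", "S4", "S4"),
                    gene = c("TP53", "TP53", "TP53", "CTNNB1"),
                    variant_class = c("missense", "truncating", "splice",
                                      "missense"))
  st <- assign_tp53_status(mut, c("S1", "S2", "S3", "S4"))
  expect_identical(st$tp53_status, c("mutant", "mutant", "wild_type",
                                     "mutant"))
  expect_identical(st$tp53_null, c(FALSE, TRUE, FALSE, TRUE))
  # null definition is parametric
  st2 <- assign_tp53_status(mut, c("S1", "S2"),
                            null_definition = "missense")
  expect_identical(st2$tp53_null, c(TRUE, FALSE))
  expect_error(assign_tp53_status(mut, "S1", null_definition = "nonsense"),
               "unknown variant class")
})

test_that("stratification forms the four-way product and reports exclusions", {
  status <- data.frame(sample_id = c("A", "B", "C", "D", "E"),
                       tp53_status = c("mutant", "mutant", "wild_type",
                                       "wild_type", "mutant"),
                       tp53_null = FALSE, variant_classes = "")
  calls <- data.frame(sample_id = c("A", "B", "C", "D", "F"),
                      score = c(2, -1, 3, 0, 1),
                      met_class = c("high", "low", "high", "low", "high"))
  strata <- stratify(status, calls)
  expect_identical(sort(strata$stratum),
                   c("mut_high", "mut_low", "wt_high", "wt_low"))
  expect_identical(attr(strata, "excluded")$status_only, "E")
  expect_identical(attr(strata, "excluded")$calls_only, "F")
  expect_error(stratify(status[1:2, ], calls[3:4, ]), "no samples")
})

test_that("crosstab counts, proportions and odds ratio reconcile", {
  status <- data.frame(sample_id = sprintf("S%02d", 1:20),
                       tp53_status = rep(c("mutant", "wild_type"), c(8, 12)),
                       tp53_null = FALSE, variant_classes = "")
  calls <- data.frame(sample_id = sprintf("S%02d", 1:20),
                      score = 0,
                      met_class = rep(c("high", "low", "high", "low"),
                                      c(6, 2, 5, 7)))
  xt <- crosstab(stratify(status, calls))
  expect_equal(as.vector(xt$counts), c(6, 5, 2, 7))
  expect_equal(sum(xt$counts), 20)
  expect_equal(rowSums(xt$counts), c(mutant = 8, wild_type = 12))
  expect_equal(xt$row_proportions["mutant", "high"], 6 / 8)
  expect_equal(xt$odds_ratio, (6 * 7) / (2 * 5))
  expect_false(xt$haldane_corrected)

  # zero cell: Haldane correction flagged
  xt0 <- crosstab(matrix(c(5, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_true(xt0$haldane_corrected)
  expect_equal(xt0$odds_ratio, (5.5 * 4.5) / (0.5 * 3.5))
})

test_that("KM product-limit estimate matches hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  km2 <- km_estimate(c(1, 2, 3), c(0, 1, 1))
  expect_equal(km2$survival[km2$time == 2], 1 / 2)
  expect_equal(km2$survival[km2$time == 3], 0)

  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km3$survival, rep(1, 3))

  expect_error(km_estimate(numeric(0), integer(0)), "empty")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(5)
  for (i in 1:10) {
    t <- rexp(sample(5:30, 1))
    km <- km_estimate(t, rep(1, length(t)))
    emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$survival, emp, tolerance = 1e-12)
  }
})

test_that("KM agrees with survival::survfit on censored data", {
  skip_if_not_installed("survival")
  set.seed(8)
  t <- round(rexp(40, 0.2), 2)
  e <- rbinom(40, 1, 0.6)
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km$survival, summary(sf, times = km$time)$surv,
               tolerance = 1e-12)
})

test_that("log-rank matches the hand-tabulated Mantel-Haenszel value", {
  # group A: times (1, 2), both events; group B: (3, 4), both events.
  # Per event time 2x2 tables give O_A = 2, E_A = 1/2 + 1/3 = 5/6,
  # V = 1/4 + 2/9 = 17/36, chi-square = (7/6)^2 / (17/36) = 49/17.
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)
  expect_equal(lr$df, 1L)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)

  # identical groups: statistic 0, p 1
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6),
                      rep(c("A", "B"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  expect_error(logrank_test(1:4, rep(0, 4), rep(c("A", "B"), 2)),
               "at least one event")
  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)),
               "at least 2 groups")
})

test_that("log-rank conserves events and is rank-invariant", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    t <- rexp(n, 0.3) + 0.01
    e <- rbinom(n, 1, 0.7)
    g <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (sum(e) == 0 || length(unique(g)) < 2) next
    lr <- logrank_test(t, e, g)
    expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)
    # monotone time transform leaves the rank-based statistic unchanged
    lr_sq <- logrank_test(t^2, e, g)
    expect_equal(lr$statistic, lr_sq$statistic, tolerance = 1e-9)
  }
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (k in c(2, 3)) {
    for (i in 1:5) {
      n <- 12 * k
      g <- rep(LETTERS[1:k], each = 12)
      t <- rexp(n, rate = rep(seq(0.2, 0.6, length.out = k), each = 12))
      e <- rbinom(n, 1, 0.8)
      if (sum(e) == 0) next
      lr <- logrank_test(t, e, g)
      sd <- survival::survdiff(survival::Surv(t, e) ~ g)
      expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
      expect_equal(unname(lr$observed), unname(sd$obs), tolerance = 1e-9)
      expect_equal(unname(lr$expected), unname(sd$exp), tolerance = 1e-9)
    }
  }
})

test_that("score comparisons match textbook-formula oracles to 1e-9", {
  set.seed(99)
  a <- rnorm(10, 1); b <- rnorm(10)
  st <- compare_scores(a, b, "student")
  os <- oracle_student(a, b)
  expect_equal(st$statistic, os$statistic, tolerance = 1e-9)
  expect_equal(st$p_value, os$p, tolerance = 1e-9)

  we <- compare_scores(a, b, "welch")
  ow <- oracle_welch(a, b)
  expect_equal(we$statistic, ow$statistic, tolerance = 1e-9)
  expect_equal(we$p_value, ow$p, tolerance = 1e-9)

  mw <- compare_scores(a, b, "mann_whitney")
  om <- oracle_mann_whitney(a, b)
  expect_equal(mw$statistic, om$statistic, tolerance = 1e-9)
  expect_equal(mw$p_value, om$p, tolerance = 1e-9)
})

test_that("score comparison edge contracts hold", {
  a <- c(1, 2, 3, 4)
  st <- compare_scores(a, a, "student")
  expect_equal(st$statistic, 0)
  expect_equal(st$p_value, 1)
  # large shift at n = 50: decisive at any conventional alpha
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50) + 100
  expect_lt(compare_scores(x, y, "student")$p_value, 1e-10)
  expect_error(compare_scores(c(1, 1), c(1, 1), "student"), "mann_whitney")
  expect_error(compare_scores(1, c(1, 2), "welch"), "at least 2")
})
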