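test_that("Welch test matches the independent formula evaluation", {
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  got <- welch_t_test(a, b)
  exp <- welch_oracle(a, b)
  expect_equal(got$t, exp$t, tolerance = 1e-9)
  expect_equal(got$df, exp$df, tolerance = 1e-9)
  expect_equal(got$p, exp$p, tolerance = 1e-9)
  set.seed(3)
  for (rep in 1:10) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), sd = 2)
    g <- welch_t_test(x, y); o <- welch_oracle(x, y)
    expect_equal(g$p, o$p, tolerance = 1e-9)
  }
})

test_that("Welch test handles identical and degenerate groups", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(welch_t_test(c(2, 2), c(2, 2)), list(t = 0, df = Inf, p = 1))
  deg <- welch_t_test(c(3, 3), c(1, 1))
  expect_identical(deg$p, 0)
  expect_true(is.infinite(deg$t) && deg$t > 0)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("Welch p is invariant under group swap, t changes sign", {
  x <- c(0.1, 0.4, 0.3); y <- c(0.9, 1.4, 1.1, 1.0)
  ab <- welch_t_test(x, y); ba <- welch_t_test(y, x)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$t, -ba$t)
})

test_that("AUROC equals the pairwise concordance oracle exactly", {
  perfect <- roc_auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_identical(perfect$auroc, 1)
  inv <- roc_auroc(c(1, 2, 3, 10, 11), c(1, 1, 1, 0, 0))
  expect_identical(inv$auroc, 0)
  set.seed(0)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    sc <- round(runif(n), 2)  # rounding forces ties
    lb <- runif(n) < 0.5
    if (!any(lb) || all(lb)) next
    r <- roc_auroc(sc, lb)
    expect_identical(r$auroc, brute_auroc(sc, lb))
    expect_gte(r$auroc, 0); expect_lte(r$auroc, 1)
    # label inversion symmetry
    expect_equal(roc_auroc(sc, !lb)$auroc, 1 - r$auroc, tolerance = 1e-12)
  }
  expect_error(roc_auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  sc <- rnorm(40)
  lb <- runif(40) < 0.4
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lb, sc, direction = "<",
                                                         quiet = TRUE))))
  expect_equal(roc_auroc(sc, lb)$auroc, ref, tolerance = 1e-12)
})

test_that("ROC points trace sensitivity/specificity at inclusive thresholds", {
  r <- roc_auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  at3 <- r$points[r$points$threshold == 3, ]
  expect_equal(at3$sensitivity, 1)
  expect_equal(at3$specificity, 1)
})

test_that("operating-point selection follows the constraint-then-maximize rule", {
  r <- roc_auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  op <- select_thresholds(r, 0.9)
  expect_equal(op$sensitivity_first$threshold, 3)
  expect_equal(op$sensitivity_first$sensitivity, 1)
  expect_equal(op$sensitivity_first$specificity, 1)
  expect_true(op$sensitivity_first$attained)
  expect_equal(op$specificity_first$threshold, 3)
  # operating points must lie on the ROC curve
  expect_true(any(r$points$threshold == op$sensitivity_first$threshold &
                  r$points$sensitivity == op$sensitivity_first$sensitivity))
})

test_that("unattainable operating points are flagged, not fabricated", {
  # all positives scored below all negatives
  r <- roc_auroc(c(1, 2, 9, 10), c(TRUE, TRUE, FALSE, FALSE))
  op <- select_thresholds(r, 0.9)
  expect_false(op$sensitivity_first$attained && op$specificity_first$attained)
})

test_that("three-group comparison applies the Bonferroni-corrected level", {
  set.seed(1)
  tab <- cohort_table(sprintf("c%02d", 1:30),
                      c(rnorm(10, 0.08, 0.002), rnorm(10, 0.03, 0.002),
                        abs(rnorm(10, 0.007, 0.002))),
                      mpdd = rep(c(TRUE, TRUE, FALSE), each = 10),
                      ppa = rep(c(TRUE, FALSE, FALSE), each = 10))
  tg <- three_group_comparison(tab)
  expect_identical(nrow(tg), 3L)
  expect_equal(attr(tg, "corrected_alpha"), 0.05 / 3)
  expect_equal(attr(tg, "printed_alpha"), 0.016)
  expect_true(all(tg$significant))  # well-separated synthetic effect sizes
  expect_true(all(tg$significant == (tg$p < 0.05 / 3)))
})

test_that("identical groups are never significant; 0.02 fails the 0.016 level", {
  tab <- cohort_table(sprintf("c%02d", 1:9), rep(c(1, 2, 3), 3),
                      mpdd = rep(c(TRUE, TRUE, FALSE), each = 3),
                      ppa = rep(c(TRUE, FALSE, FALSE), each = 3))
  tg <- three_group_comparison(tab)
  expect_true(all(tg$p == 1))
  expect_false(any(tg$significant))
  # a p-value between the corrected level and 0.05 must not be significant
  expect_false(0.02 < attr(tg, "corrected_alpha"))
})

test_that("three-group comparison names an empty group", {
  tab <- cohort_table(c("a", "b", "c", "d"), c(1, 2, 3, 4),
                      mpdd = c(TRUE, TRUE, TRUE, TRUE),
                      ppa = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(three_group_comparison(tab), "neither")
})

test_that("cohort tables validate and round-trip through CSV", {
  expect_error(cohort_table(c("a", "a"), c(1, 2), c(TRUE, FALSE), c(TRUE, FALSE)),
               "unique")
  expect_error(cohort_table(c("a", "b"), c(1, -2), c(TRUE, FALSE), c(TRUE, FALSE)),
               "finite")
  tab <- cohort_table(c("a", "b", "c"), c(0.1, 0.2, 0), c(TRUE, FALSE, FALSE),
                      c(FALSE, FALSE, TRUE))
  f <- tempfile(fileext = ".csv")
  write_cohort(tab, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("cohort evaluation skips findings lacking a class", {
  tab <- cohort_table(sprintf("c%d", 1:8), c(5, 6, 7, 8, 1, 2, 3, 4),
                      mpdd = rep(c(TRUE, FALSE), each = 4),
                      ppa = rep(FALSE, 8))
  ev <- evaluate_cohort(tab)
  expect_false(ev$mpdd$skipped)
  expect_identical(ev$mpdd$auroc, 1)
  expect_true(ev$ppa$skipped)
  expect_match(ev$ppa$reason, "PPA")
  expect_null(ev$three_group)
})
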