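# Pairing, deviation edge rules, paired t-test, cohort evaluation.

make_feat_table <- function(pid, condition, structures, metrics, values) {
  data.frame(patient_id = pid, condition = condition,
             structure = structures, metric = metrics, value = values,
             stringsAsFactors = FALSE)
}

test_that("pair_features inner-joins on feature id and drops the rest", {
  pre <- make_feat_table("p1", "pre",
                         rep(c("liver", "spleen"), each = 2),
                         rep(c("hu_mean", "volume_ml"), 2), c(60, 1500, 40, 200))
  post <- make_feat_table("p1", "post",
                          c("liver", "liver", "kidney"),
                          c("hu_mean", "volume_ml", "hu_mean"),
                          c(55, 1400, 35))
  paired <- pair_features(pre, post)
  expect_equal(nrow(paired), 2L)
  expect_setequal(paired$structure, "liver")
  expect_setequal(attr(paired, "dropped"),
                  c("spleen:hu_mean", "spleen:volume_ml", "kidney:hu_mean"))
  expect_equal(paired$pre[paired$metric == "hu_mean"], 60)
  expect_equal(paired$post[paired$metric == "hu_mean"], 55)

  # size bound and symmetry of dropping
  swapped <- pair_features(post, pre)
  expect_equal(nrow(swapped), nrow(paired))
  expect_setequal(attr(swapped, "dropped"), attr(paired, "dropped"))

  # identical feature sets pair completely
  same <- pair_features(pre, transform(pre, condition = "post"))
  expect_equal(nrow(same), 4L)
  expect_length(attr(same, "dropped"), 0L)

  expect_error(pair_features(pre, transform(post, patient_id = "p2")),
               "different patients")
})

test_that("relative difference applies the zero rule exactly", {
  expect_equal(relative_difference_pct(100, 80), -20)
  expect_equal(relative_difference_pct(200, 231.1), 15.55)
  expect_identical(relative_difference_pct(0, 5), 0)
  expect_identical(relative_difference_pct(5, 0), 0)
  expect_identical(relative_difference_pct(0, 0), 0)
  # vectorised
  expect_equal(relative_difference_pct(c(100, 0, 50), c(80, 7, 75)),
               c(-20, 0, 50))
  # sign agreement with absolute difference when both values positive
  set.seed(5)
  pre <- stats::runif(100, 1, 100)
  post <- stats::runif(100, 1, 100)
  expect_true(all(sign(relative_difference_pct(pre, post)) ==
                  sign(absolute_difference(pre, post))))
})

test_that("absolute difference is post minus pre, signed", {
  expect_equal(absolute_difference(100, 80), -20)
  expect_equal(absolute_difference(3.5, 3.5), 0)
  expect_equal(absolute_difference(-50, -60), -10)
})

test_that("compute_deviations flags zero-rule rows", {
  paired <- data.frame(patient_id = "p1",
                       structure = c("a", "b"), metric = "volume_ml",
                       pre = c(10, 0), post = c(8, 4),
                       stringsAsFactors = FALSE)
  dev <- compute_deviations(paired)
  expect_equal(dev$abs_diff, c(-2, 4))
  expect_equal(dev$rel_diff_pct, c(-20, 0))
  expect_equal(dev$flags, c("", "zero_rule"))
})

test_that("macro_average means included values, zero-rule values included", {
  expect_equal(macro_average(c(-10, -20, -30)), -20)
  expect_equal(macro_average(5), 5)
  expect_equal(macro_average(c(-10, 0, -20)), -10)
  expect_true(is.na(macro_average(numeric(0))))
})

test_that("paired_t_test matches the textbook formula and closed form", {
  # frozen worked example: differences {1, 1, -1} -> t = 0.5, df = 2
  # closed-form CDF for df = 2: P(T<=t) = 1/2 + t / (2*sqrt(2)*sqrt(1+t^2/2))
  res <- paired_t_test(c(0, 0, 0), c(1, 1, -1))
  expect_equal(res$t, 0.5, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  p_closed <- 2 * (1 - (0.5 + 0.5 / (2 * sqrt(2) * sqrt(1 + 0.25 / 2))))
  expect_equal(res$p, p_closed, tolerance = 1e-12)
  expect_equal(res$p, 2 / 3, tolerance = 1e-12)

  # brute-force textbook formula on random vectors, 12 significant digits,
  # and stats::t.test as an independent oracle route
  set.seed(123)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    pre <- stats::rnorm(n, 50, 10)
    post <- stats::rnorm(n, 48, 10)
    d <- post - pre
    t_text <- mean(d) * sqrt(n) / stats::sd(d)
    res <- paired_t_test(pre, post)
    expect_equal(res$t, t_text, tolerance = 1e-12)
    oracle <- stats::t.test(post, pre, paired = TRUE)
    expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
    # antisymmetry: swapping conditions negates t, p unchanged
    swapped <- paired_t_test(post, pre)
    expect_equal(swapped$t, -res$t, tolerance = 1e-12)
    expect_equal(swapped$p, res$p, tolerance = 1e-12)
  }
})

test_that("paired_t_test degenerate rules", {
  expect_equal(paired_t_test(5, 7),
               list(t = 0, df = 0L, p = 1, flag = "insufficient_n"))
  # no change at all -> null accepted with p = 1
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant nonzero shift -> zero-variance degenerate, p = 0
  shift <- paired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shift$p, 0)
  expect_equal(shift$flag, "degenerate")
  expect_true(is.infinite(shift$t) && shift$t > 0)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("evaluate_cohort composes macro-average and t-test per feature", {
  dev <- do.call(rbind, lapply(1:3, function(i) {
    pre <- c(100, 200)[1]
    data.frame(patient_id = paste0("p", i), structure = "SAT_C3",
               metric = "volume_ml", pre = 100,
               post = 100 * (1 + c(-10, -20, -30)[i] / 100),
               stringsAsFactors = FALSE)
  }))
  dev$rel_diff_pct <- relative_difference_pct(dev$pre, dev$post)
  dev$abs_diff <- absolute_difference(dev$pre, dev$post)
  dev$flags <- ""
  ev <- evaluate_cohort(dev)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n, 3L)
  expect_equal(ev$mean_rel_diff_pct, -20)
  oracle <- stats::t.test(dev$post, dev$pre, paired = TRUE)
  expect_equal(ev$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(ev$p, oracle$p.value, tolerance = 1e-12)

  # single-patient feature: insufficient n
  solo <- dev[1, ]
  solo$structure <- "liver"
  ev2 <- evaluate_cohort(rbind(dev, solo))
  row <- ev2[ev2$structure == "liver", ]
  expect_equal(row$p, 1)
  expect_equal(row$flags, "insufficient_n")
  expect_equal(row$n, 1L)

  # significance classes at both thresholds
  expect_equal(trendkit:::.significance_class(c(0.2, 0.03, 0.004)),
               c("ns", "p<0.05", "p<0.01"))
})

test_that("Bonferroni column is min(1, p*m) and never below raw p", {
  set.seed(77)
  dev <- do.call(rbind, lapply(1:6, function(i) {
    do.call(rbind, lapply(sprintf("s%02d", 1:25), function(s) {
      pre <- stats::rnorm(1, 100, 5)
      data.frame(patient_id = paste0("p", i), structure = s,
                 metric = "hu_mean", pre = pre,
                 post = pre + stats::rnorm(1, -1, 2),
                 stringsAsFactors = FALSE)
    }))
  }))
  dev$rel_diff_pct <- relative_difference_pct(dev$pre, dev$post)
  dev$abs_diff <- absolute_difference(dev$pre, dev$post)
  dev$flags <- ""
  ev <- evaluate_cohort(dev, bonferroni = TRUE)
  m <- nrow(ev)
  expect_equal(m, 25L)
  expect_equal(ev$p_bonferroni, pmin(1, ev$p * m))
  expect_true(all(ev$p_bonferroni >= ev$p))
  expect_true(all(ev$p_bonferroni <= 1))
})
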