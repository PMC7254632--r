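test_that("prediction errors and medians follow their definitions", {
  expect_equal(prediction_errors(c(80, 100, 125), 100), c(-20, 0, 25))
  expect_equal(prediction_errors(rep(50, 5), 50), rep(0, 5))
  expect_error(prediction_errors(numeric(), 100), "non-empty")

  bp <- bias_precision(c(-20, 0, 25))
  expect_equal(bp$mpe, 0)
  expect_equal(bp$mape, 20)
  bp2 <- bias_precision(rep(-2.5, 4))
  expect_equal(bp2$mpe, -2.5)
  expect_equal(bp2$mape, 2.5)
  # order invariance and sign-flip invariance of mape
  pe <- c(3, -8, 15, -1, 7)
  expect_equal(bias_precision(sample(pe)), bias_precision(pe))
  expect_equal(bias_precision(-pe)$mape, bias_precision(pe)$mape)
})

test_that("attainment uses inclusive bioequivalence bounds", {
  expect_equal(attainment(rep(100, 7)), 1)
  expect_equal(attainment(c(79.9, 80, 125, 125.1)), 0.5)
  # scale invariance: values and window scaled together
  vals <- c(70, 85, 100, 120, 130)
  expect_equal(attainment(vals), attainment(vals * 3, window = c(80, 125) * 3))
})

test_that("the exact quantile CI matches binomial enumeration", {
  # independent enumeration oracle: coverage of every order-statistic pair,
  # symmetric-tail choice
  enumerate_ci <- function(n, q, level) {
    alpha <- 1 - level
    probs <- dbinom(0:n, n, q)
    l <- max(which(cumsum(probs)[1:n] <= alpha / 2))  # P(Bin <= l-1) <= a/2
    u <- min(which(rev(cumsum(rev(probs)))[-1] <= alpha / 2))
    c(l, u)
  }
  set.seed(31)
  for (case in list(c(100, 0.5), c(250, 0.5), c(94, 0.5), c(60, 0.25))) {
    n <- case[1]; q <- case[2]
    x <- rnorm(n)
    ci <- quantile_ci(x, q, 0.95)
    expected <- enumerate_ci(n, q, 0.95)
    expect_equal(c(ci$l, ci$u), expected)
    s <- sort(x)
    expect_equal(c(ci$lower, ci$upper), s[expected])
    expect_gte(ci$coverage, 0.95)
  }
  # spec'd landmark: n = 100 median interval spans the 40th-61st order stats
  ci100 <- quantile_ci(rnorm(100), 0.5)
  expect_equal(c(ci100$l, ci100$u), c(40, 61))
})

test_that("quantile CI endpoints are data values and widen with the level", {
  x <- rlnorm(200)
  ci95 <- quantile_ci(x, 0.5, 0.95)
  ci99 <- quantile_ci(x, 0.5, 0.99)
  expect_true(all(c(ci95$lower, ci95$upper, ci99$lower, ci99$upper) %in% x))
  expect_lte(ci99$lower, ci95$lower)
  expect_gte(ci99$upper, ci95$upper)
  # identical values give a degenerate interval
  cid <- quantile_ci(rep(7, 50), 0.5)
  expect_equal(cid$lower, 7); expect_equal(cid$upper, 7)
  expect_error(quantile_ci(rnorm(4), 0.5, 0.95), "too small")
})

test_that("paired comparisons delegate to the named tests", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.9, 3.8, 1.7, 4.1, 2.5)
  expect_equal(compare_paired(x, x, "continuous"), 1)
  # strongly shifted pairs are detected
  expect_lt(compare_paired(x, x + 2, "continuous"), 0.05)
  expect_equal(compare_paired(x, x + 2, "continuous"),
               suppressWarnings(wilcox.test(x, x + 2, paired = TRUE)$p.value))
  # symmetric discordance: McNemar near 1
  before <- c(TRUE, FALSE, TRUE, FALSE, rep(TRUE, 6))
  after <- c(FALSE, TRUE, FALSE, TRUE, rep(TRUE, 6))
  expect_gt(compare_paired(before, after, "binary"), 0.9)
  expect_error(compare_paired(1:3, 1:4), "length")
})

test_that("evaluation reports assemble the metrics coherently", {
  set.seed(8)
  auc <- rlnorm(94, log(344), 0.25)
  rep_ <- evaluation_report(auc, 344)
  expect_s3_class(rep_, "dox_evaluation")
  expect_equal(rep_$mpe, median(prediction_errors(auc, 344)))
  expect_equal(rep_$attainment, attainment(100 * auc / 344))
  td <- tidy(rep_)
  expect_equal(td$metric, c("mpe", "mape", "attainment"))
  expect_true(all(td$conf.low[1:2] <= td$estimate[1:2]))
  gl <- glance(rep_)
  expect_equal(gl$n, 94)
})
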