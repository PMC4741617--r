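# Paired estimator, empirical-Bayes prior, moderation and ranking.

test_that("paired fit reproduces the textbook estimator", {
  em <- make_paired_em(rbind(g1 = c(1, 2, 3), g2 = c(2, 2, 2)))
  fit <- fit_paired_contrast(em, "CAF", "HPF")
  expect_equal(fit$table$logFC, c(2, 2))
  expect_equal(fit$table$s2, c(1, 0))     # constant differences: s2 = 0
  expect_equal(fit$table$df, c(2L, 2L))
  # antisymmetry: swapping conditions negates logFC, keeps s2
  rev_fit <- fit_paired_contrast(em, "HPF", "CAF")
  expect_equal(rev_fit$table$logFC, -fit$table$logFC)
  expect_equal(rev_fit$table$s2, fit$table$s2)
})

test_that("pairing is validated against the metadata", {
  em <- make_paired_em(rbind(g1 = c(1, 2)))
  expect_error(fit_paired_contrast(em, "CAF", "TGFB"), "not found")
  # dropping one patient's CAF sample leaves a single pair
  em1 <- em[, c("HPF_1", "HPF_2", "CAF_1")]
  expect_error(suppressMessages(fit_paired_contrast(em1, "CAF", "HPF")),
               "fewer than 2")
})

test_that("unmoderated pipeline matches the paired t-test oracle exactly", {
  set.seed(101)
  for (i in 1:100) {
    diffs <- matrix(rnorm(3), 1)
    x <- rnorm(3, 8)
    em <- make_paired_em(diffs)
    em$values[1, 4:6] <- x + diffs
    em$values[1, 1:3] <- x
    fit <- fit_paired_contrast(em, "CAF", "HPF")
    de <- moderate(fit, prior = list(df_prior = 0, s2_prior = 1))
    oracle <- t.test(em$values[1, 4:6], em$values[1, 1:3], paired = TRUE)
    expect_lt(abs(de$t[1] - unname(oracle$statistic)), 1e-10)
    expect_lt(abs(de$p[1] - oracle$p.value), 1e-10)
  }
})

test_that("prior estimation recovers a known hierarchical truth", {
  set.seed(202)
  d0 <- 4; s02 <- 1; d <- 10; n <- 5000
  sigma2 <- s02 * d0 / rchisq(n, d0)         # inverse-chi-squared prior
  s2 <- sigma2 * rchisq(n, d) / d
  prior <- estimate_prior(s2, d)
  expect_lt(abs(prior$df_prior - d0) / d0, 0.15)
  expect_lt(abs(prior$s2_prior - s02) / s02, 0.15)
  # agreement with the independent limma implementation
  lf <- limma::fitFDist(s2, df1 = d)
  expect_equal(prior$df_prior, lf$df2, tolerance = 1e-6)
  expect_equal(prior$s2_prior, lf$scale, tolerance = 1e-6)
})

test_that("prior estimation limits behave: zero dispersion and scaling", {
  s2 <- rep(2, 100)
  prior <- estimate_prior(s2, 4)
  expect_identical(prior$df_prior, Inf)
  set.seed(9)
  s2r <- rchisq(500, 5)
  p1 <- estimate_prior(s2r, 4)
  p2 <- estimate_prior(2 * s2r, 4)
  expect_equal(p2$s2_prior, 2 * p1$s2_prior, tolerance = 1e-8)
  expect_equal(p2$df_prior, p1$df_prior, tolerance = 1e-8)
  expect_error(estimate_prior(rep(0, 100), 4), "positive residual variance")
})

test_that("moderation follows the closed form and its limits", {
  em <- make_paired_em(rbind(g1 = c(1, 2, 3), g2 = c(0.5, 1, 1.5)))
  fit <- fit_paired_contrast(em, "CAF", "HPF")
  # hand computation: beta=2, s2=1, d=2, n=3, d0=2, s02=1 -> s2_post=1,
  # t = 2/(1/sqrt(3)) = 2*sqrt(3) on 4 df
  de <- moderate(fit, prior = list(df_prior = 2, s2_prior = 1))
  expect_equal(de$s2_post[1], 1)
  expect_equal(de$t[1], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(de$df_total[1], 4)
  expect_equal(de$p[1], 2 * pt(-2 * sqrt(3), df = 4), tolerance = 1e-12)
  # d0 = Inf: every feature uses the prior variance
  de_inf <- moderate(fit, prior = list(df_prior = Inf, s2_prior = 0.5))
  expect_equal(unique(de_inf$s2_post), 0.5)
  # shrinkage direction: s2_post between s2 and s2_prior
  set.seed(33)
  em2 <- make_paired_em(matrix(rnorm(300), 100, 3))
  de2 <- run_paired_de(em2, "CAF", "HPF")
  pr <- attr(de2, "prior")
  expect_true(all(de2$s2_post >= pmin(de2$s2, pr$s2_prior) - 1e-12))
  expect_true(all(de2$s2_post <= pmax(de2$s2, pr$s2_prior) + 1e-12))
})

test_that("zero-variance features with no prior get infinite t and p = 0", {
  em <- make_paired_em(rbind(g1 = c(2, 2, 2), g2 = c(1, 2, 3)))
  fit <- fit_paired_contrast(em, "CAF", "HPF")
  expect_warning(de <- moderate(fit, prior = list(df_prior = 0, s2_prior = 1)),
                 "Inf")
  expect_identical(de$t[1], Inf)
  expect_identical(de$p[1], 0)
})

test_that("moderated results agree with limma on a paired design", {
  set.seed(77)
  em <- make_paired_em(matrix(rnorm(1500, sd = 0.7), 500, 3))
  de <- run_paired_de(em, "CAF", "HPF")
  block <- factor(em$samples$patient)
  cond <- factor(em$samples$condition, levels = c("HPF", "CAF"))
  design <- model.matrix(~ block + cond)
  lf <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(de$logFC, unname(lf$coefficients[, "condCAF"]),
               tolerance = 1e-10)
  expect_equal(de$t, unname(lf$t[, "condCAF"]), tolerance = 1e-6)
  expect_equal(de$p, unname(lf$p.value[, "condCAF"]), tolerance = 1e-6)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  # independent brute-force step-up with enforced monotonicity
  n <- length(p); ord <- order(p)
  q_raw <- p[ord] * n / seq_len(n)
  q_mon <- rev(cummin(rev(q_raw)))
  expect_equal(adjust_bh(p)[ord], pmin(q_mon, 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("ranking is by decreasing t with documented tie-breaks", {
  em <- make_paired_em(rbind(a = c(-1, -1, -1), b = c(3, 3.1, 2.9),
                             c = c(2, 2.1, 1.9)))
  de <- moderate(fit_paired_contrast(em, "CAF", "HPF"),
                 prior = list(df_prior = 2, s2_prior = 0.1))
  rl <- rank_features(de)
  expect_equal(rl$feature, c("b", "c", "a"))
  expect_true(!is.unsorted(rev(rl$score)))
  # tie on t: feature id ascending
  de2 <- de
  de2$t <- c(1, 1, 0)
  rl2 <- rank_features(de2)
  expect_equal(rl2$feature[1:2], c("a", "b"))
})
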