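# Paired two-condition differential expression with empirical-Bayes
# variance moderation. The paired design is implemented as the
# within-patient difference estimator (equivalent to a blocked linear
# model for two conditions), which keeps a closed-form oracle: per feature
# the log-fold-change is the mean of within-patient differences and the
# residual variance is their sample variance on n_pairs - 1 df.

#' Fit a paired two-condition contrast per feature
#'
#' Pairs samples by patient: every patient contributing exactly one sample
#' in each of the two conditions forms a complete pair; patients missing
#' either condition are dropped (with a message), and a patient with more
#' than one sample in a condition is an error.
#'
#' @param em an `expr_matrix` whose metadata carries `patient` and
#'   `condition`
#' @param condition_a test condition label (e.g. `"CAF"`)
#' @param condition_b baseline condition label (e.g. `"HPF"`)
#' @return an object of class `paired_fit`: a list with `table`
#'   (data.frame: feature, logFC, s2, df), `n_pairs`, the contrast labels
#'   and the patients used
#' @export
fit_paired_contrast <- function(em, condition_a, condition_b) {
  stopifnot(inherits(em, "expr_matrix"))
  meta <- em$samples
  if (!all(c("patient", "condition") %in% names(meta))) {
    stop("sample metadata must carry `patient` and `condition`", call. = FALSE)
  }
  if (!condition_a %in% meta$condition || !condition_b %in% meta$condition) {
    stop("contrast conditions not found in the metadata", call. = FALSE)
  }
  a <- meta[meta$condition == condition_a, ]
  b <- meta[meta$condition == condition_b, ]
  if (anyDuplicated(a$patient) || anyDuplicated(b$patient)) {
    stop("a patient contributes more than one sample in a contrast condition",
         call. = FALSE)
  }
  patients <- intersect(a$patient, b$patient)
  dropped <- setdiff(union(a$patient, b$patient), patients)
  if (length(dropped)) {
    message("dropping incomplete pairs for patient(s): ",
            paste(dropped, collapse = ", "))
  }
  if (length(patients) < 2) {
    stop("fewer than 2 complete pairs for ", condition_a, " vs ", condition_b,
         call. = FALSE)
  }
  a_cols <- a$sample[match(patients, a$patient)]
  b_cols <- b$sample[match(patients, b$patient)]
  diffs <- em$values[, a_cols, drop = FALSE] - em$values[, b_cols, drop = FALSE]
  n <- length(patients)
  logFC <- rowMeans(diffs)
  s2 <- rowSums((diffs - logFC)^2) / (n - 1)
  structure(list(
    table = data.frame(feature = rownames(diffs), logFC = logFC, s2 = s2,
                       df = n - 1L, row.names = NULL,
                       stringsAsFactors = FALSE),
    n_pairs = n, condition_a = condition_a, condition_b = condition_b,
    patients = patients
  ), class = "paired_fit")
}

#' Estimate the empirical-Bayes variance prior by moment matching
#'
#' Matches the first two moments of log s2 to a scaled F distribution
#' (the marginal of sample variances under an inverse-chi-squared prior),
#' yielding the prior degrees of freedom `df_prior` and prior variance
#' `s2_prior`. When the dispersion of log s2 does not exceed its
#' theoretical minimum under equal true variances, `df_prior` is infinite.
#' Features with s2 = 0 are excluded from estimation.
#'
#' @param s2 per-feature residual variances
#' @param df residual degrees of freedom (scalar or per-feature)
#' @return a list with `df_prior` and `s2_prior`
#' @export
estimate_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10) {
    stop("need at least 10 features with positive residual variance",
         call. = FALSE)
  }
  s2 <- s2[ok]
  if (length(df) > 1) df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar <= 0) {
    return(list(df_prior = Inf, s2_prior = exp(emean)))
  }
  df_prior <- 2 * trigamma_inverse(evar)
  s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# solve trigamma(x) = y for x > 0; Newton on x with a bisection fallback
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100) {
  stopifnot(y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < tol) return(x)
  }
  # bisection fallback: trigamma is strictly decreasing
  lo <- 1e-8; hi <- 1e8
  for (i in seq_len(200)) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

#' Moderate a paired fit with an empirical-Bayes prior
#'
#' Shrinks each feature's residual variance toward the prior:
#' s2_post = (d0 * s2_prior + d * s2) / (d0 + d), computes the moderated
#' t = logFC / sqrt(s2_post / n_pairs) on d0 + d degrees of freedom,
#' two-sided p-values and Benjamini-Hochberg adjusted q-values. With
#' d0 = 0 the ordinary paired t is recovered; with d0 infinite every
#' feature uses the prior variance.
#'
#' @param fit a `paired_fit`
#' @param prior a list with `df_prior`, `s2_prior`; estimated from the fit
#'   when omitted
#' @return a `de_result`: data.frame (feature, logFC, s2, df, s2_post, t,
#'   df_total, p, q) with the contrast, prior and n_pairs as attributes
#' @export
moderate <- function(fit, prior = NULL) {
  stopifnot(inherits(fit, "paired_fit"))
  tab <- fit$table
  if (is.null(prior)) prior <- estimate_prior(tab$s2, tab$df)
  d0 <- prior$df_prior
  s02 <- prior$s2_prior
  if (d0 < 0) stop("prior df must be >= 0", call. = FALSE)
  if (d0 > 0 && (!is.finite(s02) || s02 <= 0)) {
    stop("prior variance must be > 0 when prior df > 0", call. = FALSE)
  }
  if (!is.finite(d0)) {
    s2_post <- rep(s02, nrow(tab))
  } else {
    if (any(d0 + tab$df == 0)) {
      if (all(d0 + tab$df == 0)) {
        stop("zero total degrees of freedom: no variance information",
             call. = FALSE)
      }
    }
    s2_post <- (d0 * s02 + tab$df * tab$s2) / (d0 + tab$df)
  }
  df_total <- d0 + tab$df
  se <- sqrt(s2_post / fit$n_pairs)
  t <- tab$logFC / se
  if (any(se == 0)) {
    warning("zero posterior variance for ", sum(se == 0),
            " feature(s): moderated t set to +/-Inf, p to 0")
    t[se == 0] <- sign(tab$logFC[se == 0]) * Inf
    t[se == 0 & tab$logFC == 0] <- 0
  }
  p <- 2 * pt(-abs(t), df = df_total)
  p[is.infinite(t)] <- 0
  out <- data.frame(
    feature = tab$feature, logFC = tab$logFC, s2 = tab$s2, df = tab$df,
    s2_post = s2_post, t = t, df_total = df_total, p = p,
    q = adjust_bh(p), stringsAsFactors = FALSE
  )
  structure(out, class = c("de_result", "data.frame"),
            contrast = c(fit$condition_a, fit$condition_b),
            prior = prior, n_pairs = fit$n_pairs)
}

#' Paired moderated differential expression in one call
#'
#' Convenience wrapper: [fit_paired_contrast()], [estimate_prior()] and
#' [moderate()] chained.
#'
#' @inheritParams fit_paired_contrast
#' @return a `de_result`
#' @export
run_paired_de <- function(em, condition_a, condition_b) {
  moderate(fit_paired_contrast(em, condition_a, condition_b))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p vector of p-values in \[0, 1\]
#' @return vector of BH-adjusted q-values
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Rank features by moderated t
#'
#' Sorts features by decreasing moderated t; ties are broken by feature id
#' (ascending), a stable, documented rule.
#'
#' @param de a `de_result`
#' @param metric column to rank on (default `"t"`)
#' @return a `ranked_list` (see [ranked_list()])
#' @export
rank_features <- function(de, metric = "t") {
  stopifnot(inherits(de, "de_result"), metric %in% names(de))
  ord <- order(-de[[metric]], de$feature, method = "radix")
  ranked_list(de$feature[ord], de[[metric]][ord])
}
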