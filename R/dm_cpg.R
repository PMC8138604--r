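#' Per-locus two-group linear fit on M-values
#'
#' Ordinary least squares of M on an intercept plus group indicator,
#' computed locus-wise in closed form. The coefficient is the difference of
#' group means on the M scale (second factor level minus first); residual
#' variance and degrees of freedom feed the empirical-Bayes moderation.
#' A locus missing in an entire group, or without residual degrees of
#' freedom, is flagged untestable.
#'
#' @param matrix A `meth_matrix`.
#' @param design Group labels per sample (defaults to `matrix$groups`);
#'   must have exactly two levels.
#' @return data.frame with per-locus `coef_m`, `s2`, `df`, `leverage`
#'   (`1/n1 + 1/n2`), `delta_beta` (difference of group mean beta) and
#'   `testable`.
#' @export
fit_group_contrast <- function(matrix, design = NULL) {
  if (is.null(design)) design <- matrix$groups
  design <- droplevels(factor(design))
  if (nlevels(design) != 2L) stop("design must have exactly two groups")
  g1 <- design == levels(design)[1L]
  g2 <- design == levels(design)[2L]
  m <- matrix$m
  b <- matrix$beta
  row_stats <- function(x, sel) {
    xs <- x[, sel, drop = FALSE]
    n <- rowSums(!is.na(xs))
    mu <- rowMeans(xs, na.rm = TRUE)
    ss <- rowSums((xs - mu)^2, na.rm = TRUE)
    list(n = n, mu = mu, ss = ss)
  }
  s1 <- row_stats(m, g1); s2g <- row_stats(m, g2)
  df <- s1$n + s2g$n - 2L
  testable <- s1$n >= 1L & s2g$n >= 1L & df >= 1L
  s2 <- ifelse(df > 0, (s1$ss + s2g$ss) / df, NA_real_)
  b1 <- rowMeans(b[, g1, drop = FALSE], na.rm = TRUE)
  b2 <- rowMeans(b[, g2, drop = FALSE], na.rm = TRUE)
  data.frame(coef_m = s2g$mu - s1$mu, s2 = s2, df = df,
             leverage = 1 / s1$n + 1 / s2g$n,
             delta_beta = b2 - b1, testable = testable)
}

# Solve trigamma(x) = y by Newton iteration on the monotone decreasing
# trigamma; vectorised, standard starting point 0.5 + 1/y.
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-7
  out[lo] <- 1 / sqrt(y[lo])
  hi <- y > 1e7
  out[hi] <- 1 / y[hi]
  mid <- !lo & !hi
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of per-locus variances
#'
#' Shrinks per-locus residual variances toward a common prior variance
#' `s0_sq` with prior degrees of freedom `d0`, yielding the posterior
#' variance `(d0 * s0_sq + df * s2) / (d0 + df)` used by the moderated
#' t-statistic. The hyperparameters are estimated by matching the first two
#' moments of `log(s2)` to the scaled-F form implied by the hierarchical
#' model (normal errors, inverse-chi-squared prior on the true variances):
#' the excess variance of `log(s2)` beyond the chi-squared sampling term
#' `trigamma(df/2)` determines `d0` through a trigamma inversion, and the
#' mean determines `s0_sq`. When the observed spread does not exceed the
#' sampling term, `d0` is capped at `1e6` (effectively complete shrinkage).
#'
#' @param s_sq Per-locus residual variances.
#' @param df Residual degrees of freedom (scalar or per-locus vector).
#' @param d0 Optional override of the prior degrees of freedom; `d0 = 0`
#'   disables shrinkage so the moderated t reduces to the ordinary t.
#' @return List with `d0`, `s0_sq` and `posterior_var`.
#' @export
moderate_variances <- function(s_sq, df, d0 = NULL) {
  df <- rep_len(df, length(s_sq))
  ok <- is.finite(s_sq) & s_sq > 0 & df > 0
  if (is.null(d0)) {
    if (sum(ok) < 10L) {
      warning("fewer than 10 testable loci; no moderation applied (d0 = 0)")
      d0 <- 0
      s0_sq <- if (any(ok)) mean(s_sq[ok]) else 1
    } else {
      z <- log(s_sq[ok])
      e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
      if (stats::var(z) < 1e-12) {
        d0 <- 1e6
        s0_sq <- mean(s_sq[ok])
      } else {
        excess <- stats::var(e) - mean(trigamma(df[ok] / 2))
        if (excess > 0) {
          d0 <- 2 * trigamma_inverse(excess)
          if (!is.finite(d0) || d0 > 1e6) d0 <- 1e6
          s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
        } else {
          d0 <- 1e6
          s0_sq <- exp(mean(e))
        }
      }
    }
  } else {
    s0_sq <- if (any(ok)) {
      z <- log(s_sq[ok])
      e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
      exp(mean(e))
    } else 1
  }
  post <- if (d0 == 0) s_sq else (d0 * s0_sq + df * s_sq) / (d0 + df)
  list(d0 = d0, s0_sq = s0_sq, posterior_var = post)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment of p-values controlling the expected false-discovery
#' proportion; monotone in the ranked p-values.
#'
#' @param p_values Vector of p-values in `[0, 1]` (NAs passed through).
#' @return Adjusted q-values.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially methylated CpGs / probes
#'
#' Full per-locus pipeline: locus-wise OLS of M-values on the group
#' contrast, empirical-Bayes variance moderation, moderated t-statistics
#' with `d0 + df` degrees of freedom, two-sided p-values and
#' Benjamini-Hochberg FDR over the testable loci. Effect sizes are reported
#' on the beta scale (`delta_beta` = case mean beta minus control mean
#' beta, with the second factor level as case); inference is on the M
#' scale.
#'
#' @param matrix A filtered `meth_matrix`.
#' @param design Group labels (defaults to `matrix$groups`).
#' @param fdr_threshold Significance threshold on FDR: 0.10 for RRBS-style
#'   data, 0.05 for the better-powered array datasets.
#' @param d0 Optional moderation override (see [moderate_variances()]).
#' @return data.frame of class `dm_result`: locus columns from the matrix
#'   plus `delta_beta`, `coef_m`, `s2`, `df`, `t`, `p_value`, `fdr`,
#'   `significant`, `direction` ("hyper"/"hypo") and `testable`. Untestable
#'   loci keep `NA` statistics and are excluded from the FDR denominator.
#' @export
call_dm_cpgs <- function(matrix, design = NULL, fdr_threshold = 0.10,
                         d0 = NULL) {
  fit <- fit_group_contrast(matrix, design)
  ok <- fit$testable & is.finite(fit$s2)
  mod <- moderate_variances(fit$s2[ok], fit$df[ok], d0 = d0)
  t_stat <- p <- rep(NA_real_, nrow(fit))
  se <- sqrt(mod$posterior_var * fit$leverage[ok])
  t_stat[ok] <- fit$coef_m[ok] / se
  df_total <- pmin(mod$d0 + fit$df[ok], 1e6)
  p[ok] <- 2 * stats::pt(-abs(t_stat[ok]), df_total)
  fdr <- rep(NA_real_, nrow(fit))
  fdr[ok] <- bh_fdr(p[ok])
  out <- cbind(matrix$loci,
               data.frame(delta_beta = fit$delta_beta, coef_m = fit$coef_m,
                          s2 = fit$s2, df = fit$df, t = t_stat,
                          p_value = p, fdr = fdr,
                          significant = !is.na(fdr) & fdr < fdr_threshold,
                          direction = ifelse(fit$delta_beta >= 0,
                                             "hyper", "hypo"),
                          testable = ok))
  attr(out, "hyperparams") <- list(d0 = mod$d0, s0_sq = mod$s0_sq)
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("dm_result", "data.frame")
  out
}

#' Write a per-locus differential methylation table
#' @param dm A `dm_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dm_table <- function(dm, path) {
  utils::write.table(as.data.frame(dm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
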