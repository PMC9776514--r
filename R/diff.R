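#' Two-group per-probe statistics
#'
#' For each probe (row) of a value matrix, the group-mean difference
#' (group2 - group1), the pooled residual variance and the residual degrees
#' of freedom \eqn{d_g = n_1 + n_2 - 2}.
#'
#' @param m Numeric matrix, probes x samples.
#' @param group Logical or two-level vector over columns; \code{TRUE} (or the
#'   second level) is the "high" group whose mean enters positively.
#' @return List with vectors \code{mean_diff}, \code{s2} and scalar \code{df}
#'   plus group sizes \code{n1}, \code{n2}.
#' @export
groupwise_stats <- function(m, group) {
  if (!is.matrix(m)) stop("`m` must be a matrix")
  g <- as_two_groups(group, ncol(m))
  n1 <- sum(!g); n2 <- sum(g)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(m[, !g, drop = FALSE])
  m2 <- rowMeans(m[, g, drop = FALSE])
  ss1 <- rowSums((m[, !g, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, g, drop = FALSE] - m2)^2)
  list(mean_diff = m2 - m1, s2 = (ss1 + ss2) / (n1 + n2 - 2L),
       df = n1 + n2 - 2L, n1 = n1, n2 = n2)
}

as_two_groups <- function(group, n) {
  if (length(group) != n) stop("group labels must match the number of columns")
  if (is.logical(group)) return(group)
  f <- factor(group)
  if (nlevels(f) != 2L) stop("exactly two groups required")
  f == levels(f)[2L]
}

#' Moment estimator of the empirical-Bayes variance prior
#'
#' Fits the scaled inverse-chi-square prior \eqn{s_g^2 \sim s_0^2
#' \chi^2_{d_0}/d_0} by the method of moments on
#' \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)}: the excess of
#' \eqn{\mathrm{var}(e)} over \eqn{\psi'(d_g/2)} identifies
#' \eqn{\psi'(d_0/2)}, inverted by Newton iteration on the monotone trigamma;
#' the mean of \eqn{e} then identifies \eqn{s_0^2}. When the observed spread
#' is no larger than the chi-square sampling spread, \eqn{d_0} is flagged
#' infinite and \eqn{s_0^2} is the (geometric-mean-based) common variance.
#'
#' @param s2 Vector of per-probe residual variances (zeros are excluded from
#'   the moment estimation).
#' @param df Residual degrees of freedom (scalar, shared across probes).
#' @return List of class \code{eb_prior} with \code{d0} (possibly \code{Inf})
#'   and \code{s0_sq}.
#' @export
estimate_eb_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("all residual variances are zero; cannot estimate prior")
  if (sum(ok) < 50L)
    warning("fewer than 50 positive variances; prior estimate may be unstable")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  ve <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(ve) || ve <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    half_d0 <- trigamma_inverse(ve)
    d0 <- 2 * half_d0
    s0_sq <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_prior")
}

#' Invert the trigamma function
#'
#' Solves \eqn{\psi'(x) = y} for \eqn{x > 0} by Newton iteration on
#' \eqn{1/\psi'} (nearly linear), as is standard for the variance-prior
#' moment estimator.
#'
#' @param y Positive target value.
#' @return \code{x} with \eqn{|\psi'(x) - y|} below 1e-12 (relative).
#' @export
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) stop("trigamma_inverse needs a positive finite y")
  x <- 0.5 + 1 / y # asymptotic start: trigamma(x) ~ 1/x + 1/(2x^2)
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (-dif / x < 1e-12) break
  }
  x
}

#' Moderated t-statistics
#'
#' Shrinks per-probe variances toward the prior:
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}, then
#' \eqn{t = \Delta / (\tilde s \sqrt{1/n_1 + 1/n_2})} referred to a
#' t-distribution on \eqn{d_0 + d_g} degrees of freedom (normal when
#' \eqn{d_0 = \infty}). Two-sided p-values.
#'
#' @param mean_diff,s2 Per-probe mean differences and residual variances.
#' @param df Residual degrees of freedom.
#' @param prior An \code{eb_prior} from [estimate_eb_prior()].
#' @param n1,n2 Group sizes.
#' @return List with \code{t}, \code{df_total}, \code{p}.
#' @export
moderated_t <- function(mean_diff, s2, df, prior, n1, n2) {
  stopifnot(inherits(prior, "eb_prior"))
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2")
  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + df * s2) / (prior$d0 + df)
    df_total <- prior$d0 + df
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- mean_diff / se
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t)) else
    2 * stats::pt(-abs(t), df_total)
  list(t = t, df_total = df_total, p = p)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Vector of p-values in \code{[0, 1]} (NA not allowed).
#' @return Vector of q-values, order-matched to \code{p}.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("p-values contain NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Group-mean beta differentials on the percent scale
#'
#' \code{100 * (mean beta in high group - mean beta in low group)}; a 20%
#' change is a 0.2 beta shift.
#'
#' @inheritParams groupwise_stats
#' @param beta Beta-value matrix, probes x samples.
#' @return Numeric vector of percent differentials.
#' @export
beta_differential <- function(beta, group) {
  g <- as_two_groups(group, ncol(beta))
  100 * (rowMeans(beta[, g, drop = FALSE]) - rowMeans(beta[, !g, drop = FALSE]))
}

#' Differential methylation screen between grade groups
#'
#' Moderated t-test on M-values comparing high-grade (WHO 2-3) against
#' low-grade (WHO 1) samples, BH-adjusted genome-wide, with beta-scale
#' differentials (percent) and hyper/hypo direction labels.
#'
#' @param cohort A [meth_cohort()] object.
#' @param fdr_cut Significance cutoff on q-values (default 0.05).
#' @param eps Clipping constant for the M-value transform.
#' @return An object of class \code{diff_screen}: list with \code{records}
#'   (data.frame sorted by p-value), \code{prior}, \code{fdr_cut} and a
#'   \code{summary} recomputed from the records: significant/hyper/hypo
#'   counts and the counts of significant CpGs whose |beta differential|
#'   exceeds 1%, 5% and 10%.
#' @export
diff_screen <- function(cohort, fdr_cut = 0.05, eps = 1e-3) {
  stopifnot(inherits(cohort, "meth_cohort"))
  high <- cohort$samples$grade >= 2L
  if (all(high) || !any(high)) stop("both grade groups must be present")
  m <- cohort_m_values(cohort, eps = eps)
  gs <- groupwise_stats(m, high)
  prior <- estimate_eb_prior(gs$s2, gs$df)
  mt <- moderated_t(gs$mean_diff, gs$s2, gs$df, prior, gs$n1, gs$n2)
  records <- data.frame(
    probe_id = rownames(cohort$beta),
    mean_m_diff = gs$mean_diff,
    mean_beta_diff = beta_differential(cohort$beta, high),
    t_mod = mt$t, df_total = mt$df_total, p_value = mt$p,
    q_value = bh_fdr(mt$p),
    direction = ifelse(gs$mean_diff > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE)
  records <- records[order(records$p_value, records$probe_id), , drop = FALSE]
  rownames(records) <- NULL
  res <- structure(list(records = records, prior = prior, fdr_cut = fdr_cut),
                   class = "diff_screen")
  res$summary <- summarize_diff(res)
  res
}

summarize_diff <- function(x) {
  sig <- x$records[x$records$q_value < x$fdr_cut, , drop = FALSE]
  list(n_tested = nrow(x$records), n_sig = nrow(sig),
       n_hyper = sum(sig$direction == "hyper"),
       n_hypo = sum(sig$direction == "hypo"),
       n_over_1pct = sum(abs(sig$mean_beta_diff) > 1),
       n_over_5pct = sum(abs(sig$mean_beta_diff) > 5),
       n_over_10pct = sum(abs(sig$mean_beta_diff) > 10))
}

#' @export
print.diff_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("diff_screen: %d probes tested, %d significant at FDR < %g\n",
              s$n_tested, s$n_sig, x$fdr_cut))
  cat(sprintf("  %d hypermethylated, %d hypomethylated in high grade\n",
              s$n_hyper, s$n_hypo))
  cat(sprintf("  |beta diff| > 1%% / 5%% / 10%%: %d / %d / %d\n",
              s$n_over_1pct, s$n_over_5pct, s$n_over_10pct))
  cat(sprintf("  variance prior: d0 = %s, s0^2 = %.4g\n",
              format(x$prior$d0, digits = 4), x$prior$s0_sq))
  invisible(x)
}

#' @export
summary.diff_screen <- function(object, ...) object$summary
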