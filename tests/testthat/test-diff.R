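test_that("two-group statistics match the pooled-variance formulas", {
  m <- rbind(c(1, 1, 3, 3), c(0, 2, 1, 5))
  g <- c(FALSE, FALSE, TRUE, TRUE)
  gs <- groupwise_stats(m, g)
  expect_equal(gs$mean_diff[1], 2)
  expect_equal(gs$df, 2L) # n1 + n2 - 2

  set.seed(10)
  m <- matrix(rnorm(50), 5, 10)
  g <- rep(c(FALSE, TRUE), each = 5)
  gs <- groupwise_stats(m, g)
  for (i in 1:5) {
    x1 <- m[i, !g]; x2 <- m[i, g]
    expect_equal(gs$mean_diff[i], mean(x2) - mean(x1), tolerance = 1e-12)
    s2_oracle <- ((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
      (length(x1) + length(x2) - 2)
    expect_equal(gs$s2[i], s2_oracle, tolerance = 1e-12)
  }
  # constant probe has zero residual variance
  m[1, ] <- 7
  expect_equal(groupwise_stats(m, g)$s2[1], 0)
  expect_error(groupwise_stats(m, c(rep(FALSE, 9), TRUE)), "at least 2")
})

test_that("trigamma inversion solves psi'(x) = y to high precision", {
  bisect <- function(y, lo = 1e-3, hi = 1e6) { # independent monotone bisection
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (trigamma(mid) > y) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (y in c(0.5, 0.05, 2, 10)) {
    x <- trigamma_inverse(y)
    expect_lt(abs(trigamma(x) - y), 1e-10)
    expect_equal(x, bisect(y), tolerance = 1e-6)
  }
})

test_that("the variance-prior moment estimator recovers a scaled-chi-square prior", {
  set.seed(11)
  d0 <- 8; s0 <- 4; dg <- 8
  # hierarchical draw the estimator assumes: true variances from the scaled
  # inverse-chi-square prior, observed variances chi-square about the truth
  sigma2 <- d0 * s0 / rchisq(20000, d0)
  sg2 <- sigma2 * rchisq(20000, dg) / dg
  prior <- estimate_eb_prior(sg2, dg)
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.05)
})

test_that("identical variances give an infinite prior df", {
  prior <- estimate_eb_prior(rep(2.5, 100), 8)
  expect_true(is.infinite(prior$d0))
  expect_error(estimate_eb_prior(rep(0, 100), 8), "zero")
})

test_that("moderated t matches its closed form and limiting cases", {
  prior <- structure(list(d0 = 4, s0_sq = 2), class = "eb_prior")
  mt <- moderated_t(1, 1, 8, prior, 5, 5)
  expect_equal(mt$t, 1 / sqrt((4 * 2 + 8 * 1) / 12 * 0.4), tolerance = 1e-12)
  expect_equal(mt$df_total, 12)

  expect_equal(moderated_t(0, 1, 8, prior, 5, 5)$t, 0)
  expect_equal(moderated_t(0, 1, 8, prior, 5, 5)$p, 1)

  # equal observed variances: moderation is a no-op relative to classical t
  set.seed(12)
  diffs <- rnorm(20)
  mt <- moderated_t(diffs, rep(1, 20), 8, structure(list(d0 = 7, s0_sq = 1),
                                                    class = "eb_prior"), 5, 5)
  classical <- diffs / sqrt(1 * 0.4)
  expect_equal(mt$t, classical, tolerance = 1e-12)

  # infinite prior df: posterior variance is s0^2 everywhere
  pInf <- structure(list(d0 = Inf, s0_sq = 3), class = "eb_prior")
  mtI <- moderated_t(diffs, runif(20), 8, pInf, 5, 5)
  expect_equal(mtI$t, diffs / sqrt(3 * 0.4), tolerance = 1e-12)
})

test_that("moderated pipeline agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(13)
  m <- matrix(rnorm(200 * 10, sd = rep(sqrt(0.5 + rchisq(200, 4) / 4), 10)), 200, 10)
  g <- rep(c(0, 1), each = 5)
  gs <- groupwise_stats(m, g == 1)
  prior <- estimate_eb_prior(gs$s2, gs$df)
  mt <- moderated_t(gs$mean_diff, gs$s2, gs$df, prior, gs$n1, gs$n2)

  fit <- limma::lmFit(m, cbind(1, g))
  eb <- limma::eBayes(fit)
  expect_equal(prior$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(prior$s0_sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(mt$t, unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(mt$p, unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH q-values match the step-up oracle and are permutation invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NA)), "NA")

  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
})

test_that("beta differentials are percent-scale group-mean differences", {
  beta <- rbind(c(0.6, 0.6, 0.8, 0.8), c(0.5, 0.5, 0.5, 0.5))
  g <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(beta_differential(beta, g), c(20, 0))
  set.seed(15)
  b <- matrix(runif(60), 6, 10)
  g <- rep(c(FALSE, TRUE), each = 5)
  expect_equal(beta_differential(b, g),
               100 * (rowMeans(b[, 6:10]) - rowMeans(b[, 1:5])),
               tolerance = 1e-12)
})

test_that("differential screen output is internally consistent", {
  sim <- simulate_cohort(sim_config(n_probes = 1000, n_samples = 30, seed = 21,
                                    n_pos_planted = 40, n_neg_planted = 40))
  d <- diff_screen(sim$cohort)
  r <- d$records
  expect_false(is.unsorted(r$p_value))
  expect_identical(r$direction, ifelse(r$mean_m_diff > 0, "hyper", "hypo"))
  expect_true(all(r$q_value >= r$p_value - 1e-15))
  # summary is recomputable from the records
  sig <- r[r$q_value < 0.05, ]
  expect_equal(d$summary$n_sig, nrow(sig))
  expect_equal(d$summary$n_over_5pct, sum(abs(sig$mean_beta_diff) > 5))
  # direction labels are invariant to testing on beta instead of M
  co_b <- sim$cohort; co_b$beta <- co_b$beta # beta already
  gs_b <- groupwise_stats(sim$cohort$beta, sim$cohort$samples$grade >= 2)
  agree <- sign(gs_b$mean_diff) == sign(r$mean_m_diff[match(rownames(sim$cohort$beta), r$probe_id)])
  expect_gt(mean(agree), 0.9) # null probes can flip sign; signal probes below

  sig_idx <- match(sig$probe_id, rownames(sim$cohort$beta))
  expect_true(all(sign(gs_b$mean_diff[sig_idx]) ==
                    sign(sig$mean_m_diff)))
  expect_error(diff_screen(meth_cohort(sim$cohort$beta, sim$cohort$annotation,
                                       transform(sim$cohort$samples, grade = 2L))),
               "both grade groups")
})

test_that("threshold summary counts follow the percent conventions", {
  res <- list(records = data.frame(
    probe_id = letters[1:5], mean_beta_diff = c(0.5, 2, 7, 15, 60),
    q_value = 0.01, direction = "hyper", stringsAsFactors = FALSE),
    fdr_cut = 0.05)
  s <- methprolif:::summarize_diff(res)
  expect_equal(s$n_over_1pct, 4L)
  expect_equal(s$n_over_5pct, 3L)
  expect_equal(s$n_over_10pct, 2L)
})
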