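#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximisation of the Efron-tie-corrected partial
#' likelihood. Convergence when the largest score component falls below
#' 1e-9 or the relative log-likelihood change below 1e-10 (at most 50
#' iterations, with step-halving). A fit drifting to |coef| > 15 is flagged
#' as a monotone likelihood (perfect separation) and marked non-converged.
#'
#' @param time Positive follow-up times.
#' @param event Logical/0-1 event indicators; at least one event required.
#' @param x Covariate matrix (n x p) or vector; finite, no constant column.
#' @return An object of class \code{cox_fit}: coefficients, standard errors,
#'   two-sided Wald p-values, the observed information, log partial
#'   likelihoods at the estimate and at zero, a convergence flag, and the
#'   (sorted) data for downstream residual tests.
#' @export
fit_cox <- function(time, event, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  event <- as.logical(event)
  n <- length(time)
  if (nrow(x) != n || length(event) != n) stop("length mismatch")
  if (any(time <= 0)) stop("times must be > 0")
  if (!any(event)) stop("at least one event required")
  if (any(!is.finite(x))) stop("covariates must be finite")
  if (any(apply(x, 2L, stats::sd) == 0)) stop("constant covariate")

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord, , drop = FALSE]
  p <- ncol(x)
  # fit on centred, unit-SD covariates: the partial likelihood is invariant
  # to centring, and scaling makes the monotone-likelihood flag and the
  # Newton trust region scale-free; estimates are rescaled on return
  x_orig <- x
  x_sd <- apply(x, 2L, stats::sd)
  x <- sweep(sweep(x, 2L, colMeans(x)), 2L, x_sd, `/`)
  beta <- rep(0, p)
  ll_old <- cox_partial(time, event, x, beta)$loglik
  ll0 <- ll_old
  converged <- FALSE
  for (it in seq_len(50L)) {
    pl <- cox_partial(time, event, x, beta)
    step <- tryCatch(solve(pl$info, pl$score), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_ll <- cox_partial(time, event, x, new_beta)$loglik
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < pl$loglik) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- cox_partial(time, event, x, new_beta)$loglik
      halvings <- halvings + 1L
    }
    beta <- new_beta
    if (max(abs(pl$score)) < 1e-9 ||
        abs(new_ll - pl$loglik) < 1e-10 * (abs(pl$loglik) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  pl <- cox_partial(time, event, x, beta)
  if (any(abs(beta) > 15)) converged <- FALSE
  vcov <- tryCatch(solve(pl$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  z <- beta / se
  # back to the original covariate scale
  D <- diag(1 / x_sd, p)
  structure(list(
    coef = stats::setNames(beta / x_sd, colnames(x_orig)), se = se / x_sd,
    wald_p = 2 * stats::pnorm(-abs(z)),
    info = diag(x_sd, p) %*% pl$info %*% diag(x_sd, p),
    vcov = D %*% vcov %*% D,
    loglik = pl$loglik, loglik_null = ll0,
    converged = converged,
    time = time, event = event, x = x_orig), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: %d subjects, %d events%s\n", length(x$time),
              sum(x$event), if (x$converged) "" else "  [NOT CONVERGED]"))
  print(data.frame(coef = x$coef, `HR` = exp(x$coef), se = x$se,
                   p = signif(x$wald_p, 4)))
  invisible(x)
}

# Efron partial log-likelihood, score and information at beta.
cox_partial <- function(time, event, x, beta) {
  n <- length(time); p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ev_times <- unique(time[event])
  loglik <- 0
  score <- rep(0, p)
  info <- matrix(0, p, p)
  for (tk in ev_times) {
    risk <- time >= tk
    dth <- event & time == tk
    m <- sum(dth)
    S <- sum(w[risk]); SD <- sum(w[dth])
    xw <- x * w
    Sx <- colSums(xw[risk, , drop = FALSE]); SxD <- colSums(xw[dth, , drop = FALSE])
    # second-moment sums
    xr <- x[risk, , drop = FALSE]; wr <- w[risk]
    Sxx <- crossprod(xr, xr * wr)
    xd <- x[dth, , drop = FALSE]; wd <- w[dth]
    SxxD <- crossprod(xd, xd * wd)
    loglik <- loglik + sum(eta[dth])
    score <- score + colSums(xd)
    for (l in seq_len(m) - 1L) {
      phi <- l / m
      den <- S - phi * SD
      a <- Sx - phi * SxD
      B <- Sxx - phi * SxxD
      loglik <- loglik - log(den)
      score <- score - a / den
      info <- info + B / den - tcrossprod(a / den)
    }
  }
  list(loglik = loglik, score = score, info = info)
}

# Efron-adjusted Schoenfeld residuals: one row per event (time order),
# each death in a tie group receives the group's averaged expected covariate.
schoenfeld_residuals <- function(fit) {
  time <- fit$time; event <- fit$event; x <- fit$x
  w <- exp(drop(x %*% fit$coef))
  ev_times <- unique(time[event])
  res <- NULL; gt <- NULL
  for (tk in ev_times) {
    risk <- time >= tk
    dth <- event & time == tk
    m <- sum(dth)
    S <- sum(w[risk]); SD <- sum(w[dth])
    xw <- x * w
    Sx <- colSums(xw[risk, , drop = FALSE]); SxD <- colSums(xw[dth, , drop = FALSE])
    xbar <- rep(0, ncol(x))
    for (l in seq_len(m) - 1L) {
      phi <- l / m
      xbar <- xbar + (Sx - phi * SxD) / (S - phi * SD)
    }
    xbar <- xbar / m
    r <- sweep(x[dth, , drop = FALSE], 2L, xbar)
    res <- rbind(res, r)
    gt <- c(gt, rep(tk, m))
  }
  list(residuals = res, times = gt)
}

# Kaplan-Meier transform g(t) = 1 - KM(t) evaluated at the event times.
km_transform <- function(time, event, at) {
  ut <- sort(unique(time[event]))
  nrisk <- vapply(ut, function(tt) sum(time >= tt), numeric(1L))
  ndeath <- vapply(ut, function(tt) sum(event & time == tt), numeric(1L))
  km <- cumprod(1 - ndeath / nrisk)
  idx <- findInterval(at, ut)
  surv <- c(1, km)[idx + 1L]
  1 - surv
}

#' Proportional-hazards score test from scaled Schoenfeld residuals
#'
#' Tests constancy of each covariate's effect over time by correlating its
#' Schoenfeld residuals with a transform of the event times (default: the
#' Kaplan-Meier transform \eqn{g(t) = 1 - \hat S_{KM}(t)}). Per-covariate
#' chi-square statistics on 1 df and a global joint chi-square on p df
#' share the residual set but weight it differently (inverse-information
#' diagonal vs the full inverse).
#'
#' @param fit A converged [fit_cox()] object.
#' @return List with \code{covariate_p} (named, one per covariate),
#'   \code{global_p}, and the underlying chi-square statistics.
#' @export
test_ph <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  d <- sum(fit$event)
  if (d < 3L) stop("too few events for a proportional-hazards test")
  sr <- schoenfeld_residuals(fit)
  g <- km_transform(fit$time, fit$event, sr$times)
  gc <- g - mean(g)
  u <- drop(crossprod(gc, sr$residuals))              # p-vector
  denom <- sum(gc^2)
  vinv <- fit$vcov
  chisq_cov <- d * u^2 * diag(vinv) / denom
  chisq_glob <- d * drop(t(u) %*% vinv %*% u) / denom
  list(covariate_p = stats::setNames(
         stats::pchisq(chisq_cov, 1L, lower.tail = FALSE), names(fit$coef)),
       global_p = stats::pchisq(chisq_glob, length(u), lower.tail = FALSE),
       chisq_covariate = chisq_cov, chisq_global = chisq_glob)
}

# ---------------------------------------------------------------------------
# Vectorised univariate Cox screen: one single-covariate model per column of
# `X`, all probes iterated simultaneously (shared risk sets, per-probe
# Newton step on the concave partial likelihood).
cox_uni_screen <- function(X, time, event, max_iter = 50L) {
  event <- as.logical(event)
  n <- length(time); P <- ncol(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  # standardise each probe's covariate so the Newton trust region and the
  # separation flag are scale-free; coefficients are rescaled on return
  x_sd <- matrixStats_row_sd(t(X))
  X <- sweep(sweep(X, 2L, colMeans(X)), 2L, pmax(x_sd, 1e-300), `/`)
  ev_times <- unique(time[event])
  K <- length(ev_times)
  Trisk <- outer(ev_times, time, `<=`) * 1          # K x n
  Dmat <- outer(ev_times, time, `==`) * outer(rep(1, K), event * 1)
  m_k <- rowSums(Dmat)
  sum_xd <- Dmat %*% X                              # K x P, constant in beta
  nonconst <- x_sd > 0

  beta <- rep(0, P)
  ll_old <- rep(NA_real_, P)
  done <- !nonconst
  info <- rep(NA_real_, P)
  for (it in seq_len(max_iter)) {
    W <- exp(X * rep(beta, each = n))
    XW <- X * W; XXW <- X * XW
    S <- Trisk %*% W;  SD <- Dmat %*% W
    SX <- Trisk %*% XW; SXD <- Dmat %*% XW
    SXX <- Trisk %*% XXW; SXXD <- Dmat %*% XXW
    U <- colSums(sum_xd)
    I <- rep(0, P)
    ll <- colSums(Dmat %*% (X * rep(beta, each = n)))
    for (k in seq_len(K)) {
      for (l in seq_len(m_k[k]) - 1L) {
        phi <- l / m_k[k]
        den <- S[k, ] - phi * SD[k, ]
        a <- (SX[k, ] - phi * SXD[k, ]) / den
        U <- U - a
        I <- I + (SXX[k, ] - phi * SXXD[k, ]) / den - a^2
        ll <- ll - log(den)
      }
    }
    step <- ifelse(done | I <= 0, 0, U / I)
    step <- pmin(pmax(step, -1), 1)                 # trust region
    newly_done <- !done & (abs(U) < 1e-9 |
      (!is.na(ll_old) & abs(ll - ll_old) < 1e-10 * (abs(ll) + 1e-10)))
    done <- done | newly_done
    beta <- ifelse(done, beta, pmin(pmax(beta + step, -20), 20))
    ll_old <- ll
    info <- I
    if (all(done)) break
  }
  flagged <- !nonconst | abs(beta) >= 15 | !done | info <= 0
  se <- ifelse(flagged, NA_real_, 1 / sqrt(info))
  z <- beta / se
  list(coef = ifelse(nonconst, beta / x_sd, NA_real_),
       se = se / x_sd,
       wald_p = 2 * stats::pnorm(-abs(z)), info = info, flagged = flagged,
       coef_std = beta,
       time = time, event = event, X = X,
       ev_times = ev_times, m_k = m_k, Trisk = Trisk, Dmat = Dmat)
}

# Vectorised PH score test for the univariate screen (1 covariate per probe).
cox_uni_ph <- function(scr) {
  time <- scr$time; event <- scr$event; X <- scr$X
  n <- length(time); P <- ncol(X); K <- length(scr$ev_times)
  d <- sum(event)
  # all quantities on the standardised covariate scale (the statistic is
  # invariant to linear rescaling)
  W <- exp(X * rep(scr$coef_std, each = n))
  W[, is.na(scr$coef)] <- NA_real_
  XW <- X * W
  S <- scr$Trisk %*% W; SD <- scr$Dmat %*% W
  SX <- scr$Trisk %*% XW; SXD <- scr$Dmat %*% XW
  xbar <- matrix(0, K, P)
  for (k in seq_len(K)) {
    acc <- rep(0, P)
    for (l in seq_len(scr$m_k[k]) - 1L) {
      phi <- l / scr$m_k[k]
      acc <- acc + (SX[k, ] - phi * SXD[k, ]) / (S[k, ] - phi * SD[k, ])
    }
    xbar[k, ] <- acc / scr$m_k[k]
  }
  g_events <- km_transform(time, event, time[event])
  gc <- g_events - mean(g_events)
  # sum over deaths of gc * (x_i - xbar_{k(i)})
  death_k <- match(time[event], scr$ev_times)
  term1 <- drop(crossprod(gc, X[event, , drop = FALSE]))
  gsum_k <- vapply(seq_len(K), function(k) sum(gc[death_k == k]), numeric(1L))
  term2 <- drop(crossprod(gsum_k, xbar))
  u <- term1 - term2
  chisq <- d * u^2 / (scr$info * sum(gc^2))
  p <- stats::pchisq(chisq, 1L, lower.tail = FALSE)
  list(covariate_p = p, global_p = p, chisq = chisq)
}
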