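# Small programmatic fixtures shared across test files.

# minimal valid annotation for `n` probes on one chromosome
tiny_annotation <- function(n, pos = seq(100L, by = 500L, length.out = n),
                            chrom = "chr1", cgi = "island", gene = "promoter",
                            symbols = "") {
  data.frame(probe_id = sprintf("p%03d", seq_len(n)),
             chrom = chrom, pos = pos, chrom_arm = "q",
             cgi_context = cgi, gene_context = gene, gene_symbols = symbols,
             stringsAsFactors = FALSE)
}

tiny_samples <- function(n, grade = rep_len(c(1L, 2L), n)) {
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             grade = grade,
             mitotic_index = seq_len(n), ki67_li = seq_len(n),
             mcm6_li = rev(seq_len(n)), age = 50 + seq_len(n),
             sex = rep_len(c("F", "M"), n),
             pfs_months = 10 * seq_len(n), pfs_event = rep_len(c(TRUE, FALSE), n),
             os_months = 20 * seq_len(n), os_event = rep_len(c(FALSE, TRUE), n),
             stringsAsFactors = FALSE)
}

tiny_cohort <- function(n_probes = 10L, n_samples = 4L, seed = 42L) {
  set.seed(seed)
  beta <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
                 dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  meth_cohort(beta, tiny_annotation(n_probes), tiny_samples(n_samples))
}

# brute-force Spearman: explicit average ranks, then Pearson on the ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# brute-force complete-linkage agglomeration: returns sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# independent Efron partial log-likelihood, written from the definition
oracle_efron_loglik <- function(b, time, event, x) {
  ll <- 0
  for (tk in unique(time[event])) {
    dth <- event & time == tk
    risk <- time >= tk
    m <- sum(dth)
    S <- sum(exp(b * x[risk])); SD <- sum(exp(b * x[dth]))
    ll <- ll + sum(b * x[dth])
    for (l in seq_len(m) - 1L) ll <- ll - log(S - (l / m) * SD)
  }
  ll
}

# grid-search maximiser of the oracle partial likelihood (single covariate)
oracle_cox_grid <- function(time, event, x, lower = -5, upper = 5, tol = 1e-8) {
  stats::optimize(oracle_efron_loglik, c(lower, upper), maximum = TRUE,
                  tol = tol, time = time, event = event, x = x)$maximum
}
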