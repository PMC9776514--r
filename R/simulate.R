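#' Simulation configuration for EPIC-like synthetic cohorts
#'
#' Defaults mirror the cohort structure the screens assume: 48 samples with a
#' WHO-grade mix of 21/69/10% (grades 1/2/3), CGI strata at
#' island/shore/shelf/open-sea fractions 0.30/0.15/0.10/0.45, 300 positively
#' and 400 negatively planted CpGs coupled to a latent proliferation score,
#' planted beta shifts up to 0.5, and exponential progression/overall
#' survival coupled to the same score.
#'
#' @param n_probes Number of probes (default 20000).
#' @param n_samples Number of samples (default 48).
#' @param seed Integer seed; every random draw in [simulate_cohort()] derives
#'   from it.
#' @param frac_island,frac_shore,frac_shelf,frac_open_sea CGI stratum
#'   proportions; must sum to 1.
#' @param grade_probs Probabilities for grades 1/2/3.
#' @param n_pos_planted,n_neg_planted Counts of CpGs coupled positively
#'   (hypermethylating with proliferation) and negatively to the latent score.
#' @param effect_scale Maximum planted beta shift, in (0, 1); per-probe
#'   effects are Uniform(0.3, \code{effect_scale}) on the beta-range scale.
#' @param marker_noise Multiplier on the calibrated marker noise dispersions
#'   (1 reproduces the target inter-marker rank correlations).
#' @param survival_gamma Log-hazard per unit latent score for PFS; OS uses
#'   half this coupling.
#' @param censor_frac Target censoring fraction for both endpoints.
#' @param noise_sd_range Range of per-probe logit-scale measurement noise SDs.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_probes = 20000L, n_samples = 48L, seed = 1L,
                       frac_island = 0.30, frac_shore = 0.15,
                       frac_shelf = 0.10, frac_open_sea = 0.45,
                       grade_probs = c(0.21, 0.69, 0.10),
                       n_pos_planted = 300L, n_neg_planted = 400L,
                       effect_scale = 0.5, marker_noise = 1,
                       survival_gamma = 0.8, censor_frac = 0.6,
                       noise_sd_range = c(0.2, 0.5)) {
  fr <- c(frac_island, frac_shore, frac_shelf, frac_open_sea)
  if (abs(sum(fr) - 1) > 1e-9) stop("stratum fractions must sum to 1")
  if (any(fr < 0)) stop("stratum fractions must be non-negative")
  if (length(grade_probs) != 3L || abs(sum(grade_probs) - 1) > 1e-9)
    stop("grade_probs must be 3 probabilities summing to 1")
  if (effect_scale <= 0 || effect_scale >= 1) stop("effect_scale must lie in (0, 1)")
  if (n_pos_planted + n_neg_planted > n_probes)
    stop("planted counts exceed n_probes")
  structure(list(
    n_probes = as.integer(n_probes), n_samples = as.integer(n_samples),
    seed = as.integer(seed),
    frac_island = frac_island, frac_shore = frac_shore,
    frac_shelf = frac_shelf, frac_open_sea = frac_open_sea,
    grade_probs = grade_probs,
    n_pos_planted = as.integer(n_pos_planted),
    n_neg_planted = as.integer(n_neg_planted),
    effect_scale = effect_scale, marker_noise = marker_noise,
    survival_gamma = survival_gamma, censor_frac = censor_frac,
    noise_sd_range = noise_sd_range), class = "sim_config")
}

# Marker factor loadings. Targets for the inter-marker Spearman correlations
# are 0.71 (Ki-67 ~ MI), 0.69 (MCM6 ~ Ki-67) and 0.60 (MCM6 ~ MI). Each
# marker is a strictly monotone transform of u_i = lambda_i * z + s_i * eps,
# so its Spearman correlations equal those of the underlying normals, where
# Pearson r implies Spearman rho = (6/pi) asin(r/2). Inverting gives the
# pairwise r's, and a single-factor model r_ij = lambda_i * lambda_j solves
# in closed form.
marker_loadings <- function() {
  rho <- c(ki_mi = 0.71, mc_ki = 0.69, mc_mi = 0.60)
  r <- 2 * sin(pi * rho / 6)
  l_mi <- sqrt(r[["ki_mi"]] * r[["mc_mi"]] / r[["mc_ki"]])
  c(mi = l_mi, ki67 = r[["ki_mi"]] / l_mi, mcm6 = r[["mc_mi"]] / l_mi)
}

logit  <- function(p) log(p / (1 - p))
expit  <- function(x) stats::plogis(x)

# logit-linear link through (z = -2, lo) and (z = +2, hi)
planted_link <- function(lo, hi) {
  list(center = (logit(lo) + logit(hi)) / 2, slope = (logit(hi) - logit(lo)) / 4)
}

#' Simulate an EPIC-like methylation cohort with ground truth
#'
#' Generates (i) probe annotation on 22 autosomes with clustered island/
#' shore/shelf probes (runs of 3-15 probes spaced 50-300 bp, giving the DMR
#' caller realistic targets) and open-sea singletons spaced >= 2 kb;
#' (ii) a bimodal baseline beta landscape (islands low, open sea high) via
#' logit-normal draws; (iii) a latent proliferation score \eqn{z \sim N(0,1)}
#' per sample driving WHO grade (quantile cut), three noisy proliferation
#' markers (mitotic index, Ki-67 and MCM6 labeling indices) and exponential
#' survival; (iv) planted CpGs whose beta follows a monotone logit-linear
#' link in \eqn{z} — positive effects preferentially in island/promoter
#' strata, negative effects in open-sea/body strata.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements \code{cohort} (a [meth_cohort()]) and
#'   \code{truth} (class \code{sim_truth}: latent scores and the planted-probe
#'   manifest).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  np <- config$n_probes; ns <- config$n_samples

  ann <- simulate_annotation(np, config)

  # latent proliferation score; grade by empirical quantile cut so the
  # realised grade mix matches the configured proportions exactly (a 48-
  # sample draw reproduces the 10/33/5 grade-1/2/3 design)
  z <- stats::rnorm(ns)
  ng <- round(cumsum(config$grade_probs)[1:2] * ns)
  r <- rank(z, ties.method = "first")
  grade <- 1L + (r > ng[1L]) + (r > ng[2L])

  samples <- simulate_samples(z, grade, config)

  # baseline probe means on the logit scale, bimodal by CGI stratum
  strat_mu <- c(island = logit(0.10), shore = logit(0.30),
                shelf = logit(0.55), open_sea = logit(0.80))
  base_eta <- stats::rnorm(np, strat_mu[ann$cgi_context], 0.8)
  base_beta <- expit(base_eta)
  noise_sd <- stats::runif(np, config$noise_sd_range[1L], config$noise_sd_range[2L])

  planted <- place_planted(ann, base_beta, config)

  # per-probe x per-sample mean on the logit scale
  eta <- matrix(base_eta, np, ns)
  if (nrow(planted)) {
    idx <- match(planted$probe_id, ann$probe_id)
    eta[idx, ] <- planted$center + outer(planted$sign * planted$slope, z)
  }
  beta <- expit(eta + matrix(stats::rnorm(np * ns, 0, noise_sd), np, ns))
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  rownames(beta) <- ann$probe_id
  colnames(beta) <- samples$sample_id

  truth <- structure(list(
    latent_score = stats::setNames(z, samples$sample_id),
    planted = planted[, c("probe_id", "direction", "effect", "stratum")]),
    class = "sim_truth")
  list(cohort = meth_cohort(beta, ann, samples), truth = truth)
}

simulate_annotation <- function(np, config) {
  n_str <- round(np * c(config$frac_island, config$frac_shore,
                        config$frac_shelf, config$frac_open_sea))
  n_str[4L] <- np - sum(n_str[1:3])
  pool <- rep(CGI_LEVELS, n_str)

  # probes per chromosome, roughly proportional to a declining size profile
  chrom_w <- (23 - (1:22)) / sum(23 - (1:22))
  n_chr <- as.vector(stats::rmultinom(1L, np, chrom_w))

  chrom <- character(np); pos <- integer(np); cgi <- character(np)
  gene_ctx <- character(np); gene <- character(np)
  i <- 1L; gene_id <- 0L
  clustered <- sample(pool[pool != "open_sea"])
  open_sea_left <- n_str[4L]
  ci <- 1L
  for (ch in seq_len(22L)) {
    left <- n_chr[ch]; cursor <- 1e5L
    while (left > 0L) {
      open_frac <- open_sea_left / max(open_sea_left + length(clustered) - ci + 1L, 1L)
      if (open_sea_left > 0L && (ci > length(clustered) || stats::runif(1L) < open_frac)) {
        # open-sea singleton, spaced >= 2 kb
        cursor <- cursor + as.integer(stats::runif(1L, 2000, 50000))
        chrom[i] <- paste0("chr", ch); pos[i] <- cursor; cgi[i] <- "open_sea"
        if (stats::runif(1L) < 0.5) {
          gene_id <- gene_id + 1L
          gene_ctx[i] <- "body"; gene[i] <- sprintf("GENE%05d", gene_id)
        } else gene_ctx[i] <- "intergenic"
        open_sea_left <- open_sea_left - 1L; left <- left - 1L; i <- i + 1L
      } else {
        # clustered island/shore/shelf run of 3-15 probes, 50-300 bp apart
        run <- min(sample(3:15, 1L), left, length(clustered) - ci + 1L)
        if (run < 1L) { # only open-sea probes remain
          next
        }
        gene_id <- gene_id + 1L
        gname <- sprintf("GENE%05d", gene_id)
        ctx <- sample(c("promoter", "body", "intergenic"), 1L,
                      prob = c(0.6, 0.25, 0.15))
        cursor <- cursor + as.integer(stats::runif(1L, 2000, 50000))
        for (k in seq_len(run)) {
          chrom[i] <- paste0("chr", ch); pos[i] <- cursor
          cgi[i] <- clustered[ci]; ci <- ci + 1L
          gene_ctx[i] <- ctx
          gene[i] <- if (ctx == "intergenic") "" else gname
          cursor <- cursor + as.integer(stats::runif(1L, 50, 300))
          i <- i + 1L
        }
        left <- left - run
      }
    }
  }
  ord <- order(chrom, pos) # already grouped; sort for per-chrom position order
  ann <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(np)),
    chrom = chrom[ord], pos = pos[ord], chrom_arm = "q",
    cgi_context = cgi[ord], gene_context = gene_ctx[ord],
    gene_symbols = gene[ord], stringsAsFactors = FALSE)
  # centromere at 40% of each chromosome's probe span
  for (ch in unique(ann$chrom)) {
    sel <- ann$chrom == ch
    cen <- stats::quantile(ann$pos[sel], 0.4, names = FALSE)
    ann$chrom_arm[sel] <- ifelse(ann$pos[sel] < cen, "p", "q")
  }
  ann
}

place_planted <- function(ann, base_beta, config) {
  pos_pool <- which(ann$cgi_context %in% c("island", "shore") &
                      ann$gene_context == "promoter")
  neg_pool <- which(ann$cgi_context == "open_sea" &
                      ann$gene_context != "promoter")
  if (config$n_pos_planted > length(pos_pool))
    stop("n_pos_planted exceeds the island/promoter stratum size")
  if (config$n_neg_planted > length(neg_pool))
    stop("n_neg_planted exceeds the open-sea stratum size")
  pick_pos <- sort(sample(pos_pool, config$n_pos_planted))
  pick_neg <- sort(sample(neg_pool, config$n_neg_planted))
  idx <- c(pick_pos, pick_neg)
  sgn <- rep(c(1, -1), c(length(pick_pos), length(pick_neg)))
  n <- length(idx)
  if (!n)
    return(data.frame(probe_id = character(), direction = character(),
                      effect = numeric(), stratum = character(),
                      sign = numeric(), center = numeric(), slope = numeric(),
                      stringsAsFactors = FALSE))
  effect <- stats::runif(n, min(0.3, config$effect_scale), config$effect_scale)
  lo <- numeric(n); b <- base_beta[idx]
  up <- sgn > 0
  lo[up]  <- pmin(pmax(b[up], 0.02), 0.96 - effect[up])
  lo[!up] <- pmin(pmax(b[!up] - effect[!up], 0.02), 0.96 - effect[!up])
  link <- planted_link(lo, lo + effect)
  data.frame(
    probe_id = ann$probe_id[idx],
    direction = ifelse(up, "pos", "neg"),
    effect = effect, stratum = ann$cgi_context[idx],
    sign = sgn, center = link$center, slope = link$slope,
    stringsAsFactors = FALSE)
}

simulate_samples <- function(z, grade, config) {
  ns <- length(z)
  lam <- marker_loadings()
  s <- sqrt(pmax(1 - lam^2, 0)) * config$marker_noise
  u_mi <- lam[["mi"]]   * z + stats::rnorm(ns, 0, s[["mi"]])
  u_ki <- lam[["ki67"]] * z + stats::rnorm(ns, 0, s[["ki67"]])
  u_mc <- lam[["mcm6"]] * z + stats::rnorm(ns, 0, s[["mcm6"]])

  mitotic_index <- round(exp(1.45 + 0.75 * u_mi))
  ki67_li <- round(100 * expit(-1.7 + 1.0 * u_ki), 1)
  mcm6_li <- round(100 * expit(-0.85 + 0.9 * u_mc), 1)

  pfs <- simulate_endpoint(z, config$survival_gamma, median_months = 48,
                           censor_frac = config$censor_frac)
  os  <- simulate_endpoint(z, config$survival_gamma / 2, median_months = 96,
                           censor_frac = config$censor_frac)

  data.frame(
    sample_id = sprintf("S%03d", seq_len(ns)),
    grade = grade,
    mitotic_index = mitotic_index,
    ki67_li = pmin(pmax(ki67_li, 0), 100),
    mcm6_li = pmin(pmax(mcm6_li, 0), 100),
    age = pmin(pmax(round(stats::rnorm(ns, 58, 13)), 20), 90),
    sex = sample(c("F", "M"), ns, replace = TRUE, prob = c(0.7, 0.3)),
    pfs_months = pfs$time, pfs_event = pfs$event,
    os_months = os$time, os_event = os$event,
    stringsAsFactors = FALSE)
}

# exponential event times with hazard rate0 * exp(gamma * z); uniform
# censoring window calibrated so the expected censoring fraction matches
simulate_endpoint <- function(z, gamma, median_months, censor_frac) {
  rate <- log(2) / median_months * exp(gamma * z)
  t_event <- stats::rexp(length(z), rate)
  cens_prob <- function(cmax) {
    mean((1 - exp(-rate * cmax)) / (rate * cmax)) - censor_frac
  }
  cmax <- if (cens_prob(1e6) > 0) 1e6 else
    stats::uniroot(cens_prob, c(0.5, 1e6), tol = 1e-6)$root
  t_cens <- stats::runif(length(z), 0, cmax)
  time <- pmax(round(pmin(t_event, t_cens), 1), 0.1)
  list(time = time, event = t_event <= t_cens)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d samples, %d planted probes (%d pos, %d neg)\n",
              length(x$latent_score), nrow(x$planted),
              sum(x$planted$direction == "pos"),
              sum(x$planted$direction == "neg")))
  invisible(x)
}

#' Write / read the ground-truth manifest
#'
#' Long single-file TSV: rows of kind \code{probe} carry the planted-probe
#' manifest (direction, beta-scale effect, CGI stratum); rows of kind
#' \code{sample} carry the latent proliferation scores. The roundtrip is
#' lossless.
#'
#' @param truth A \code{sim_truth} object from [simulate_cohort()].
#' @param path Output TSV path.
#' @return \code{write_truth}: invisibly, \code{path}. \code{read_truth}: a
#'   \code{sim_truth} object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  pr <- truth$planted
  df <- rbind(
    data.frame(kind = rep("probe", nrow(pr)), id = pr$probe_id,
               direction = pr$direction, effect = pr$effect,
               stratum = pr$stratum, stringsAsFactors = FALSE),
    data.frame(kind = "sample", id = names(truth$latent_score), direction = "",
               effect = unname(truth$latent_score), stratum = "",
               stringsAsFactors = FALSE))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(kind = "character", id = "character",
                                         direction = "character",
                                         effect = "numeric",
                                         stratum = "character"))
  if (!identical(names(df), c("kind", "id", "direction", "effect", "stratum")))
    stop("truth manifest schema mismatch")
  if (!all(df$kind %in% c("probe", "sample"))) stop("truth manifest schema mismatch")
  pr <- df[df$kind == "probe", , drop = FALSE]
  sm <- df[df$kind == "sample", , drop = FALSE]
  structure(list(
    latent_score = stats::setNames(sm$effect, sm$id),
    planted = data.frame(probe_id = pr$id, direction = pr$direction,
                         effect = pr$effect, stratum = pr$stratum,
                         stringsAsFactors = FALSE)),
    class = "sim_truth")
}
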