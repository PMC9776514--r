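#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation on average ranks (ties receive average ranks), with
#' the two-sided p-value from \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on
#' \eqn{n - 2} degrees of freedom; \eqn{|\rho| = 1} gives p = 0 by
#' convention.
#'
#' @param x,y Numeric vectors of equal length (>= 4), finite.
#' @return List with \code{rho} and \code{p}.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  list(rho = rho, p = p)
}

spearman_p <- function(rho, n) {
  p <- numeric(length(rho))
  at_one <- abs(rho) >= 1 - 1e-15
  t <- rho[!at_one] * sqrt((n - 2) / (1 - rho[!at_one]^2))
  p[!at_one] <- 2 * stats::pt(-abs(t), n - 2)
  p[at_one] <- 0
  p
}

#' Categorise a probe's methylation level from its median beta
#'
#' Low: median beta value at or below 0.3; high: at or above 0.7; medium in
#' between.
#'
#' @param beta_median Numeric vector in \code{[0, 1]}.
#' @return Character vector with levels low/medium/high.
#' @export
categorize_level <- function(beta_median) {
  if (any(beta_median < 0 | beta_median > 1)) stop("medians must lie in [0, 1]")
  ifelse(beta_median <= 0.3, "low", ifelse(beta_median >= 0.7, "high", "medium"))
}

#' Genome-wide Spearman screen of beta values against a proliferation index
#'
#' Correlates every probe's beta row with a quantitative index (mitotic
#' index, Ki-67 or MCM6 labeling index), BH-adjusts across all tested
#' probes, and annotates each record with the methylation-dynamics metrics:
#' mean, median, SD (n-1 denominator), max-min range and Q3-Q1 IQR
#' (quartiles by linear interpolation, type 7), the two on the percent
#' scale, plus the low/medium/high level category and the PC/NC direction.
#' Probes with a constant beta row have an undefined correlation; they are
#' dropped with a warning and excluded from the BH multiplicity count.
#'
#' @param cohort A [meth_cohort()] object.
#' @param index_name One of \code{"mitotic_index"}, \code{"ki67"},
#'   \code{"mcm6"}, naming the sample-sheet column (\code{ki67} and
#'   \code{mcm6} map to the \code{*_li} columns).
#' @param fdr_cut Significance cutoff on q-values (default 0.05).
#' @return An object of class \code{corr_screen}: list with \code{records}
#'   (sorted by p), \code{index_name}, \code{fdr_cut} and a \code{summary}
#'   recomputed from the records (significant, PC/NC and very-high
#'   |rho| > 2/3 counts).
#' @export
correlation_screen <- function(cohort, index_name = c("mitotic_index", "ki67", "mcm6"),
                               fdr_cut = 0.05) {
  stopifnot(inherits(cohort, "meth_cohort"))
  index_name <- match.arg(index_name)
  col <- switch(index_name, mitotic_index = "mitotic_index",
                ki67 = "ki67_li", mcm6 = "mcm6_li")
  y <- cohort$samples[[col]]
  if (stats::sd(y) == 0) stop("index '", index_name, "' is constant across samples")
  beta <- cohort$beta
  n <- ncol(beta)
  if (n < 4L) stop("need at least 4 samples")

  keep <- matrixStats_row_sd(beta) > 0
  if (!all(keep)) {
    warning(sprintf("%d constant probe(s) dropped from the %s screen",
                    sum(!keep), index_name), call. = FALSE)
    beta <- beta[keep, , drop = FALSE]
  }

  rho <- row_spearman(beta, y)
  p <- spearman_p(rho, n)
  q1q3 <- row_quartiles(beta)
  records <- data.frame(
    probe_id = rownames(beta),
    index_name = index_name,
    rho = rho, p_value = p, q_value = bh_fdr(p),
    direction = ifelse(rho > 0, "PC", "NC"),
    very_high = abs(rho) > 2 / 3,
    beta_mean = rowMeans(beta),
    beta_median = row_median(beta),
    beta_sd = matrixStats_row_sd(beta),
    range_maxmin = 100 * (row_max(beta) - row_min(beta)),
    iqr_q3q1 = 100 * (q1q3[, 2L] - q1q3[, 1L]),
    stringsAsFactors = FALSE)
  records$level <- categorize_level(records$beta_median)
  records <- records[order(records$p_value, records$probe_id), , drop = FALSE]
  rownames(records) <- NULL
  res <- structure(list(records = records, index_name = index_name,
                        fdr_cut = fdr_cut), class = "corr_screen")
  res$summary <- summarize_corr(res)
  res
}

summarize_corr <- function(x) {
  sig <- x$records[x$records$q_value < x$fdr_cut, , drop = FALSE]
  list(n_tested = nrow(x$records), n_sig = nrow(sig),
       n_PC = sum(sig$direction == "PC"), n_NC = sum(sig$direction == "NC"),
       n_very_high_PC = sum(sig$very_high & sig$direction == "PC"),
       n_very_high_NC = sum(sig$very_high & sig$direction == "NC"))
}

#' @export
print.corr_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("corr_screen [%s]: %d probes tested, %d significant at FDR < %g\n",
              x$index_name, s$n_tested, s$n_sig, x$fdr_cut))
  cat(sprintf("  %d PC, %d NC; very high |rho| > 2/3: %d PC, %d NC\n",
              s$n_PC, s$n_NC, s$n_very_high_PC, s$n_very_high_NC))
  invisible(x)
}

#' @export
summary.corr_screen <- function(object, ...) object$summary

#' Directional hit sets of a correlation screen
#'
#' @param screen A \code{corr_screen}.
#' @return List with \code{PC} and \code{NC} probe-id vectors (significant at
#'   the screen's cutoff).
#' @export
corr_hit_sets <- function(screen) {
  stopifnot(inherits(screen, "corr_screen"))
  sig <- screen$records[screen$records$q_value < screen$fdr_cut, , drop = FALSE]
  list(PC = sig$probe_id[sig$direction == "PC"],
       NC = sig$probe_id[sig$direction == "NC"])
}

# --- row-wise helpers (dense matrix, base R) ---------------------------------

row_spearman <- function(beta, y) {
  ry <- rank(y)
  rb <- t(apply(beta, 1L, rank))
  rb <- rb - rowMeans(rb)
  ry <- ry - mean(ry)
  num <- rb %*% ry
  den <- sqrt(rowSums(rb^2) * sum(ry^2))
  as.vector(num) / den
}

matrixStats_row_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
}

row_median <- function(m) apply(m, 1L, stats::median)
row_max <- function(m) apply(m, 1L, max)
row_min <- function(m) apply(m, 1L, min)
row_quartiles <- function(m)
  t(apply(m, 1L, stats::quantile, probs = c(0.25, 0.75), type = 7, names = FALSE))

#' Inclusive intersection structure of directional hit lists
#'
#' Computes, for every non-empty subset of the supplied hit lists (up to
#' order 8), the inclusive (non-disjoint) intersection size, together with
#' the CGI-context and gene-context composition of each intersection, in the
#' long format UpSet-style plots consume. Cross-direction overlaps (e.g.
#' grade-hyper against any NC list) are ordinary subsets here, so their
#' empirical zeros can be asserted directly.
#'
#' @param hit_lists Named list of probe-id vectors (e.g. grade_hyper,
#'   grade_hypo, MI_PC, MI_NC, Ki67_PC, Ki67_NC, MCM6_PC, MCM6_NC).
#' @param annotation Probe annotation; every listed probe must be annotated.
#' @return An object of class \code{overlap_structure}: data.frame with one
#'   row per subset: \code{sets} (plus-joined member names), \code{order},
#'   \code{size}, CGI composition columns \code{cgi_*} and gene-context
#'   columns \code{gene_*} (proportions, NA for empty intersections).
#' @export
overlap_structure <- function(hit_lists, annotation) {
  stopifnot(is.list(hit_lists), !is.null(names(hit_lists)))
  if (length(hit_lists) > 8L) stop("at most 8 hit lists supported")
  annotation <- validate_annotation(annotation)
  univ <- annotation$probe_id
  for (nm in names(hit_lists)) {
    out <- setdiff(hit_lists[[nm]], univ)
    if (length(out))
      stop("hit list '", nm, "' contains probes outside the universe: ", out[1L])
  }
  members <- unique(unlist(hit_lists, use.names = FALSE))
  memb <- vapply(hit_lists, function(l) members %in% l, logical(length(members)))
  if (length(members) == 0L)
    memb <- matrix(logical(), 0L, length(hit_lists),
                   dimnames = list(NULL, names(hit_lists)))
  k <- length(hit_lists)
  ann_idx <- match(members, univ)
  subsets <- lapply(seq_len(2^k - 1L), function(mask) which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0))
  rows <- lapply(subsets, function(s) {
    inside <- if (length(members)) rowSums(memb[, s, drop = FALSE]) == length(s)
              else logical(0)
    idx <- ann_idx[inside]
    cgi <- prop_of(annotation$cgi_context[idx], CGI_LEVELS)
    gen <- prop_of(annotation$gene_context[idx], GENE_LEVELS)
    data.frame(sets = paste(names(hit_lists)[s], collapse = "+"),
               order = length(s), size = sum(inside),
               as.list(stats::setNames(cgi, paste0("cgi_", CGI_LEVELS))),
               as.list(stats::setNames(gen, paste0("gene_", GENE_LEVELS))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$order, -out$size, out$sets), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("overlap_structure", "data.frame"))
}

prop_of <- function(x, levels) {
  if (!length(x)) return(rep(NA_real_, length(levels)))
  as.vector(table(factor(x, levels))) / length(x)
}

#' @export
print.overlap_structure <- function(x, ...) {
  cat(sprintf("overlap_structure: %d subsets over %d lists\n",
              nrow(x), max(x$order)))
  print.data.frame(utils::head(x[x$order <= 2, c("sets", "order", "size")], 12L))
  invisible(x)
}

#' Top-candidate table of highly dynamic, regulatory-region CpGs
#'
#' Filters a correlation screen's significant records conjunctively on
#' methylation dynamics (max-min range above \code{min_range} percent and
#' Q3-Q1 IQR above \code{min_iqr} percent) and regulatory context (CGI
#' island/shore/shelf, or promoter gene context), then annotates each row
#' with its gene symbols and the per-gene hit count (significant CpGs
#' sharing a gene symbol within the same direction), sorted by |rho|
#' descending within direction.
#'
#' @param screen A \code{corr_screen}.
#' @param annotation Probe annotation.
#' @param min_range,min_iqr Percent-scale dynamics cutoffs (defaults 50, 10).
#' @return data.frame of filtered candidate records.
#' @export
top_candidate_table <- function(screen, annotation, min_range = 50, min_iqr = 10) {
  stopifnot(inherits(screen, "corr_screen"))
  annotation <- validate_annotation(annotation)
  sig <- screen$records[screen$records$q_value < screen$fdr_cut, , drop = FALSE]
  ai <- match(sig$probe_id, annotation$probe_id)
  sig$cgi_context <- annotation$cgi_context[ai]
  sig$gene_context <- annotation$gene_context[ai]
  sig$gene_symbols <- annotation$gene_symbols[ai]

  regulatory <- sig$cgi_context %in% c("island", "shore", "shelf") |
    sig$gene_context == "promoter"
  keep <- sig$range_maxmin > min_range & sig$iqr_q3q1 > min_iqr & regulatory
  out <- sig[keep, , drop = FALSE]

  # per-gene hit counts among same-direction significant CpGs (any context)
  out$gene_hits <- 0L
  for (dir in c("PC", "NC")) {
    pool <- sig$gene_symbols[sig$direction == dir & nzchar(sig$gene_symbols)]
    counts <- table(unlist(strsplit(pool, ";", fixed = TRUE)))
    sel <- out$direction == dir & nzchar(out$gene_symbols)
    out$gene_hits[sel] <- vapply(strsplit(out$gene_symbols[sel], ";", fixed = TRUE),
                                 function(gs) sum(counts[gs], na.rm = TRUE), integer(1L))
  }
  out <- out[order(out$direction, -abs(out$rho)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
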