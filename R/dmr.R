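#' DMR caller configuration
#'
#' Hard constraints for the greedy gap-merge caller: consecutive member CpGs
#' closer than \code{max_gap} bp, at least \code{min_cpgs} members, mean
#' beta differential exceeding \code{min_mean_diff} percent, seeded on CpGs
#' significant at \code{cpg_fdr_cut}. The kernel-smoothing scale constant
#' \code{C} of bandwidth-based callers is accepted for interface parity but
#' unused by this caller.
#'
#' @param max_gap Maximum allowed gap between consecutive member CpGs, bp
#'   (gaps must be strictly smaller); default 1000.
#' @param min_cpgs Minimum member count; default 3.
#' @param min_mean_diff Minimum |mean beta differential| in percent; default 10.
#' @param cpg_fdr_cut Seed-CpG q-value cutoff; default 0.05.
#' @param C Unused smoothing-scale constant (interface parity); default 3.
#' @return A list of class \code{dmr_config}.
#' @export
dmr_config <- function(max_gap = 1000L, min_cpgs = 3L, min_mean_diff = 10,
                       cpg_fdr_cut = 0.05, C = 3) {
  if (max_gap <= 0) stop("max_gap must be positive")
  if (min_cpgs < 2L) stop("min_cpgs must be >= 2")
  structure(list(max_gap = as.integer(max_gap), min_cpgs = as.integer(min_cpgs),
                 min_mean_diff = min_mean_diff, cpg_fdr_cut = cpg_fdr_cut,
                 C = C), class = "dmr_config")
}

#' Call differentially methylated regions by greedy gap-merge
#'
#' Per chromosome, seed CpGs (q below \code{cpg_fdr_cut}) are merged into
#' maximal runs whose consecutive genomic gaps are strictly below
#' \code{max_gap}; runs are split into maximal same-direction sub-runs; and
#' sub-runs with at least \code{min_cpgs} members and |mean member beta
#' differential| above \code{min_mean_diff} percent are emitted, sorted by
#' |mean differential| descending (ties by chromosome, then start).
#' Region significance combines member p-values by Fisher's method, then BH
#' across emitted regions.
#'
#' @param diff A \code{diff_screen} object or its \code{records} data.frame.
#' @param annotation Probe annotation covering all tested probes.
#' @param config A [dmr_config()].
#' @return An object of class \code{dmr_set}: data.frame with one row per
#'   region (chrom, start, end, n_cpgs, probe_ids (comma-joined), mean_diff,
#'   max_diff, direction, fisher_p, region_q), plus the config as attribute.
#' @export
call_dmrs <- function(diff, annotation, config = dmr_config()) {
  records <- if (inherits(diff, "diff_screen")) diff$records else diff
  stopifnot(is.data.frame(records))
  annotation <- validate_annotation(annotation)
  miss <- setdiff(records$probe_id, annotation$probe_id)
  if (length(miss)) stop("diff records cover unannotated probes: ", miss[1L])

  d <- merge(records, annotation[, c("probe_id", "chrom", "pos")], by = "probe_id")
  regions <- list()
  for (ch in unique(d$chrom)) {
    dc <- d[d$chrom == ch, , drop = FALSE]
    dc <- dc[order(dc$pos), , drop = FALSE]
    if (anyDuplicated(dc$pos)) stop("duplicate probe positions on ", ch)
    seeds <- dc[dc$q_value < config$cpg_fdr_cut, , drop = FALSE]
    if (nrow(seeds) < config$min_cpgs) next
    run_id <- cumsum(c(1L, diff(seeds$pos) >= config$max_gap))
    for (r in split(seeds, run_id)) {
      for (sub in split_direction_runs(r)) {
        if (nrow(sub) < config$min_cpgs) next
        mean_diff <- mean(sub$mean_beta_diff)
        if (abs(mean_diff) <= config$min_mean_diff) next
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = ch, start = min(sub$pos), end = max(sub$pos),
          n_cpgs = nrow(sub),
          probe_ids = paste(sub$probe_id, collapse = ","),
          mean_diff = mean_diff,
          max_diff = sub$mean_beta_diff[which.max(abs(sub$mean_beta_diff))],
          direction = if (mean_diff > 0) "hyper" else "hypo",
          fisher_p = combine_region_p(sub$p_value),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpgs = integer(), probe_ids = character(),
               mean_diff = numeric(), max_diff = numeric(),
               direction = character(), fisher_p = numeric(),
               stringsAsFactors = FALSE)
  out$region_q <- if (nrow(out)) bh_fdr(out$fisher_p) else numeric()
  out <- out[order(-abs(out$mean_diff), out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("dmr_set", "data.frame"), config = config)
}

#' Split a candidate run of seed CpGs into same-direction sub-runs
#'
#' Maximal sub-runs of consistent differential sign; callers re-check
#' \code{min_cpgs} on each sub-run.
#'
#' @param run data.frame of seed CpGs, position-ordered, with a
#'   \code{mean_beta_diff} column.
#' @return List of data.frames.
#' @export
split_direction_runs <- function(run) {
  if (!nrow(run)) return(list())
  sgn <- sign(run$mean_beta_diff)
  grp <- cumsum(c(1L, diff(sgn) != 0))
  unname(split(run, grp))
}

#' Combine member p-values by Fisher's method
#'
#' \eqn{\chi^2 = -2 \sum \log p} on \eqn{2k} degrees of freedom. Zero
#' p-values are clamped at 1e-300 with a warning.
#'
#' @param p Member p-values.
#' @return The combined p-value.
#' @export
combine_region_p <- function(p) {
  if (any(p == 0)) {
    warning("zero member p-value clamped at 1e-300")
    p <- pmax(p, 1e-300)
  }
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("dmr_set: %d regions (%d hyper, %d hypo)\n", nrow(x),
              sum(x$direction == "hyper"), sum(x$direction == "hypo")))
  if (nrow(x)) {
    cat("top regions by |mean differential|:\n")
    print.data.frame(utils::head(x[, c("chrom", "start", "end", "n_cpgs",
                                       "mean_diff", "max_diff", "direction")], 5L),
                     digits = 3)
  }
  invisible(x)
}

#' Export DMRs as a BED table
#'
#' Converts the 1-based inclusive probe spans to BED's 0-based half-open
#' coordinates.
#'
#' @param dmrs A \code{dmr_set}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
                    name = sprintf("DMR_%s_%d", dmrs$direction, seq_len(nrow(dmrs))),
                    score = round(abs(dmrs$mean_diff)), strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
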