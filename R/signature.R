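#' Build the proliferation methylation signature
#'
#' Intersects the three per-index positive-correlation hit sets and,
#' separately, the three negative-correlation hit sets, then keeps only
#' highly dynamic members: probes whose beta standard deviation exceeds
#' \code{sd_threshold} (beta scale; 0.10 corresponds to the 10-percent
#' convention). The two directional intersections must be disjoint — an
#' overlap signals inconsistent upstream screens and is an error.
#'
#' @param pc_sets,nc_sets Lists of three probe-id vectors each (one per
#'   proliferation index).
#' @param beta_sd Named numeric vector of per-probe beta SDs covering every
#'   intersected member.
#' @param sd_threshold Minimum beta SD (default 0.10).
#' @return An object of class \code{prolif_signature}: data.frame of
#'   \code{probe_id}, \code{direction} (PC/NC), \code{beta_sd}; attributes
#'   carry the provenance sizes (3-way PC and NC intersections, post-filter
#'   total) and the threshold.
#' @export
build_signature <- function(pc_sets, nc_sets, beta_sd, sd_threshold = 0.10) {
  if (length(pc_sets) != 3L || length(nc_sets) != 3L)
    stop("exactly three PC and three NC hit sets required")
  pc <- Reduce(intersect, pc_sets)
  nc <- Reduce(intersect, nc_sets)
  both <- intersect(pc, nc)
  if (length(both))
    stop("probes in both PC and NC intersections (inconsistent screens): ",
         both[1L])
  all_ids <- c(pc, nc)
  miss <- setdiff(all_ids, names(beta_sd))
  if (length(miss)) stop("beta_sd missing for probe ", miss[1L])
  df <- data.frame(probe_id = all_ids,
                   direction = rep(c("PC", "NC"), c(length(pc), length(nc))),
                   beta_sd = unname(beta_sd[all_ids]),
                   stringsAsFactors = FALSE)
  df <- df[df$beta_sd > sd_threshold, , drop = FALSE]
  df <- df[order(df$direction, df$probe_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("prolif_signature", "data.frame"),
            provenance = list(n_pc_intersect = length(pc),
                              n_nc_intersect = length(nc),
                              n_final = nrow(df)),
            sd_threshold = sd_threshold)
}

#' Signature from three correlation screens
#'
#' Convenience wrapper: extracts the directional hit sets of three
#' \code{corr_screen} objects (order-invariant) and the per-probe beta SDs,
#' then calls [build_signature()].
#'
#' @param screens List of three \code{corr_screen} objects.
#' @param sd_threshold Minimum beta SD (default 0.10).
#' @return A \code{prolif_signature}.
#' @export
signature_from_screens <- function(screens, sd_threshold = 0.10) {
  stopifnot(length(screens) == 3L,
            all(vapply(screens, inherits, logical(1L), "corr_screen")))
  hits <- lapply(screens, corr_hit_sets)
  sds <- do.call(c, unname(lapply(screens, function(s)
    stats::setNames(s$records$beta_sd, s$records$probe_id))))
  sds <- sds[!duplicated(names(sds))]
  build_signature(lapply(hits, `[[`, "PC"), lapply(hits, `[[`, "NC"),
                  sds, sd_threshold)
}

#' @export
print.prolif_signature <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("prolif_signature: %d CpGs (%d PC, %d NC)\n", nrow(x),
              sum(x$direction == "PC"), sum(x$direction == "NC")))
  cat(sprintf("  3-way intersections: %d PC, %d NC; beta SD > %g kept %d\n",
              pv$n_pc_intersect, pv$n_nc_intersect, attr(x, "sd_threshold"),
              pv$n_final))
  invisible(x)
}

#' Complete-linkage hierarchical clustering of a signature submatrix
#'
#' Agglomerative clustering with Euclidean distance and complete linkage,
#' run independently on samples (columns) and probes (rows) of the beta
#' submatrix over the signature probes — the metric pair used for
#' proliferation-signature heat maps.
#'
#' @param beta Beta submatrix (signature probes x samples).
#' @param k Number of sample clusters for the cut (default 2).
#' @return An object of class \code{meth_clust}: list with \code{sample_hclust},
#'   \code{probe_hclust}, \code{sample_order}, \code{probe_order},
#'   \code{cut} (sample assignments at \code{k}).
#' @export
hierarchical_cluster <- function(beta, k = 2L) {
  if (!is.matrix(beta) || nrow(beta) < 1L) stop("non-empty matrix required")
  if (ncol(beta) < 2L) stop("at least 2 samples required")
  sh <- stats::hclust(stats::dist(t(beta), method = "euclidean"),
                      method = "complete")
  ph <- if (nrow(beta) >= 2L)
    stats::hclust(stats::dist(beta, method = "euclidean"), method = "complete")
  else NULL
  structure(list(
    sample_hclust = sh, probe_hclust = ph,
    sample_order = colnames(beta)[sh$order],
    probe_order = if (is.null(ph)) rownames(beta) else rownames(beta)[ph$order],
    cut = stats::cutree(sh, k = min(k, ncol(beta)))),
    class = "meth_clust")
}

#' @export
print.meth_clust <- function(x, ...) {
  cat(sprintf("meth_clust: %d samples, %d probes; cut at k = %d (sizes %s)\n",
              length(x$sample_order), length(x$probe_order),
              max(x$cut), paste(tabulate(x$cut), collapse = "/")))
  invisible(x)
}

#' Per-sample signature methylation profile
#'
#' Mean beta over the signature's NC members and over its PC members, per
#' sample — the numeric companion to the heat-map reading: on proliferative
#' cohorts the NC mean falls with the proliferation score.
#'
#' @param beta Beta matrix covering the signature probes.
#' @param signature A \code{prolif_signature}.
#' @return data.frame with \code{sample_id}, \code{nc_mean}, \code{pc_mean}.
#' @export
signature_sample_profile <- function(beta, signature) {
  stopifnot(inherits(signature, "prolif_signature"))
  miss <- setdiff(signature$probe_id, rownames(beta))
  if (length(miss)) stop("beta matrix lacks signature probe ", miss[1L])
  one_dir <- function(dir) {
    ids <- signature$probe_id[signature$direction == dir]
    if (!length(ids)) return(rep(NA_real_, ncol(beta)))
    colMeans(beta[ids, , drop = FALSE])
  }
  data.frame(sample_id = colnames(beta),
             nc_mean = one_dir("NC"), pc_mean = one_dir("PC"),
             stringsAsFactors = FALSE)
}
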