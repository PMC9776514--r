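#' Pipeline configuration
#'
#' Collects every stage threshold in one object. \code{sim} is a list of
#' [sim_config()] arguments (used when no \code{cohort_dir} is given);
#' \code{dmr} a list of [dmr_config()] arguments. The resolved configuration
#' is written beside the outputs of every run.
#'
#' @param seed Integer seed for the whole run.
#' @param cohort_dir Optional directory holding beta.tsv / annotation.tsv /
#'   samples.tsv to analyse instead of simulating.
#' @param sim Named list of [sim_config()] overrides.
#' @param fdr_cut FDR cutoff shared by the differential and correlation
#'   screens (default 0.05).
#' @param dmr Named list of [dmr_config()] overrides.
#' @param sd_threshold Signature dynamics filter on beta SD (default 0.10).
#' @param uni_p_select Named list with \code{pfs} and \code{os} univariate
#'   selection cutoffs (defaults 1e-5, 1e-4).
#' @param enrich_p_cut Univariate p cutoff defining enrichment hit sets
#'   (default 1e-4).
#' @param enrich_regions Character vector of region labels (default
#'   \code{c("chr1q", "chr20")}).
#' @param use_m_values,grade_dummy Flags forwarded to [survival_screen()].
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, cohort_dir = NULL, sim = list(),
                            fdr_cut = 0.05, dmr = list(), sd_threshold = 0.10,
                            uni_p_select = list(pfs = 1e-5, os = 1e-4),
                            enrich_p_cut = 1e-4,
                            enrich_regions = c("chr1q", "chr20"),
                            use_m_values = FALSE, grade_dummy = FALSE) {
  if (fdr_cut <= 0 || fdr_cut >= 1) stop("fdr_cut must lie in (0, 1)")
  if (sd_threshold < 0 || sd_threshold >= 1) stop("sd_threshold must lie in [0, 1)")
  for (nm in c("pfs", "os"))
    if (uni_p_select[[nm]] <= 0 || uni_p_select[[nm]] > 1)
      stop("uni_p_select$", nm, " must lie in (0, 1]")
  structure(list(seed = as.integer(seed), cohort_dir = cohort_dir, sim = sim,
                 fdr_cut = fdr_cut, dmr = dmr, sd_threshold = sd_threshold,
                 uni_p_select = uni_p_select, enrich_p_cut = enrich_p_cut,
                 enrich_regions = enrich_regions,
                 use_m_values = use_m_values, grade_dummy = grade_dummy),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full methylome-proliferation analysis
#'
#' Orchestrates simulate (or load) -> differential screen -> DMR calling ->
#' three correlation screens -> overlap structure -> signature + clustering
#' -> PFS/OS survival screens -> region enrichment, writing every stage
#' table plus a consolidated machine-readable report. Deterministic given
#' the seed: two runs with the same configuration produce byte-identical
#' reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return An object of class \code{meth_pipeline}: list with all stage
#'   objects and the \code{report} list; written artifacts under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("methprolif %s | R %s | seed %d\n",
              as.character(utils::packageVersion("methprolif")),
              paste(R.version$major, R.version$minor, sep = "."), config$seed),
      file = log_path)
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    cat(sprintf("stage %-12s %8.2f s\n", name, proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    res
  }

  stage_cohort <- stage("cohort", {
    if (!is.null(config$cohort_dir)) {
      list(cohort = load_cohort(file.path(config$cohort_dir, "beta.tsv"),
                                file.path(config$cohort_dir, "annotation.tsv"),
                                file.path(config$cohort_dir, "samples.tsv")),
           truth = NULL)
    } else {
      sim <- simulate_cohort(do.call(sim_config, c(list(seed = config$seed),
                                                   config$sim)))
      write_truth(sim$truth, file.path(out_dir, "truth.tsv"))
      sim
    }
  })
  cohort <- stage_cohort$cohort
  truth <- stage_cohort$truth

  diff <- stage("diff", diff_screen(cohort, fdr_cut = config$fdr_cut))
  write_screen_table(diff$records, file.path(out_dir, "diff.tsv"))

  dmrs <- stage("dmr", call_dmrs(diff, cohort$annotation,
                                 do.call(dmr_config, config$dmr)))
  write_screen_table(as.data.frame(dmrs), file.path(out_dir, "dmrs.tsv"))

  idx_names <- c("mitotic_index", "ki67", "mcm6")
  corr <- stage("correlate", lapply(idx_names, function(ix)
    correlation_screen(cohort, ix, fdr_cut = config$fdr_cut)))
  names(corr) <- idx_names
  for (ix in idx_names)
    write_screen_table(corr[[ix]]$records,
                       file.path(out_dir, paste0("corr_", ix, ".tsv")))

  overlaps <- stage("overlaps", {
    sig_diff <- diff$records[diff$records$q_value < config$fdr_cut, ]
    hits <- c(list(grade_hyper = sig_diff$probe_id[sig_diff$direction == "hyper"],
                   grade_hypo = sig_diff$probe_id[sig_diff$direction == "hypo"]),
              unlist(lapply(idx_names, function(ix) {
                h <- corr_hit_sets(corr[[ix]])
                stats::setNames(h, paste0(ix, "_", names(h)))
              }), recursive = FALSE))
    overlap_structure(hits, cohort$annotation)
  })
  write_screen_table(as.data.frame(overlaps), file.path(out_dir, "overlaps.tsv"))

  signature <- stage("signature",
                     signature_from_screens(corr, config$sd_threshold))
  write_screen_table(as.data.frame(signature), file.path(out_dir, "signature.tsv"))
  clust <- NULL
  if (nrow(signature) >= 2L) {
    clust <- stage("cluster",
                   hierarchical_cluster(cohort$beta[signature$probe_id, , drop = FALSE]))
    profile <- signature_sample_profile(cohort$beta, signature)
    write_screen_table(profile, file.path(out_dir, "signature_profile.tsv"))
  }

  surv <- list()
  for (ep in c("pfs", "os")) {
    surv[[ep]] <- stage(paste0("survive_", ep),
                        survival_screen(cohort, ep,
                                        uni_p_select = config$uni_p_select[[ep]],
                                        use_m_values = config$use_m_values,
                                        grade_dummy = config$grade_dummy))
    write_screen_table(surv[[ep]]$records,
                       file.path(out_dir, paste0("surv_", ep, ".tsv")))
  }

  enrich <- stage("enrich", {
    r <- surv$pfs$records
    hits <- r$probe_id[!r$flagged & r$uni_wald_p < config$enrich_p_cut]
    background <- r$probe_id[!r$flagged]
    do.call(rbind, lapply(config$enrich_regions, function(reg)
      region_enrichment(hits, background, cohort$annotation, reg)))
  })
  write_screen_table(as.data.frame(enrich), file.path(out_dir, "enrich.tsv"))

  report <- list(
    seed = config$seed,
    n_probes = nrow(cohort$beta), n_samples = ncol(cohort$beta),
    differential = diff$summary,
    dmr = list(n_regions = nrow(dmrs),
               n_hyper = sum(dmrs$direction == "hyper"),
               n_hypo = sum(dmrs$direction == "hypo")),
    correlation = lapply(corr, summary),
    overlap_order2 = {
      o2 <- overlaps[overlaps$order == 2L, c("sets", "size")]
      stats::setNames(as.list(o2$size), o2$sets)
    },
    signature = c(attr(signature, "provenance"),
                  list(sd_threshold = attr(signature, "sd_threshold"),
                       n_pc = sum(signature$direction == "PC"),
                       n_nc = sum(signature$direction == "NC"))),
    survival = lapply(surv, summary),
    enrichment = lapply(seq_len(nrow(enrich)), function(i)
      as.list(enrich[i, c("region", "hits_in", "hits_total", "bg_in",
                          "bg_total", "fold", "chi2_p")]))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  cat(sprintf("total %19.2f s\n", proc.time()[["elapsed"]] - t_all),
      file = log_path, append = TRUE)

  structure(list(config = config, cohort = cohort, truth = truth, diff = diff,
                 dmrs = dmrs, corr = corr, overlaps = overlaps,
                 signature = signature, clust = clust, surv = surv,
                 enrich = enrich, report = report, out_dir = out_dir),
            class = "meth_pipeline")
}

#' @export
print.meth_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf("meth_pipeline (seed %d): %d probes x %d samples -> %s\n",
              r$seed, r$n_probes, r$n_samples, x$out_dir))
  cat(sprintf("  differential: %d significant (%d hyper / %d hypo)\n",
              r$differential$n_sig, r$differential$n_hyper, r$differential$n_hypo))
  cat(sprintf("  DMRs: %d (%d hyper / %d hypo)\n",
              r$dmr$n_regions, r$dmr$n_hyper, r$dmr$n_hypo))
  for (ix in names(r$correlation))
    cat(sprintf("  %s: %d significant (%d PC / %d NC)\n", ix,
                r$correlation[[ix]]$n_sig, r$correlation[[ix]]$n_PC,
                r$correlation[[ix]]$n_NC))
  cat(sprintf("  signature: %d CpGs (PC intersect %d, NC intersect %d)\n",
              r$signature$n_final, r$signature$n_pc_intersect,
              r$signature$n_nc_intersect))
  for (ep in names(r$survival))
    cat(sprintf("  %s: %d univariate hits, %d multivariate (%d protective)\n",
                toupper(ep), r$survival[[ep]]$n_uni_hits,
                r$survival[[ep]]$n_multi, r$survival[[ep]]$n_protective))
  invisible(x)
}

#' @export
summary.meth_pipeline <- function(object, ...) object$report
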