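#' Genome-wide per-CpG Cox survival screen
#'
#' For every probe, a univariate Cox model of the endpoint on the probe's
#' methylation (beta scale by default, so coefficients read as log hazard
#' ratio per full methylation change), followed by the scaled-Schoenfeld
#' proportional-hazards gate: a probe is retained only when both the
#' methylation covariate's PH p-value and the model's global PH p-value
#' exceed 0.05. Retained probes whose univariate Wald p falls below
#' \code{uni_p_select} proceed to a multivariate fit with age (continuous)
#' and WHO grade (ordinal numeric 1/2/3 by default; dummy coding by flag).
#' Sign convention: a positive coefficient means higher hazard, so
#' methylation "protective" of survival corresponds to a negative
#' multivariate coefficient.
#'
#' @param cohort A [meth_cohort()] object.
#' @param endpoint \code{"pfs"} or \code{"os"}.
#' @param uni_p_select Univariate Wald p cutoff for multivariate follow-up;
#'   defaults 1e-5 for PFS and 1e-4 for OS.
#' @param ph_alpha PH-gate level (default 0.05).
#' @param use_m_values Model the M-value instead of the beta value.
#' @param grade_dummy Dummy-code grade (two indicator columns) instead of the
#'   ordinal numeric default.
#' @param run_multivariate Set \code{FALSE} to stop after the univariate
#'   screen and PH gate.
#' @return An object of class \code{surv_screen}: list with \code{records}
#'   (one row per probe: univariate coef/HR/Wald p, PH p-values, retained
#'   flag, multivariate coef/Wald p and effect direction for probes taken
#'   forward), \code{endpoint}, \code{uni_p_select} and a \code{summary}.
#' @export
survival_screen <- function(cohort, endpoint = c("pfs", "os"),
                            uni_p_select = NULL, ph_alpha = 0.05,
                            use_m_values = FALSE, grade_dummy = FALSE,
                            run_multivariate = TRUE) {
  stopifnot(inherits(cohort, "meth_cohort"))
  endpoint <- match.arg(endpoint)
  if (is.null(uni_p_select))
    uni_p_select <- if (endpoint == "pfs") 1e-5 else 1e-4
  if (uni_p_select <= 0 || uni_p_select > 1) stop("uni_p_select must lie in (0, 1]")
  time <- cohort$samples[[paste0(endpoint, "_months")]]
  event <- cohort$samples[[paste0(endpoint, "_event")]]
  if (!any(event)) stop("no events for endpoint ", endpoint)

  vals <- if (use_m_values) cohort_m_values(cohort) else cohort$beta
  X <- t(vals)                                     # samples x probes
  scr <- cox_uni_screen(X, time, event)
  ph <- cox_uni_ph(scr)

  retained <- !scr$flagged & ph$covariate_p > ph_alpha & ph$global_p > ph_alpha
  records <- data.frame(
    probe_id = rownames(cohort$beta),
    endpoint = toupper(endpoint),
    uni_coef = scr$coef, uni_hr = exp(scr$coef),
    uni_wald_p = scr$wald_p,
    ph_covariate_p = ph$covariate_p, ph_global_p = ph$global_p,
    flagged = scr$flagged, retained = retained,
    multi_coef = NA_real_, multi_wald_p = NA_real_,
    effect_direction = NA_character_,
    stringsAsFactors = FALSE)
  if (any(scr$flagged))
    warning(sprintf("%d probe(s) flagged (non-convergent or degenerate) and excluded from gating",
                    sum(scr$flagged)), call. = FALSE)

  if (run_multivariate) {
    sel <- which(retained & records$uni_wald_p < uni_p_select)
    grade_cov <- if (grade_dummy)
      cbind(grade2 = as.numeric(cohort$samples$grade == 2L),
            grade3 = as.numeric(cohort$samples$grade == 3L))
    else cbind(grade = as.numeric(cohort$samples$grade))
    for (i in sel) {
      xi <- cbind(meth = X[, i], age = as.numeric(cohort$samples$age), grade_cov)
      fit <- tryCatch(fit_cox(time, event, xi), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      records$multi_coef[i] <- fit$coef[["meth"]]
      records$multi_wald_p[i] <- fit$wald_p[["meth"]]
      records$effect_direction[i] <-
        if (fit$coef[["meth"]] < 0) "protective" else "deleterious"
    }
  }
  records <- records[order(records$uni_wald_p, records$probe_id), , drop = FALSE]
  rownames(records) <- NULL
  res <- structure(list(records = records, endpoint = toupper(endpoint),
                        uni_p_select = uni_p_select, ph_alpha = ph_alpha),
                   class = "surv_screen")
  res$summary <- summarize_surv(res)
  res
}

summarize_surv <- function(x) {
  r <- x$records
  multi <- r[!is.na(r$multi_coef), , drop = FALSE]
  list(n_tested = nrow(r), n_retained = sum(r$retained),
       n_uni_hits = sum(r$retained & r$uni_wald_p < x$uni_p_select),
       n_multi = nrow(multi),
       n_protective = sum(multi$effect_direction == "protective"),
       n_deleterious = sum(multi$effect_direction == "deleterious"))
}

#' @export
print.surv_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf("surv_screen [%s]: %d probes, %d pass the PH gate\n",
              x$endpoint, s$n_tested, s$n_retained))
  cat(sprintf("  univariate hits at p < %g: %d; multivariate fits: %d (%d protective, %d deleterious)\n",
              x$uni_p_select, s$n_uni_hits, s$n_multi, s$n_protective,
              s$n_deleterious))
  invisible(x)
}

#' @export
summary.surv_screen <- function(object, ...) object$summary

#' Chromosome-region enrichment of survival hits
#'
#' Fold enrichment of a hit set within a chromosome (e.g. \code{"chr20"}) or
#' chromosome arm (e.g. \code{"chr1q"}) against a background probe set, with
#' a Pearson chi-squared test on the 2x2 table (hit/non-hit by in/out of
#' region), no continuity correction.
#'
#' @param hits Probe-id vector; must be a subset of \code{background}.
#' @param background Probe-id vector (the screen's tested universe).
#' @param annotation Probe annotation.
#' @param region Region label: \code{"chrN"} or \code{"chrNp"}/\code{"chrNq"}.
#' @return An object of class \code{enrichment_result}: one-row data.frame
#'   with region, counts, \code{fold} and \code{chi2_p}.
#' @export
region_enrichment <- function(hits, background, annotation, region) {
  annotation <- validate_annotation(annotation)
  if (length(setdiff(hits, background))) stop("hits must be a subset of background")
  m <- regmatches(region, regexec("^(chr[0-9]+)([pq]?)$", region))[[1L]]
  if (!length(m)) stop("region must look like 'chr1', 'chr1p' or 'chr1q'")
  in_region <- annotation$chrom == m[2L]
  if (nzchar(m[3L])) in_region <- in_region & annotation$chrom_arm == m[3L]
  region_probes <- annotation$probe_id[in_region]

  hits_in <- sum(hits %in% region_probes)
  bg_in <- sum(background %in% region_probes)
  if (bg_in == 0L) stop("no background probes in region ", region)
  hits_total <- length(hits); bg_total <- length(background)
  fold <- (hits_in / hits_total) / (bg_in / bg_total)

  # 2x2: hit / non-hit x in / out of region
  o <- matrix(c(hits_in, hits_total - hits_in,
                bg_in - hits_in, (bg_total - hits_total) - (bg_in - hits_in)),
              2L, 2L, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  chi2 <- sum((o - e)^2 / e)
  structure(data.frame(region = region, hits_in = hits_in,
                       hits_total = hits_total, bg_in = bg_in,
                       bg_total = bg_total, fold = fold, chi2 = chi2,
                       chi2_p = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment [%s]: %d/%d hits vs %d/%d background; fold = %.2f, chi2 p = %.3g\n",
              x$region, x$hits_in, x$hits_total, x$bg_in, x$bg_total,
              x$fold, x$chi2_p))
  invisible(x)
}
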