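#' @keywords internal
"_PACKAGE"

CGI_LEVELS  <- c("island", "shore", "shelf", "open_sea")
GENE_LEVELS <- c("promoter", "body", "intergenic")
AUTOSOMES   <- paste0("chr", 1:22)

#' Construct a methylation cohort object
#'
#' Bundles the three tables every screen consumes: a probes-x-samples beta
#' matrix, a probe annotation table and a sample sheet. Performs the full
#' validation battery: beta range, missing values, key uniqueness, key
#' agreement between tables, annotation level checks.
#'
#' @param beta Numeric matrix of beta values, rownames = probe ids,
#'   colnames = sample ids.
#' @param annotation data.frame with columns \code{probe_id, chrom, pos,
#'   chrom_arm, cgi_context, gene_context, gene_symbols}.
#' @param samples data.frame with columns \code{sample_id, grade,
#'   mitotic_index, ki67_li, mcm6_li, age, sex, pfs_months, pfs_event,
#'   os_months, os_event}.
#' @return An object of class \code{meth_cohort}: a list with elements
#'   \code{beta}, \code{annotation}, \code{samples}.
#' @export
meth_cohort <- function(beta, annotation, samples) {
  if (!is.matrix(beta) || !is.numeric(beta)) stop("`beta` must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("`beta` must carry probe rownames and sample colnames")
  if (anyNA(beta)) {
    idx <- which(is.na(beta), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing beta value at probe '%s', sample '%s' (no imputation)",
                 rownames(beta)[idx[1L]], colnames(beta)[idx[2L]]))
  }
  bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value %.4g outside [0, 1] at probe '%s', sample '%s'",
                 beta[bad[1L, , drop = FALSE]],
                 rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]]))
  }
  if (anyDuplicated(rownames(beta))) stop("duplicated probe ids in beta matrix")
  if (anyDuplicated(colnames(beta))) stop("duplicated sample ids in beta matrix")

  annotation <- validate_annotation(annotation)
  samples    <- validate_samples(samples)

  # inner join on probes, annotation order wins
  keep <- annotation$probe_id %in% rownames(beta)
  if (!all(keep)) {
    message(sprintf("dropping %d annotated probe(s) absent from beta matrix", sum(!keep)))
    annotation <- annotation[keep, , drop = FALSE]
  }
  extra <- setdiff(rownames(beta), annotation$probe_id)
  if (length(extra))
    warning(sprintf("%d probe(s) in beta matrix lack annotation and were dropped",
                    length(extra)), call. = FALSE)
  if (!nrow(annotation)) stop("no probes shared between beta matrix and annotation")
  beta <- beta[annotation$probe_id, , drop = FALSE]

  if (!setequal(colnames(beta), samples$sample_id))
    stop("sample ids differ between beta matrix and sample sheet")
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  rownames(annotation) <- NULL

  structure(list(beta = beta, annotation = annotation, samples = samples),
            class = "meth_cohort")
}

validate_annotation <- function(annotation) {
  req <- c("probe_id", "chrom", "pos", "chrom_arm", "cgi_context",
           "gene_context", "gene_symbols")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  annotation <- as.data.frame(annotation)[req]
  if (anyDuplicated(annotation$probe_id)) stop("duplicated probe_id in annotation")
  if (!all(annotation$chrom %in% AUTOSOMES))
    stop("annotation chrom must be autosomal (chr1..chr22)")
  annotation$pos <- as.integer(annotation$pos)
  if (any(is.na(annotation$pos)) || any(annotation$pos < 1L))
    stop("annotation pos must be integer >= 1")
  if (!all(annotation$chrom_arm %in% c("p", "q"))) stop("chrom_arm must be 'p' or 'q'")
  if (!all(annotation$cgi_context %in% CGI_LEVELS))
    stop("cgi_context must be one of: ", paste(CGI_LEVELS, collapse = ", "))
  if (!all(annotation$gene_context %in% GENE_LEVELS))
    stop("gene_context must be one of: ", paste(GENE_LEVELS, collapse = ", "))
  annotation$gene_symbols <- as.character(annotation$gene_symbols)
  annotation$gene_symbols[is.na(annotation$gene_symbols)] <- ""
  annotation
}

validate_samples <- function(samples) {
  req <- c("sample_id", "grade", "mitotic_index", "ki67_li", "mcm6_li", "age",
           "sex", "pfs_months", "pfs_event", "os_months", "os_event")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[req]
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id in sample sheet")
  if (!all(samples$grade %in% 1:3)) stop("grade must be in {1, 2, 3}")
  if (any(samples$mitotic_index < 0)) stop("mitotic_index must be non-negative")
  for (li in c("ki67_li", "mcm6_li"))
    if (any(samples[[li]] < 0 | samples[[li]] > 100))
      stop(li, " must lie in [0, 100]")
  if (!all(samples$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  for (tm in c("pfs_months", "os_months"))
    if (any(samples[[tm]] <= 0)) stop(tm, " must be > 0")
  for (ev in c("pfs_event", "os_event"))
    samples[[ev]] <- as.logical(samples[[ev]])
  if (anyNA(samples)) stop("missing values in sample sheet")
  samples
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("meth_cohort: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  cat("  grades:", paste(sprintf("%d (n=%d)", 1:3,
                                 tabulate(x$samples$grade, 3L)), collapse = ", "), "\n")
  cgi <- table(factor(x$annotation$cgi_context, CGI_LEVELS))
  cat("  CGI strata:", paste(sprintf("%s=%d", names(cgi), cgi), collapse = ", "), "\n")
  invisible(x)
}

#' M-value view of a cohort's beta matrix
#'
#' @param cohort A [meth_cohort()] object.
#' @param eps Clipping constant passed to [beta_to_m()].
#' @return Numeric matrix of M-values, same dimnames as the beta matrix.
#' @export
cohort_m_values <- function(cohort, eps = 1e-3) {
  stopifnot(inherits(cohort, "meth_cohort"))
  m <- beta_to_m(cohort$beta, eps = eps)
  dim(m) <- dim(cohort$beta)
  dimnames(m) <- dimnames(cohort$beta)
  m
}

#' Load a cohort from the three tab-separated interchange files
#'
#' Reads the beta matrix (first column \code{probe_id}, remaining columns
#' sample ids), the probe annotation and the sample sheet, then validates and
#' joins them via [meth_cohort()]. Probes are kept in annotation order
#' (inner join); any mismatch in sample ids is an error.
#'
#' @param beta_path,annotation_path,sample_sheet_path Paths to the TSV files.
#' @return A [meth_cohort()] object.
#' @export
load_cohort <- function(beta_path, annotation_path, sample_sheet_path) {
  for (p in c(beta_path, annotation_path, sample_sheet_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bt <- utils::read.delim(beta_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(bt)[1L] != "probe_id") stop("beta matrix must start with a probe_id column")
  if (anyDuplicated(bt$probe_id)) stop("duplicated probe_id in beta matrix file")
  beta <- as.matrix(bt[, -1L, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- bt$probe_id
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  ss  <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  cohort <- meth_cohort(beta, ann, ss)
  message(sprintf("loaded cohort: %d probes, %d samples",
                  nrow(cohort$beta), ncol(cohort$beta)))
  cohort
}

#' Write a cohort back to the three interchange TSVs
#'
#' @param cohort A [meth_cohort()] object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (beta, annotation, samples).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("beta.tsv", "annotation.tsv", "samples.tsv"))
  bt <- data.frame(probe_id = rownames(cohort$beta), cohort$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(bt, paths[1L])
  write_tsv(cohort$annotation, paths[2L])
  ss <- cohort$samples
  ss$pfs_event <- as.integer(ss$pfs_event)
  ss$os_event  <- as.integer(ss$os_event)
  write_tsv(ss, paths[3L])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a per-probe screen table
#'
#' Tab-separated, one row per record, deterministic column order and stable
#' float formatting: p/q-value columns in scientific notation, other numeric
#' columns at full precision via \code{format(..., digits = 15)}.
#'
#' @param records data.frame of screen records sharing a schema.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_screen_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    if (grepl("(^|_)(p|q)(_value)?$|_p$|_q$", nm)) {
      out[[nm]] <- formatC(out[[nm]], format = "e", digits = 6)
    } else {
      out[[nm]] <- vapply(out[[nm]], function(v)
        format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1L))
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file (optional external validation loader)
#'
#' Minimal reader for the uncompressed `series_matrix.txt` layout used by GEO
#' methylation submissions (e.g. accession GSE200321 for external validation):
#' returns the probes-x-samples value matrix between the
#' \code{!series_matrix_table_begin}/\code{end} markers. Never used by the
#' test-suite; provided for users holding a local copy of the series matrix.
#'
#' @param path Path to an uncompressed series-matrix text file.
#' @return Numeric matrix, probe ids as rownames.
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series-matrix table found in ", path)
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  m
}
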