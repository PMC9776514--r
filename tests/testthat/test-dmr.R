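# records table for hand-built DMR fixtures
dmr_records <- function(pos, diffs, q = 0.01, p = q / 10) {
  data.frame(probe_id = sprintf("p%03d", seq_along(pos)),
             mean_beta_diff = diffs, p_value = p, q_value = q,
             mean_m_diff = sign(diffs), stringsAsFactors = FALSE)
}

test_that("gap, size and effect constraints shape the called regions", {
  ann <- tiny_annotation(4L, pos = c(100L, 400L, 800L, 1900L))
  rec <- dmr_records(c(100, 400, 800, 1900), c(-45, -40, -38, -42))
  dm <- call_dmrs(rec, ann)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$start, 100L)
  expect_equal(dm$end, 800L) # the 1900 bp probe is cut off by the 1100 bp gap
  expect_equal(dm$n_cpgs, 3L)
  expect_equal(dm$direction, "hypo")
  expect_equal(dm$mean_diff, mean(c(-45, -40, -38)))
  expect_equal(dm$max_diff, -45)

  # two adjacent significant CpGs only: below min_cpgs
  ann2 <- tiny_annotation(2L, pos = c(100L, 300L))
  expect_equal(nrow(call_dmrs(dmr_records(c(100, 300), c(30, 35)), ann2)), 0L)

  # mean differential at or below 10 percent is not emitted
  ann3 <- tiny_annotation(3L, pos = c(100L, 300L, 500L))
  expect_equal(nrow(call_dmrs(dmr_records(1:3, c(9, 10, 11)), ann3)), 0L)
  expect_equal(nrow(call_dmrs(dmr_records(c(100, 300, 500), c(12, 15, 11)), ann3)), 1L)
})

test_that("direction splitting yields maximal same-sign sub-runs", {
  run <- dmr_records(1:6, c(5, 6, -7, 8, 9, 10))
  subs <- split_direction_runs(run)
  expect_length(subs, 3L)
  expect_equal(vapply(subs, nrow, integer(1L)), c(2L, 1L, 3L))

  expect_length(split_direction_runs(dmr_records(1:4, c(5, 6, 7, 8))), 1L)
  alt <- dmr_records(1:4, c(5, -6, 7, -8))
  expect_true(all(vapply(split_direction_runs(alt), nrow, integer(1L)) == 1L))

  # a run mixing signs never yields a mixed-sign DMR
  ann <- tiny_annotation(6L, pos = seq(100L, by = 200L, length.out = 6L))
  dm <- call_dmrs(dmr_records(1:6, c(25, 26, -27, 28, 29, 30)), ann)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$n_cpgs, 3L)
  expect_equal(dm$direction, "hyper")
})

test_that("Fisher combination matches the chi-square definition", {
  expect_equal(combine_region_p(c(0.01, 0.01, 0.01)),
               pchisq(-2 * 3 * log(0.01), df = 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(-2 * 3 * log(0.01), 27.63102, tolerance = 1e-5)
  expect_equal(combine_region_p(rep(1, 4)), 1)
  expect_warning(p0 <- combine_region_p(c(0, 0.5)), "clamped")
  expect_lt(p0, 1e-250)
  # a lone region keeps its Fisher p as region q (BH with m = 1)
  ann <- tiny_annotation(3L, pos = c(100L, 300L, 500L))
  dm <- call_dmrs(dmr_records(c(100, 300, 500), c(20, 22, 24), p = 0.001), ann)
  expect_equal(dm$region_q, dm$fisher_p)
})

test_that("calls are order-invariant and always satisfy the config constraints", {
  sim <- simulate_cohort(sim_config(n_probes = 1500, n_samples = 24, seed = 31,
                                    n_pos_planted = 60, n_neg_planted = 60))
  d <- diff_screen(sim$cohort)
  cfg <- dmr_config()
  dm <- call_dmrs(d, sim$cohort$annotation, cfg)
  perm <- sample(nrow(d$records))
  dm2 <- call_dmrs(d$records[perm, ], sim$cohort$annotation, cfg)
  expect_equal(as.data.frame(dm), as.data.frame(dm2))

  expect_true(all(dm$n_cpgs >= cfg$min_cpgs))
  expect_true(all(abs(dm$mean_diff) > cfg$min_mean_diff))
  expect_true(all(abs(dm$mean_diff) <= abs(dm$max_diff)))
  pos_of <- function(ids) sort(sim$cohort$annotation$pos[
    match(strsplit(ids, ",")[[1L]], sim$cohort$annotation$probe_id)])
  for (i in seq_len(nrow(dm)))
    expect_true(all(diff(pos_of(dm$probe_ids[i])) < cfg$max_gap))
})

test_that("a planted clustered region is recovered as one hyper DMR", {
  sim <- simulate_cohort(sim_config(n_probes = 1500, n_samples = 48, seed = 3,
                                    n_pos_planted = 0, n_neg_planted = 0))
  co <- sim$cohort
  ann <- co$annotation
  # pick a run of 8 consecutive island probes < 1 kb apart on one chromosome
  is_isl <- ann$cgi_context == "island"
  run_start <- NA
  for (i in seq_len(nrow(ann) - 7L)) {
    w <- i:(i + 7L)
    if (all(is_isl[w]) && length(unique(ann$chrom[w])) == 1L &&
        all(diff(ann$pos[w]) < 1000)) { run_start <- i; break }
  }
  expect_false(is.na(run_start))
  member_ids <- ann$probe_id[run_start + 0:7]
  high <- co$samples$grade >= 2
  planted_beta <- co$beta
  planted_beta[member_ids, high] <- pmin(planted_beta[member_ids, high] + 0.3,
                                         0.999)
  co2 <- meth_cohort(planted_beta, ann, co$samples)
  dm <- call_dmrs(diff_screen(co2), ann)
  hits <- dm[vapply(strsplit(dm$probe_ids, ","), function(ids)
    length(intersect(ids, member_ids)) > 0, logical(1L)), , drop = FALSE]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$direction, "hyper")
  expect_gte(length(intersect(strsplit(hits$probe_ids, ",")[[1L]], member_ids)), 6L)
})

test_that("BED export converts to 0-based half-open coordinates", {
  ann <- tiny_annotation(3L, pos = c(100L, 300L, 500L))
  dm <- call_dmrs(dmr_records(c(100, 300, 500), c(20, 22, 24)), ann)
  path <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(dm, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 99L)
  expect_equal(bed$V3, 500L)
})
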