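test_that("Spearman matches the rank-then-Pearson oracle, ties included", {
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$p, 0)
  expect_equal(spearman_test(1:4, 4:1)$rho, -1)

  set.seed(41)
  for (i in 1:30) {
    x <- sample(1:5, 10, replace = TRUE) # heavy ties
    y <- rnorm(10) + x
    st <- spearman_test(x, y)
    expect_equal(st$rho, oracle_spearman(x, y), tolerance = 1e-12)
    # t-approximation p-value
    tstat <- st$rho * sqrt(8 / (1 - st$rho^2))
    expect_equal(st$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  }
  # cross-check against the standard implementation (asymptotic, with ties)
  x <- c(1, 1, 2, 3, 4, 4, 5, 6, 7, 8)
  y <- c(2, 1, 2, 5, 3, 7, 6, 6, 9, 8)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(spearman_test(x, y)$rho, unname(ct$estimate), tolerance = 1e-12)

  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:3, 1:3), "at least 4")
  expect_error(spearman_test(c(1, 2, NA, 4), 1:4), "finite")
})

test_that("methylation level categories follow the boundary conventions", {
  expect_equal(categorize_level(0.3), "low")
  expect_equal(categorize_level(0.7), "high")
  expect_equal(categorize_level(0.5), "medium")
  expect_equal(categorize_level(c(0, 0.30001, 0.69999, 1)),
               c("low", "medium", "medium", "high"))
  expect_error(categorize_level(1.2), "\\[0, 1\\]")
})

test_that("screen records carry correct dynamics metrics and directions", {
  row <- c(0.1, 0.2, 0.3, 0.9)
  beta <- matrix(rep(row, each = 3) + rep(c(0, 0.001, -0.001), 4), 3, 4,
                 dimnames = list(sprintf("p%03d", 1:3), sprintf("s%02d", 1:4)))
  beta[1, ] <- row
  ann <- tiny_annotation(3L)
  ss <- tiny_samples(4L)
  co <- meth_cohort(beta, ann, ss)
  scr <- correlation_screen(co, "mitotic_index")
  r1 <- scr$records[scr$records$probe_id == "p001", ]
  expect_equal(r1$range_maxmin, 80)
  expect_equal(r1$beta_median, 0.25)
  expect_equal(r1$level, "low")
  expect_equal(r1$iqr_q3q1,
               100 * diff(quantile(row, c(0.25, 0.75), names = FALSE)))
  expect_equal(r1$beta_sd, sd(row))
  expect_equal(r1$direction, ifelse(r1$rho > 0, "PC", "NC"))
  expect_true(all(scr$records$range_maxmin >= scr$records$iqr_q3q1))
  # summary recomputable from records
  sig <- scr$records[scr$records$q_value < scr$fdr_cut, ]
  expect_equal(scr$summary$n_sig, nrow(sig))
  expect_equal(scr$summary$n_PC, sum(sig$direction == "PC"))
})

test_that("the screen is invariant under monotone transforms of beta", {
  sim <- simulate_cohort(sim_config(n_probes = 300, n_samples = 20, seed = 43,
                                    n_pos_planted = 20, n_neg_planted = 20))
  co <- sim$cohort
  s1 <- correlation_screen(co, "ki67")
  co2 <- co
  co2$beta <- co$beta^3 # strictly monotone
  s2 <- correlation_screen(co2, "ki67")
  expect_equal(s1$records$rho,
               s2$records$rho[match(s1$records$probe_id, s2$records$probe_id)],
               tolerance = 1e-12)

  ssc <- co$samples; ssc$ki67_li <- 1
  expect_error(correlation_screen(meth_cohort(co$beta, co$annotation, ssc), "ki67"),
               "constant")
  # constant beta rows are dropped from the multiplicity count
  cob <- co$beta; cob[1, ] <- 0.5
  co3 <- meth_cohort(cob, co$annotation, co$samples)
  expect_warning(s3 <- correlation_screen(co3, "ki67"), "constant probe")
  expect_equal(s3$summary$n_tested, nrow(co$beta) - 1L)
})

test_that("overlap structure matches a brute-force power-set oracle", {
  ann <- tiny_annotation(10L)
  ids <- ann$probe_id
  lists <- list(A = ids[1:3], B = ids[2:3], C = ids[3])
  ov <- overlap_structure(lists, ann)
  get_size <- function(sets) ov$size[ov$sets == sets]
  expect_equal(get_size("A+B"), 2L)
  expect_equal(get_size("A+B+C"), 1L)
  expect_equal(get_size("A"), 3L) # inclusive

  disj <- overlap_structure(list(A = ids[1:2], B = ids[3:4], C = ids[5:6]), ann)
  expect_true(all(disj$size[disj$order >= 2] == 0L))

  set.seed(44)
  rand <- lapply(1:4, function(i) sample(ids, sample(0:8, 1)))
  names(rand) <- LETTERS[1:4]
  ov <- overlap_structure(rand, ann)
  for (i in seq_len(nrow(ov))) {
    members <- strsplit(ov$sets[i], "+", fixed = TRUE)[[1L]]
    expect_equal(ov$size[i], length(Reduce(intersect, rand[members])))
  }
  # composition proportions sum to 1 per axis on non-empty intersections
  nonz <- ov[ov$size > 0, ]
  expect_equal(rowSums(nonz[, paste0("cgi_", c("island", "shore", "shelf", "open_sea"))]),
               rep(1, nrow(nonz)), ignore_attr = TRUE)
  expect_error(overlap_structure(list(A = "nope"), ann), "outside the universe")
})

test_that("top-candidate filtering is conjunctive and counts gene hits", {
  sim <- simulate_cohort(sim_config(n_probes = 500, n_samples = 30, seed = 45,
                                    n_pos_planted = 40, n_neg_planted = 40))
  scr <- correlation_screen(sim$cohort, "mitotic_index")
  top <- top_candidate_table(scr, sim$cohort$annotation)
  sig <- scr$records[scr$records$q_value < scr$fdr_cut, ]
  expect_true(all(top$range_maxmin > 50))
  expect_true(all(top$iqr_q3q1 > 10))
  expect_true(all(top$cgi_context %in% c("island", "shore", "shelf") |
                    top$gene_context == "promoter"))
  # excluded: dynamic range high but IQR low
  excl <- sig$probe_id[sig$range_maxmin > 50 & sig$iqr_q3q1 <= 10]
  expect_false(any(excl %in% top$probe_id))
  # per-gene hit counts match a direct recount within direction
  if (nrow(top)) {
    i <- which.max(top$gene_hits)
    gene <- strsplit(top$gene_symbols[i], ";")[[1L]][1]
    ann <- sim$cohort$annotation
    same_dir <- sig[sig$direction == top$direction[i], ]
    syms <- ann$gene_symbols[match(same_dir$probe_id, ann$probe_id)]
    recount <- sum(vapply(strsplit(syms, ";"), function(g) gene %in% g,
                          logical(1L)))
    expect_equal(top$gene_hits[i], recount)
  }
})
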