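test_that("source generation is deterministic and respects proportions", {
  a <- simulate_sources(n_genes = 120, seed = 9)
  b <- simulate_sources(n_genes = 120, seed = 9)
  expect_identical(a, b)
  expect_equal(sort(unique(a$truth$archetype)), sort(default_archetypes()$name))
  counts <- table(a$truth$archetype)
  expect_equal(unname(counts["general"]), 0.45 * 120)

  bad <- default_archetypes()
  bad$proportion[1] <- 0.5
  expect_error(simulate_sources(120, archetypes = bad),
               class = "testistools_parameter_error")
})

test_that("degenerate noise reproduces archetype means exactly", {
  out <- simulate_sources(n_genes = 100, noise_sd = 1e-12,
                          dropout = rep(0, 5), seed = 2)
  s1 <- out$sources$seg_testis
  m <- as.matrix(tibble::as_tibble(as.data.frame(s1))[-1])
  late <- out$truth$archetype == "testis_late"
  # seg_testis category 3 is the latest stage: t = 1, mean = 1 + 60 q
  expect_equal(unname(m[late, 3]),
               1 + 60 * out$truth$specificity_q[late], tolerance = 1e-6)
  under <- out$truth$archetype == "underrepresented"
  expect_equal(unname(m[under, 1]), rep(1, sum(under)), tolerance = 1e-6)
})

test_that("testis_late genes exceed somatic genes in late categories", {
  out <- simulate_sources(n_genes = 1000, seed = 1)
  fca <- as.matrix(tibble::as_tibble(as.data.frame(out$sources$fca))[-1])
  late_cols <- 30:39  # latest cell types of the highest-resolution source
  late <- out$truth$archetype == "testis_late"
  somatic <- out$truth$archetype == "somatic"
  expect_gt(mean(fca[late, late_cols]), mean(fca[somatic, late_cols]))
})

test_that("dropout zeroes single-cell sources but never the bulk source", {
  out <- simulate_sources(n_genes = 200, seed = 4)
  bulk <- as.matrix(tibble::as_tibble(as.data.frame(out$sources$seg_testis))[-1])
  sc <- as.matrix(tibble::as_tibble(as.data.frame(out$sources$fca))[-1])
  expect_true(all(bulk > 0))
  expect_gt(mean(sc == 0), 0.2)
  expect_lt(mean(sc == 0), 0.4)
})

test_that("atlas generation separates archetypes by testis expression", {
  out <- simulate_sources(n_genes = 150, seed = 5)
  atl <- simulate_atlases(out$truth, noise_sd = 1e-12, seed = 5)
  expect_length(atl, 3)
  a1 <- atl$atlas1
  m <- expr_matrix(a1)
  meta <- col_meta(a1)
  testis_col <- meta$column_id[meta$category == "testis"]
  late <- out$truth$archetype == "testis_late"
  expect_equal(unname(m[late, testis_col]),
               0.5 * 200^out$truth$specificity_q[late], tolerance = 1e-6)
  other <- setdiff(colnames(m), testis_col)
  expect_true(all(m[late, other] < 1))
  expect_identical(simulate_atlases(out$truth, seed = 8),
                   simulate_atlases(out$truth, seed = 8))
  expect_error(simulate_atlases(out$truth, n_tissues = 1),
               class = "testistools_parameter_error")
})

test_that("atlases feed the specificity index with the intended ordering", {
  out <- simulate_sources(n_genes = 400, seed = 6)
  atl <- simulate_atlases(out$truth, seed = 6)
  spec <- testis_specificity(atl)
  df <- dplyr::left_join(out$truth, spec, by = "gene_id")
  mu <- tapply(df$tsp, df$archetype, mean)
  expect_gt(mu["testis_late"], 0.5)
  expect_lt(mu["underrepresented"], 0)
  expect_gt(mu["testis_late"], mu["somatic"])
})

test_that("TF target lists have the constructed coverage and contamination", {
  out <- simulate_sources(n_genes = 1000, seed = 3)
  late <- out$truth$gene_id[out$truth$archetype == "testis_late"]

  all_late <- simulate_tf_targets(out$truth, coverage = 1, contamination = 0)
  expect_setequal(all_late, late)
  expect_length(simulate_tf_targets(out$truth, coverage = 0,
                                    contamination = 0), 0)
  t80 <- simulate_tf_targets(out$truth, coverage = 0.8, contamination = 0.02,
                             seed = 2)
  expect_equal(length(intersect(t80, late)), round(0.8 * length(late)))
  expect_equal(length(setdiff(t80, late)),
               round(0.02 * (nrow(out$truth) - length(late))))
})

test_that("promoter simulation plants motifs exactly as specified", {
  out <- simulate_sources(n_genes = 120, seed = 11)
  none <- simulate_promoters(out$truth, planted = list(
    m = planted_motif_spec(default_planted_motifs()$tce_like$motif,
                           insertion_probability = 0)), seed = 1)
  expect_equal(nrow(none$truth_hits), 0)

  det <- simulate_promoters(out$truth, planted = list(
    m = planted_motif_spec(default_planted_motifs()$tce_like$motif,
                           offset_mean = -150, offset_sd = 0,
                           sense_fraction = 1, insertion_probability = 1)),
    seed = 1)
  expect_true(all(det$truth_hits$offset == -150))
  expect_true(all(det$truth_hits$strand == "sense"))
  n_late <- sum(out$truth$archetype == "testis_late")
  expect_equal(nrow(det$truth_hits), n_late)

  expect_identical(simulate_promoters(out$truth, seed = 3),
                   simulate_promoters(out$truth, seed = 3))
  # distribution must fit inside the window
  expect_error(simulate_promoters(out$truth, half_width = 100, planted = list(
    m = planted_motif_spec(default_planted_motifs()$tce_like$motif,
                           offset_mean = -90, offset_sd = 20))),
    class = "testistools_parameter_error")
})

test_that("planted instances are recoverable from the written sequences", {
  out <- simulate_sources(n_genes = 100, seed = 13)
  pr <- simulate_promoters(out$truth, planted = list(
    m = planted_motif_spec(default_planted_motifs()$tce_like$motif,
                           offset_mean = -200, offset_sd = 0,
                           sense_fraction = 1, insertion_probability = 1)),
    seed = 2)
  w <- extract_tss_windows(pr$genome, pr$tss, half_width = 1000)
  # instance occupies window indices tss_index - 200 .. + L - 1 in the
  # gene frame, for plus- and minus-strand genes alike
  hit <- pr$truth_hits[1, ]
  row <- w[w$gene_id == hit$gene_id, ]
  written <- substr(row$sequence, row$tss_index - 200,
                    row$tss_index - 200 + 11)
  # sampled from a 0.94 PWM: close to consensus
  expect_gte(sum(strsplit(written, "")[[1]] ==
                   strsplit("CAAAATTCGTGC", "")[[1]]), 9)
})
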