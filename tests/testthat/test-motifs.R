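test_that("log-odds scores match the pseudocount formula", {
  uni <- motif_model("u", matrix(0.25, 2, 4))
  expect_equal(unname(log_odds(uni)), matrix(0, 2, 4))

  near <- motif_model("n", rbind(c(1, 0, 0, 0)), pseudocount = 1e-9)
  expect_equal(unname(log_odds(near)[1, "A"]), 2, tolerance = 1e-6)

  half <- motif_model("h", rbind(c(0.5, 0.5, 0, 0)), pseudocount = 0.01)
  s <- log_odds(half)
  expect_equal(unname(s[1, "A"]), 0.9928, tolerance = 1e-4)
  expect_equal(unname(s[1, "C"]), 0.9928, tolerance = 1e-4)
  expect_equal(unname(s[1, "G"]), -6.6582, tolerance = 1e-4)
})

test_that("relative scores span [0,1] from anti-consensus to consensus", {
  m <- random_motif(6, seed = 8)
  cons <- motif_consensus(m)
  expect_equal(relative_score(m, cons), 1)
  worst <- paste(colnames(m$prob)[apply(log_odds(m), 1, which.min)],
                 collapse = "")
  expect_equal(relative_score(m, worst), 0)
  expect_error(relative_score(m, "ACG"),
               class = "testistools_parameter_error")
})

test_that("all dinucleotide scores match exhaustive enumeration", {
  m <- random_motif(2, seed = 9)
  s <- log_odds_oracle(m$prob, m$background, m$pseudocount)
  smin <- sum(apply(s, 1, min))
  smax <- sum(apply(s, 1, max))
  for (b1 in c("A", "C", "G", "T")) for (b2 in c("A", "C", "G", "T")) {
    raw <- unname(s[1, b1] + s[2, b2])
    expect_equal(relative_score(m, paste0(b1, b2)),
                 (raw - smin) / (smax - smin))
  }
})

test_that("TSS windows are extracted with exact coordinate arithmetic", {
  contig <- random_dna(2000, seed = 10)
  genome <- c(chrA = contig)
  tss <- tibble::tibble(chrom = "chrA", start = 1000L, end = 1001L,
                        gene_id = "gP", strand = "+")
  w <- extract_tss_windows(genome, tss, half_width = 2)
  expect_equal(w$sequence, substr(contig, 999, 1003))  # 0-based [998, 1003)
  expect_equal(w$tss_index, 3L)
  expect_false(w$truncated)

  tss_m <- tibble::tibble(chrom = "chrA", start = 1000L, end = 1001L,
                          gene_id = "gM", strand = "-")
  wm <- extract_tss_windows(genome, tss_m, half_width = 2)
  expect_equal(wm$sequence, revcomp_oracle(substr(contig, 999, 1003)))

  near_end <- tibble::tibble(chrom = "chrA", start = 1998L, end = 1999L,
                             gene_id = "gT", strand = "+")
  expect_warning(wt <- extract_tss_windows(genome, near_end, half_width = 5),
                 "truncated")
  expect_true(wt$truncated)
  expect_equal(nchar(wt$sequence), 7)  # 5 upstream + TSS + 1 downstream

  bad <- tibble::tibble(chrom = "chrB", start = 10L, end = 11L,
                        gene_id = "gX", strand = "+")
  expect_error(extract_tss_windows(genome, bad, half_width = 2),
               class = "testistools_format_error")
})

test_that("the scanner matches the exhaustive oracle on random instances", {
  withr::with_seed(77, {
    for (i in 1:10) {
      L <- sample(4:12, 1)
      m <- random_motif(L, seed = 200 + i)
      n <- sample(100:400, 1)
      seq <- random_dna(n, seed = 300 + i)
      ti <- sample(seq_len(n), 1)
      w <- tibble::tibble(gene_id = "g", sequence = seq,
                          tss_index = as.integer(ti), truncated = FALSE)
      cutoff <- stats::runif(1, 0.55, 0.8)
      got <- scan_windows(w, m, cutoff = cutoff)
      want <- scan_oracle(seq, ti, m, cutoff)
      got <- got[order(got$offset, got$strand), ]
      want <- want[order(want$offset, want$strand), ]
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$relative_score, want$relative_score)
    }
  })
})

test_that("reverse-complementing a window mirrors and strand-swaps its hits", {
  m <- random_motif(5, seed = 12)
  seq <- random_dna(300, seed = 13)
  M <- nchar(seq)
  w <- tibble::tibble(gene_id = "g", sequence = seq, tss_index = 150L,
                      truncated = FALSE)
  wrc <- tibble::tibble(gene_id = "g", sequence = revcomp_oracle(seq),
                        tss_index = as.integer(M - 150L + 1L),
                        truncated = FALSE)
  h <- scan_windows(w, m, cutoff = 0.6)
  hrc <- scan_windows(wrc, m, cutoff = 0.6)
  expect_equal(nrow(h), nrow(hrc))
  # a sense hit at gene-frame position p becomes an antisense hit whose
  # leftmost base mirrors to -(p + L - 1) in the flipped frame
  flip <- tibble::tibble(offset = -(h$offset + nrow(m$prob) - 1L),
                         strand = ifelse(h$strand == "sense",
                                         "antisense", "sense"),
                         relative_score = h$relative_score)
  flip <- flip[order(flip$offset, flip$strand), ]
  hrc2 <- hrc[order(hrc$offset, hrc$strand), c("offset", "strand",
                                               "relative_score")]
  expect_equal(hrc2$offset, flip$offset)
  expect_equal(hrc2$strand, flip$strand)
  expect_equal(hrc2$relative_score, flip$relative_score)
})

test_that("consensus-only scanning at cutoff 1 finds exact matches only", {
  m <- motif_model("exact", rbind(c(0.97, 0.01, 0.01, 0.01),
                                  c(0.01, 0.97, 0.01, 0.01),
                                  c(0.01, 0.01, 0.97, 0.01)))
  seq <- paste0("TTTTT", "ACG", "TTTTT", "ACG", "TTTTT")
  w <- tibble::tibble(gene_id = "g", sequence = seq, tss_index = 1L,
                      truncated = FALSE)
  h <- scan_windows(w, m, cutoff = 1)
  sense <- h[h$strand == "sense", ]
  expect_equal(sense$offset + 1L, c(6L, 14L))  # 1-based match starts
  expect_true(all(h$relative_score == 1))
})

test_that("gene filters combine by conjunction and need a criterion", {
  expr <- tibble::tibble(gene_id = c("gA", "gB"), expression = c(5, 0.1))
  tsp <- tibble::tibble(gene_id = c("gA", "gB"), tsp = c(0.95, 0.95))
  expect_equal(filter_genes(expr, tsp, expression_min = 1, tsp_min = 0.9),
               "gA")
  expect_setequal(filter_genes(expr, tsp, tsp_min = 0.9), c("gA", "gB"))
  expect_equal(filter_genes(expr, tsp, tsp_max = 0, genes = "gA") |>
                 suppressWarnings(), character(0))
  expect_error(filter_genes(expr, tsp), class = "testistools_parameter_error")
  expect_warning(filter_genes(expr, tsp, expression_min = 100), "no genes")
})

test_that("positional distributions bin offsets and conserve counts", {
  hits <- tibble::tibble(gene_id = "g", motif_id = "m",
                         offset = rep(-150L, 10),
                         strand = rep(c("sense", "antisense"), 5),
                         relative_score = 0.9)
  d <- positional_distribution(hits, half_width = 1000, bin_width = 25)
  peak <- d[d$total > 0, ]
  expect_equal(nrow(peak), 1)
  expect_equal(peak$bin_start, -150L)
  expect_equal(peak$total, 10)
  expect_equal(peak$sense, 5)
  expect_equal(d$total, d$sense + d$antisense)

  withr::with_seed(19, {
    many <- tibble::tibble(gene_id = "g", motif_id = "m",
                           offset = as.integer(sample(-1000:1000, 500,
                                                      replace = TRUE)),
                           strand = sample(c("sense", "antisense"), 500,
                                           replace = TRUE),
                           relative_score = 0.85)
  })
  dm <- positional_distribution(many, half_width = 1000, bin_width = 25)
  expect_equal(sum(dm$total), 500)
  expect_equal(dm$total, dm$sense + dm$antisense)
  empty <- positional_distribution(many, gene_set = character(0),
                                   half_width = 1000)
  expect_equal(sum(empty$total), 0)
})

test_that("group sequences are collected deterministically and round-trip", {
  w <- tibble::tibble(gene_id = c("gB", "gA", "gC"),
                      sequence = c("ACGT", "TTTT", "GGGG"),
                      tss_index = 2L, truncated = FALSE)
  seqs <- collect_group_sequences(w, c("gC", "gA", "gZ"))
  expect_equal(names(seqs), c("gA", "gC"))
  p <- withr::local_tempfile(fileext = ".fa")
  collect_group_sequences(w, c("gC", "gA"), path = p)
  expect_equal(read_fasta(p), c(gA = "TTTT", gC = "GGGG"))
})
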