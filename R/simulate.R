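# Synthetic study generator: multi-source testis expression tables, tissue
# atlases, TF-target lists, and promoter sequences with planted motifs.

#' Default gene archetypes
#'
#' Archetypes stand in for the broad expression classes of a testis
#' transcriptome: late-spermatogenesis-specific genes, early/germline
#' genes, somatic-cell genes, generally expressed genes, and genes
#' under-represented in testis relative to other tissues. Default
#' proportions (0.15 / 0.10 / 0.20 / 0.45 / 0.10) reproduce the class
#' imbalance that motivates minority oversampling downstream.
#'
#' @return A tibble with columns `name`, `proportion`.
#' @export
default_archetypes <- function() {
  tibble::tibble(
    name = c("testis_late", "testis_early", "somatic", "general",
             "underrepresented"),
    proportion = c(0.15, 0.10, 0.20, 0.45, 0.10))
}

# mean expression of an archetype in a testis-source category at
# developmental progression t in [0, 1] (0 = earliest/somatic-most
# category, 1 = latest spermatogenic category); q is the gene's
# specificity quantile, scaling the testis-specific signal so tissue
# specificity forms a continuum rather than two extremes
archetype_source_mean <- function(archetype, t, q = 1) {
  switch(archetype,
    testis_late = 1 + 60 * q * t^2,
    testis_early = 1 + 40 * q * exp(-((t - 0.25)^2) / (2 * 0.15^2)),
    somatic = 1 + 10 * (t < 0.3),
    general = 15,
    underrepresented = 1,
    abort_param(paste0("unknown archetype: ", archetype)))
}

# mean expression of an archetype in an atlas tissue; for testis
# archetypes the testis level is log-interpolated between the background
# level and the fully specific level by the gene's quantile q
archetype_atlas_mean <- function(archetype, is_testis, q = 1) {
  switch(archetype,
    testis_late = if (is_testis) 0.5 * 200^q else 0.5,
    testis_early = if (is_testis) 0.5 * 160^q else 0.5,
    somatic = 10,
    general = 20,
    underrepresented = if (is_testis) 0.5 else 15,
    abort_param(paste0("unknown archetype: ", archetype)))
}

# deterministically assign archetypes to n genes in the stated proportions
assign_archetypes <- function(n_genes, archetypes) {
  if (abs(sum(archetypes$proportion) - 1) > 1e-8) {
    abort_param("archetype proportions must sum to 1")
  }
  counts <- floor(archetypes$proportion * n_genes)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    frac <- archetypes$proportion * n_genes - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sample(rep(archetypes$name, counts))
}

#' Simulate multi-source testis expression tables
#'
#' Generates one expression table per testis data source. Category counts
#' default to `c(3, 8, 10, 9, 39)`, mirroring a segmented-testis RNA-seq
#' series, a single-cyst series, larval and adult single-cell datasets, and
#' a cell-atlas dataset. Expression is the archetype mean for the
#' (source, category) cell times log-normal multiplicative noise
#' (`noise_sd` on the natural-log scale), then zeroed with probability
#' `dropout` for single-cell-like sources; the bulk-like first source has
#' no dropout by default.
#'
#' @param n_genes Number of genes (default 11019; at least 100).
#' @param archetypes Tibble of archetype names and proportions
#'   (see [default_archetypes()]).
#' @param category_counts Integer vector, one entry per source.
#' @param source_names Names for the sources.
#' @param dropout Per-source dropout probability in `[0, 1)`.
#' @param noise_sd Log-scale noise standard deviation.
#' @param n_replicates Measured columns per category.
#' @param seed Integer seed; outputs are deterministic given the seed.
#' @return A list with `sources` (named list of `expr_tbl`) and `truth`
#'   (tibble `gene_id`, `archetype`, `specificity_q`); the specificity
#'   quantile `specificity_q` in `(0, 1]` scales how testis-specific each
#'   testis-archetype gene is, so specificity forms a continuum.
#' @export
simulate_sources <- function(n_genes = 11019,
                             archetypes = default_archetypes(),
                             category_counts = c(3, 8, 10, 9, 39),
                             source_names = c("seg_testis", "single_cyst",
                                              "larval_sc", "adult_sc", "fca"),
                             dropout = c(0, rep(0.3, length(category_counts) - 1)),
                             noise_sd = 0.5, n_replicates = 1, seed = 1) {
  if (n_genes < 100) abort_param("n_genes must be at least 100")
  if (length(source_names) != length(category_counts) ||
      length(dropout) != length(category_counts)) {
    abort_param("category_counts, source_names and dropout must align")
  }
  if (any(dropout < 0 | dropout >= 1)) abort_param("dropout must be in [0, 1)")
  withr::with_seed(seed, {
    truth <- tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      archetype = assign_archetypes(n_genes, archetypes))
    # specificity quantile: testis genes span a continuum of specificity
    # (most are strongly specific, a minority intermediate), other
    # archetypes sit at their archetype profile exactly
    truth$specificity_q <- ifelse(
      truth$archetype %in% c("testis_late", "testis_early"),
      stats::rbeta(n_genes, 2, 1), 1)
    sources <- purrr::map(seq_along(category_counts), function(j) {
      k <- category_counts[j]
      tt <- if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1)
      mu <- vapply(seq_len(k), function(i) {
        mapply(archetype_source_mean, truth$archetype,
               q = truth$specificity_q, MoreArgs = list(t = tt[i]))
      }, numeric(n_genes))
      cols <- list()
      meta <- list()
      for (i in seq_len(k)) {
        for (r in seq_len(n_replicates)) {
          vals <- mu[, i] * exp(stats::rnorm(n_genes, 0, noise_sd))
          if (dropout[j] > 0) {
            vals[stats::runif(n_genes) < dropout[j]] <- 0
          }
          cid <- if (n_replicates == 1) {
            sprintf("%s_c%02d", source_names[j], i)
          } else {
            sprintf("%s_c%02d_r%d", source_names[j], i, r)
          }
          cols[[cid]] <- vals
          meta[[cid]] <- tibble::tibble(column_id = cid,
                                        source_id = source_names[j],
                                        category = sprintf("c%02d", i))
        }
      }
      expression_table(
        dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id),
                         tibble::as_tibble(cols)),
        dplyr::bind_rows(meta))
    })
    names(sources) <- source_names
    list(sources = sources, truth = truth)
  })
}

#' Simulate tissue expression atlases
#'
#' Generates `n_atlases` whole-body tissue atlases over the same genes,
#' each with `n_tissues` tissues including one labelled `testis`.
#' Testis-specific archetypes are high in testis and near-silent elsewhere;
#' the under-represented archetype is low in testis and moderate elsewhere,
#' so the downstream testis-specificity index separates them by sign.
#'
#' @param truth Tibble `gene_id`, `archetype` (from [simulate_sources()]).
#' @param n_tissues Number of tissues (at least 2; default 15).
#' @param n_atlases Number of atlases (default 3).
#' @param noise_sd Log-scale noise standard deviation.
#' @param seed Integer seed.
#' @return Named list of `expr_tbl` atlases.
#' @export
simulate_atlases <- function(truth, n_tissues = 15, n_atlases = 3,
                             noise_sd = 0.5, seed = 1) {
  if (n_tissues < 2) abort_param("n_tissues must be at least 2")
  tissues <- c("testis", sprintf("tissue%02d", seq_len(n_tissues - 1)))
  n_genes <- nrow(truth)
  qv <- if ("specificity_q" %in% names(truth)) truth$specificity_q else
    rep(1, n_genes)
  withr::with_seed(seed, {
    atlases <- purrr::map(seq_len(n_atlases), function(a) {
      cols <- list()
      meta <- list()
      for (ti in tissues) {
        mu <- mapply(archetype_atlas_mean, truth$archetype, q = qv,
                     MoreArgs = list(is_testis = ti == "testis"))
        cid <- ti
        cols[[cid]] <- mu * exp(stats::rnorm(n_genes, 0, noise_sd))
        meta[[cid]] <- tibble::tibble(column_id = cid,
                                      source_id = sprintf("atlas%d", a),
                                      category = ti)
      }
      expression_table(
        dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id),
                         tibble::as_tibble(cols)),
        dplyr::bind_rows(meta))
    })
    names(atlases) <- sprintf("atlas%d", seq_len(n_atlases))
    atlases
  })
}

#' Simulate a transcription-factor target gene list
#'
#' Emulates an experimentally derived TF-target list (e.g. from DamID) as a
#' noisy view of the late-spermatogenesis archetype: a `coverage` fraction
#' of the testis_late genes plus a `contamination` fraction of all other
#' genes.
#'
#' @param truth Tibble `gene_id`, `archetype`.
#' @param coverage Fraction of testis_late genes included, in `[0, 1]`.
#' @param contamination Fraction of non-testis_late genes included.
#' @param seed Integer seed.
#' @return Character vector of target gene ids.
#' @export
simulate_tf_targets <- function(truth, coverage = 0.8, contamination = 0.02,
                                seed = 1) {
  if (coverage < 0 || coverage > 1 || contamination < 0 || contamination > 1) {
    abort_param("coverage and contamination must be in [0, 1]")
  }
  pos <- truth$gene_id[truth$archetype == "testis_late"]
  neg <- truth$gene_id[truth$archetype != "testis_late"]
  withr::with_seed(seed, {
    targets <- character()
    n_pos <- round(coverage * length(pos))
    if (n_pos > 0) targets <- sample(pos, n_pos)
    n_neg <- round(contamination * length(neg))
    if (n_neg > 0) targets <- c(targets, sample(neg, n_neg))
    sort(targets)
  })
}

#' Planted motif specification
#'
#' Describes how a motif is planted into promoter windows of target genes:
#' a Gaussian TSS-relative position, a sense-strand probability, and a
#' per-gene insertion probability. Instances are sampled from the PWM, not
#' always the consensus, so relative scores near the scanning cutoff occur.
#'
#' @param motif A `motif_model`.
#' @param target_archetypes Archetype names whose genes receive the motif.
#' @param offset_mean Mean TSS-relative offset of the instance's leftmost
#'   base in the gene-oriented frame (negative = upstream).
#' @param offset_sd Positional standard deviation (nt).
#' @param sense_fraction Probability of planting on the sense strand.
#' @param insertion_probability Per-target-gene insertion probability.
#' @return A `planted_motif_spec` list.
#' @export
planted_motif_spec <- function(motif, target_archetypes = "testis_late",
                               offset_mean = -150, offset_sd = 20,
                               sense_fraction = 0.8,
                               insertion_probability = 0.9) {
  stopifnot(inherits(motif, "motif_model"))
  if (offset_sd < 0) abort_param("offset_sd must be non-negative")
  if (sense_fraction < 0 || sense_fraction > 1 ||
      insertion_probability < 0 || insertion_probability > 1) {
    abort_param("sense_fraction and insertion_probability must be in [0, 1]")
  }
  structure(list(motif = motif, target_archetypes = target_archetypes,
                 offset_mean = as.integer(offset_mean),
                 offset_sd = offset_sd, sense_fraction = sense_fraction,
                 insertion_probability = insertion_probability),
            class = "planted_motif_spec")
}

#' Default planted motif
#'
#' A 12-nt motif with an AT-rich core reminiscent of the
#' translational-control-element family found upstream of late
#' spermatogenesis genes, with 0.94 consensus-base probability per
#' position. At the usual 0.8 relative-score cutoff a PWM-sampled instance
#' is recovered with probability ~0.97 while random background sequence
#' yields well under one hit per 10 kb.
#'
#' @return A list with one [planted_motif_spec()].
#' @export
default_planted_motifs <- function() {
  consensus <- strsplit("CAAAATTCGTGC", "")[[1]]
  prob <- matrix(0.02, length(consensus), 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) prob[i, consensus[i]] <- 0.94
  list(tce_like = planted_motif_spec(motif_model("tce_like", prob)))
}

#' Simulate a promoter genome with planted motifs
#'
#' Builds one contig per gene containing a TSS-centred promoter window of
#' i.i.d. background sequence at the stated GC content, assigns each gene a
#' random strand, and plants motif instances per [planted_motif_spec()].
#' Instances are sampled from the PWM; antisense instances are written as
#' the reverse complement. Overlapping placements are re-sampled up to 10
#' times, then skipped with a warning.
#'
#' @param truth Tibble `gene_id`, `archetype` (rows may be a subset).
#' @param half_width Promoter half-width W; windows span `[-W, W]` around
#'   the TSS (default 1000).
#' @param planted List of [planted_motif_spec()] objects.
#' @param gc_content Background GC fraction (default 0.45).
#' @param pad Flanking background length added on each side of the window.
#' @param seed Integer seed.
#' @return A list: `genome` (named character vector of contig sequences),
#'   `tss` (BED-convention tibble as from [read_tss_table()]), and
#'   `truth_hits` (tibble `gene_id`, `motif_id`, `offset`, `strand`).
#' @export
simulate_promoters <- function(truth, half_width = 1000,
                               planted = default_planted_motifs(),
                               gc_content = 0.45, pad = 100, seed = 1) {
  W <- as.integer(half_width)
  M <- 2L * W + 1L
  for (sp in planted) {
    L <- nrow(sp$motif$prob)
    if (abs(sp$offset_mean) + 3 * sp$offset_sd > W - L) {
      abort_param("planted motif distribution does not fit the window")
    }
  }
  base_p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
              G = gc_content / 2, T = (1 - gc_content) / 2)
  withr::with_seed(seed, {
    genes <- truth$gene_id
    strands <- sample(c("+", "-"), length(genes), replace = TRUE)
    windows <- vapply(seq_along(genes), function(i) {
      paste(sample(names(base_p), M, replace = TRUE, prob = base_p),
            collapse = "")
    }, character(1))
    hits <- list()
    occupied <- vector("list", length(genes))
    for (sname in names(planted)) {
      sp <- planted[[sname]]
      L <- nrow(sp$motif$prob)
      tgt <- which(truth$archetype %in% sp$target_archetypes)
      for (i in tgt) {
        if (stats::runif(1) >= sp$insertion_probability) next
        placed <- FALSE
        for (attempt in 1:10) {
          off <- as.integer(round(stats::rnorm(1, sp$offset_mean,
                                               sp$offset_sd)))
          if (off < -W || off + L - 1L > W) next
          pos <- W + 1L + off  # 1-based leftmost index in the window
          span <- pos:(pos + L - 1L)
          if (length(intersect(span, occupied[[i]]))) next
          inst <- paste(vapply(seq_len(L), function(j) {
            sample(colnames(sp$motif$prob), 1, prob = sp$motif$prob[j, ])
          }, character(1)), collapse = "")
          strand <- if (stats::runif(1) < sp$sense_fraction) "sense"
                    else "antisense"
          written <- if (strand == "sense") inst else revcomp_chr(inst)
          substr(windows[i], pos, pos + L - 1L) <- written
          occupied[[i]] <- c(occupied[[i]], span)
          hits[[length(hits) + 1]] <- tibble::tibble(
            gene_id = genes[i], motif_id = sp$motif$motif_id,
            offset = off, strand = strand)
          placed <- TRUE
          break
        }
        if (!placed) {
          warning(sprintf("could not place motif %s in gene %s",
                          sp$motif$motif_id, genes[i]), call. = FALSE)
        }
      }
    }
    pads <- vapply(seq_len(2 * length(genes)), function(i) {
      paste(sample(names(base_p), pad, replace = TRUE, prob = base_p),
            collapse = "")
    }, character(1))
    contigs <- vapply(seq_along(genes), function(i) {
      core <- if (strands[i] == "+") windows[i] else revcomp_chr(windows[i])
      paste0(pads[2 * i - 1], core, pads[2 * i])
    }, character(1))
    names(contigs) <- paste0("chr_", genes)
    tss_pos <- pad + W  # 0-based TSS coordinate on every contig
    tss <- tibble::tibble(chrom = names(contigs),
                          start = as.integer(tss_pos),
                          end = as.integer(tss_pos + 1L),
                          gene_id = genes, strand = strands)
    truth_hits <- if (length(hits)) dplyr::bind_rows(hits) else
      tibble::tibble(gene_id = character(), motif_id = character(),
                     offset = integer(), strand = character())
    list(genome = contigs, tss = tss, truth_hits = truth_hits)
  })
}

# reverse complement of plain character DNA
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Simulate a complete study
#'
#' Convenience wrapper generating the testis sources, tissue atlases and a
#' TF-target list from one seed, so every downstream stage can run from a
#' single call.
#'
#' @param n_genes Number of genes (default 1000 for desk-scale work).
#' @param seed Integer seed.
#' @param noise_sd Log-scale noise standard deviation for sources/atlases.
#' @param ... Passed to [simulate_sources()].
#' @return A list with `truth`, `sources`, `atlases`, `tf_targets`.
#' @export
simulate_study <- function(n_genes = 1000, seed = 1, noise_sd = 0.5, ...) {
  src <- simulate_sources(n_genes = n_genes, noise_sd = noise_sd,
                          seed = seed, ...)
  atlases <- simulate_atlases(src$truth, noise_sd = noise_sd,
                              seed = child_seed(seed, 2))
  targets <- simulate_tf_targets(src$truth, seed = child_seed(seed, 3))
  list(truth = src$truth, sources = src$sources, atlases = atlases,
       tf_targets = targets)
}
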