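# Independent oracles and fixture builders shared across tests. The
# oracles deliberately re-derive each quantity from first principles
# (direct formula evaluation, exhaustive enumeration, graph reachability)
# rather than calling the implementation under test.

# --- tiny expression-table fixture ------------------------------------------

tiny_expr <- function(values = rbind(gA = c(1, 2, 3), gB = c(4, 5, 6)),
                      source_id = "src",
                      category = c("early", "early", "late")) {
  cols <- paste0("col", seq_len(ncol(values)))
  df <- tibble::as_tibble(values, .name_repair = ~cols)
  df <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(values)), df)
  meta <- tibble::tibble(column_id = cols, source_id = source_id,
                         category = category)
  expression_table(df, meta)
}

# --- specificity oracles ----------------------------------------------------

tau_oracle <- function(e) {
  mx <- max(e)
  sum((1 - e / mx)^2) / (length(e) - 1)
}

zscore_oracle <- function(e) {
  n <- length(e)
  s <- sqrt(sum((e - mean(e))^2) / (n - 1))
  (e - mean(e)) / s
}

# --- ROC oracle: Mann-Whitney over all (pos, neg) pairs ---------------------

auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# --- DBSCAN oracle: density reachability via graph components ---------------
# Core points: >= min_samples neighbours within eps (self included).
# Clusters: connected components of the eps-adjacency graph restricted to
# core points, numbered by the rank of each component's smallest core
# index (= first-touch order of a sequential scan). Border points join the
# lowest-numbered cluster having a core point within eps; all else noise.

dbscan_oracle <- function(x, eps, min_samples) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  adj <- d <= eps + 1e-12
  core <- which(rowSums(adj) >= min_samples)
  labels <- rep(-1L, n)
  if (length(core)) {
    g <- igraph::graph_from_adjacency_matrix(
      adj[core, core, drop = FALSE], mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    first_idx <- tapply(core, comp, min)
    relabel <- rank(first_idx) - 1L
    labels[core] <- as.integer(relabel[comp])
    for (i in setdiff(seq_len(n), core)) {
      near_core <- core[adj[i, core]]
      if (length(near_core)) labels[i] <- min(labels[near_core])
    }
  }
  labels
}

# --- PWM scanning oracle: direct formula evaluation, all offsets ------------

revcomp_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

log_odds_oracle <- function(prob, background, pseudocount) {
  t(vapply(seq_len(nrow(prob)), function(j) {
    log2((prob[j, ] + pseudocount * background) /
           ((1 + pseudocount) * background))
  }, numeric(4)))
}

# every placement on both strands with relative score >= cutoff;
# offsets are leftmost-base positions relative to tss_index
scan_oracle <- function(seq, tss_index, motif, cutoff) {
  s <- log_odds_oracle(motif$prob, motif$background, motif$pseudocount)
  smin <- sum(apply(s, 1, min))
  smax <- sum(apply(s, 1, max))
  L <- nrow(s)
  M <- nchar(seq)
  res <- list()
  for (strand in c("sense", "antisense")) {
    sseq <- if (strand == "sense") seq else revcomp_oracle(seq)
    chars <- strsplit(sseq, "")[[1]]
    for (p in seq_len(M - L + 1)) {
      raw <- 0
      for (j in seq_len(L)) {
        b <- chars[p + j - 1]
        raw <- raw + if (b %in% c("A", "C", "G", "T")) {
          s[j, b]
        } else {
          sum(motif$background * s[j, ])
        }
      }
      rel <- (raw - smin) / (smax - smin)
      if (rel >= cutoff - 1e-12) {
        left <- if (strand == "sense") p else M - p - L + 2
        res[[length(res) + 1]] <- tibble::tibble(
          offset = as.integer(left - tss_index), strand = strand,
          relative_score = unname(rel))
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(offset = integer(), strand = character(),
                          relative_score = double()))
  }
  dplyr::bind_rows(res)
}

random_motif <- function(L, seed) {
  withr::with_seed(seed, {
    prob <- matrix(stats::rgamma(4 * L, 0.8), L, 4)
    prob <- prob / rowSums(prob)
    colnames(prob) <- c("A", "C", "G", "T")
    motif_model(paste0("m", L), prob)
  })
}

random_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}
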