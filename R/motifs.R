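# PWM scanning of TSS-centred promoter windows, gene-set filtering, and
# strand-resolved positional distributions.

#' Log-odds score matrix of a motif
#'
#' Converts the position probability matrix to log2-odds against the
#' background, with a pseudocount proportional to the background:
#' `s[j, b] = log2((p[j, b] + pc * bg[b]) / ((1 + pc) * bg[b]))`.
#'
#' @param motif A `motif_model`.
#' @return An L x 4 matrix of log2-odds scores (columns A, C, G, T).
#' @export
log_odds <- function(motif) {
  pc <- motif$pseudocount
  bg <- matrix(motif$background, nrow(motif$prob), 4, byrow = TRUE)
  s <- log2((motif$prob + pc * bg) / ((1 + pc) * bg))
  dimnames(s) <- dimnames(motif$prob)
  s
}

#' Relative score of a subsequence under a motif
#'
#' The raw log-odds sum rescaled by the motif's attainable range:
#' `(raw - min) / (max - min)` where min/max are the column-wise worst/best
#' log-odds sums, so the consensus scores exactly 1 and the anti-consensus
#' exactly 0. Ambiguous bases (anything outside ACGT) contribute their
#' column's background-expected score.
#'
#' @param motif A `motif_model`.
#' @param subsequence Character scalar of the motif's length.
#' @return Relative score in `[0, 1]`.
#' @export
relative_score <- function(motif, subsequence) {
  s <- log_odds(motif)
  L <- nrow(s)
  codes <- seq_match_codes(toupper(subsequence))
  if (length(codes) != L) abort_param("subsequence length must equal motif length")
  st <- score_table(motif, s)
  raw <- sum(st[cbind(codes, seq_len(L))])
  (raw - sum(apply(s, 1, min))) / (sum(apply(s, 1, max)) - sum(apply(s, 1, min)))
}

# 5 x L score table: rows A,C,G,T plus the background-expected score for
# ambiguous bases
score_table <- function(motif, s = log_odds(motif)) {
  rbind(t(s), colSums(t(s) * motif$background))
}

# encode a DNA string as 1..4 = ACGT, 5 = anything else
seq_match_codes <- function(seq) {
  v <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v
}

#' Extract oriented TSS-centred promoter windows
#'
#' For every TSS record, extracts the genomic window of `2 * half_width +
#' 1` bases centred on the TSS base and orients it 5'→3' in the gene's
#' frame: minus-strand windows are reverse-complemented, so in every
#' returned sequence the index `tss_index` is the TSS and increasing
#' positions run downstream. Windows running off a contig end are truncated
#' and flagged.
#'
#' @param genome Named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param tss TSS tibble (see [read_tss_table()]); the TSS base is `start`
#'   for `+` genes and `end - 1` for `-` genes.
#' @param half_width Window half-width W in nt (default 1000).
#' @return A tibble `gene_id`, `sequence`, `tss_index` (1-based index of
#'   the TSS within the sequence), `truncated`; attribute `half_width`.
#' @export
extract_tss_windows <- function(genome, tss, half_width = 1000) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
    names(seqs) <- sub("\\s.*$", "", names(genome))
    genome <- seqs
  }
  genome <- toupper(genome)
  W <- as.integer(half_width)
  missing_chrom <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing_chrom)) {
    abort_format(paste0("contigs absent from genome: ",
                        paste(missing_chrom, collapse = ", ")))
  }
  rows <- purrr::pmap(tss, function(chrom, start, end, gene_id, strand, ...) {
    contig <- genome[[chrom]]
    clen <- nchar(contig)
    tss0 <- if (strand == "+") start else end - 1L  # 0-based TSS base
    lo <- max(0L, tss0 - W)
    hi <- min(clen - 1L, tss0 + W)
    seq <- substr(contig, lo + 1L, hi + 1L)
    truncated <- (tss0 - W < 0L) || (tss0 + W > clen - 1L)
    if (strand == "+") {
      tss_index <- tss0 - lo + 1L
    } else {
      seq <- revcomp_chr(seq)
      tss_index <- hi - tss0 + 1L
    }
    tibble::tibble(gene_id = gene_id, sequence = seq,
                   tss_index = as.integer(tss_index), truncated = truncated)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$truncated)) {
    warning(sprintf("%d window(s) truncated at contig ends",
                    sum(out$truncated)), call. = FALSE)
  }
  attr(out, "half_width") <- W
  out
}

#' Scan promoter windows with motifs on both strands
#'
#' Slides each motif over every window on the sense strand and over the
#' window's reverse complement for the antisense strand (positions mapped
#' back to the gene frame), reporting every placement whose relative score
#' reaches the cutoff. Offsets are TSS-relative positions of the hit's
#' leftmost base in the gene-oriented frame (0 = TSS, negative = upstream);
#' strand is `"sense"`/`"antisense"` relative to the gene. Overlapping hits
#' are all reported.
#'
#' @param windows Window tibble from [extract_tss_windows()].
#' @param motifs A `motif_model` or list of them.
#' @param cutoff Relative-score cutoff in `[0, 1]` (default 0.8).
#' @return A hits tibble `gene_id`, `motif_id`, `offset`, `strand`,
#'   `relative_score`.
#' @export
scan_windows <- function(windows, motifs, cutoff = 0.8) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  out <- list()
  for (motif in motifs) {
    s <- log_odds(motif)
    st <- score_table(motif, s)
    L <- nrow(s)
    smin <- sum(apply(s, 1, min))
    srange <- sum(apply(s, 1, max)) - smin
    for (r in seq_len(nrow(windows))) {
      seq <- toupper(windows$sequence[r])
      M <- nchar(seq)
      if (M < L) next
      ti <- windows$tss_index[r]
      for (strand in c("sense", "antisense")) {
        scan_seq <- if (strand == "sense") seq else revcomp_chr(seq)
        codes <- seq_match_codes(scan_seq)
        n_off <- M - L + 1L
        raw <- numeric(n_off)
        for (j in seq_len(L)) {
          raw <- raw + st[cbind(codes[j:(j + n_off - 1L)], j)]
        }
        rel <- (raw - smin) / srange
        hit <- which(rel >= cutoff - 1e-12)
        if (!length(hit)) next
        left <- if (strand == "sense") hit else M - hit - L + 2L
        out[[length(out) + 1]] <- tibble::tibble(
          gene_id = windows$gene_id[r], motif_id = motif$motif_id,
          offset = as.integer(left - ti), strand = strand,
          relative_score = rel[hit])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(gene_id = character(), motif_id = character(),
                          offset = integer(), strand = character(),
                          relative_score = double()))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$gene_id, .data$motif_id, .data$offset, .data$strand)
}

#' Filter genes by expression, specificity and explicit lists
#'
#' Combines the supplied criteria by conjunction: minimum mean expression
#' (e.g. >1, >100, >1000), a testis-specificity interval (e.g. tsp > 0.9,
#' > 0.5, < 0, < -0.5), and/or an explicit gene list (e.g. TF targets). At
#' least one criterion must be given.
#'
#' @param expression Tibble `gene_id`, `expression` (mean expression), or
#'   `NULL`.
#' @param tsp Tibble `gene_id`, `tsp`, or `NULL`.
#' @param expression_min Keep genes with expression strictly above this.
#' @param tsp_min,tsp_max Keep genes with `tsp > tsp_min` and/or
#'   `tsp < tsp_max` (strict, matching the published interval notation).
#' @param genes Explicit gene list to intersect with.
#' @return Character vector of gene ids (warning when empty).
#' @export
filter_genes <- function(expression = NULL, tsp = NULL,
                         expression_min = NULL, tsp_min = NULL,
                         tsp_max = NULL, genes = NULL) {
  if (is.null(expression_min) && is.null(tsp_min) && is.null(tsp_max) &&
      is.null(genes)) {
    abort_param("at least one filtering criterion must be set")
  }
  universe <- unique(c(if (!is.null(expression)) expression$gene_id,
                       if (!is.null(tsp)) tsp$gene_id,
                       genes))
  keep <- universe
  if (!is.null(expression_min)) {
    if (is.null(expression)) abort_param("expression table required")
    ok <- expression$gene_id[!is.na(expression$expression) &
                             expression$expression > expression_min]
    keep <- intersect(keep, ok)
  }
  if (!is.null(tsp_min) || !is.null(tsp_max)) {
    if (is.null(tsp)) abort_param("tsp table required")
    v <- tsp$tsp
    ok <- !is.na(v)
    if (!is.null(tsp_min)) ok <- ok & v > tsp_min
    if (!is.null(tsp_max)) ok <- ok & v < tsp_max
    keep <- intersect(keep, tsp$gene_id[ok])
  }
  if (!is.null(genes)) keep <- intersect(keep, genes)
  if (!length(keep)) warning("no genes pass the filter", call. = FALSE)
  keep
}

#' Strand-resolved positional distribution of motif hits
#'
#' Bins TSS-relative hit offsets for a gene set into fixed-width bins over
#' `[-half_width, half_width]`, overall and separately per strand. Counts
#' are reported, not densities; the overall histogram is the element-wise
#' sum of the two strand histograms. A tail bin is truncated when
#' `bin_width` does not divide the span.
#'
#' @param hits Hits tibble (see [scan_windows()]).
#' @param gene_set Optional character vector restricting the genes.
#' @param half_width Window half-width used for the scan.
#' @param bin_width Bin width in nt (default 25).
#' @return A tibble `bin_start`, `bin_end`, `bin_mid`, `sense`,
#'   `antisense`, `total`.
#' @export
positional_distribution <- function(hits, gene_set = NULL, half_width,
                                    bin_width = 25) {
  if (!is.null(gene_set)) hits <- hits[hits$gene_id %in% gene_set, ]
  W <- as.integer(half_width)
  starts <- seq(-W, W, by = bin_width)
  ends <- pmin(starts + bin_width, W + 1L)
  bin_of <- function(off) findInterval(off, starts)
  count_strand <- function(str) {
    off <- hits$offset[hits$strand == str]
    off <- off[off >= -W & off <= W]
    tabulate(bin_of(off), nbins = length(starts))
  }
  sense <- count_strand("sense")
  anti <- count_strand("antisense")
  tibble::tibble(bin_start = as.integer(starts), bin_end = as.integer(ends),
                 bin_mid = (starts + ends - 1) / 2,
                 sense = sense, antisense = anti, total = sense + anti)
}

#' Collect the window sequences of a gene set as FASTA-ready records
#'
#' Orders the available sequences by gene id, ready to be written as the
#' input of an external motif discovery tool.
#'
#' @param windows Window tibble from [extract_tss_windows()] (or any tibble
#'   with `gene_id`, `sequence`).
#' @param gene_set Character vector of gene ids.
#' @param path Optional FASTA output path.
#' @return A named character vector of sequences (headers = gene ids).
#' @export
collect_group_sequences <- function(windows, gene_set, path = NULL) {
  keep <- windows[windows$gene_id %in% gene_set, ]
  keep <- keep[order(keep$gene_id), ]
  seqs <- stats::setNames(keep$sequence, keep$gene_id)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(seqs)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
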