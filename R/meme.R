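#' Construct a motif model
#'
#' A motif model is a position probability matrix over the DNA alphabet
#' together with a background distribution and a pseudocount used when the
#' matrix is converted to log-odds scores (see [log_odds()]).
#'
#' @param motif_id Motif identifier.
#' @param prob Numeric matrix, one row per motif position, four columns in
#'   A, C, G, T order; every row must sum to 1 (tolerance 1e-3).
#' @param background Background base probabilities (A, C, G, T), summing
#'   to 1; defaults to uniform.
#' @param pseudocount Fraction of the background added to each probability
#'   before taking log-odds; default 0.01.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(motif_id, prob,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        pseudocount = 0.01) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) abort_format("motif matrix must have 4 columns (ACGT)")
  if (nrow(prob) < 1) abort_format("motif must have at least one position")
  if (any(prob < 0)) abort_format("motif probabilities must be non-negative")
  if (any(abs(rowSums(prob) - 1) > 1e-3)) {
    abort_format("motif probability rows must sum to 1 (tolerance 1e-3)")
  }
  colnames(prob) <- c("A", "C", "G", "T")
  background <- as.numeric(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-3 ||
      any(background <= 0)) {
    abort_format("background must be 4 positive probabilities summing to 1")
  }
  names(background) <- c("A", "C", "G", "T")
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort_param("pseudocount must be positive")
  }
  structure(list(motif_id = as.character(motif_id), prob = prob,
                 background = background, pseudocount = pseudocount),
            class = "motif_model")
}

#' @exportS3Method base::print
print.motif_model <- function(x, ...) {
  cat("<motif_model> ", x$motif_id, " (", nrow(x$prob), " nt), consensus ",
      motif_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a motif (column-wise most probable base)
#' @param motif A `motif_model`.
#' @return Character scalar.
#' @export
motif_consensus <- function(motif) {
  paste(colnames(motif$prob)[max.col(motif$prob, ties.method = "first")],
        collapse = "")
}

#' Read motifs in MEME minimal text format
#'
#' Parses the minimal motif text format written by motif discovery tools:
#' a version line, an `ALPHABET=` line, an optional background frequency
#' block, and one `MOTIF` block per motif with its letter-probability
#' matrix. When no background block is present, a uniform background is
#' assumed.
#'
#' @param path Path to a MEME minimal format file.
#' @param pseudocount Pseudocount passed to [motif_model()].
#' @return A named list of `motif_model` objects.
#' @export
read_meme_motifs <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!any(grepl("^MEME version", lines))) {
    abort_format("not a MEME minimal format file (missing version line)")
  }
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_line)) {
    alpha <- gsub("[^A-Za-z]", "", sub("^ALPHABET\\s*=?", "", alpha_line[1]))
    if (toupper(alpha) != "ACGT") {
      abort_format(paste0("unsupported alphabet: ", alpha))
    }
  }
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- character()
    i <- bg_at[1] + 1
    while (i <= length(lines) && !startsWith(lines[i], "MOTIF") &&
           nzchar(lines[i])) {
      toks <- c(toks, strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1
    }
    if (length(toks) >= 8) {
      bases <- toupper(toks[seq(1, 8, by = 2)])
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      background[bases] <- vals
    }
  }
  motif_at <- grep("^MOTIF\\b", lines)
  motifs <- list()
  for (m in motif_at) {
    id <- strsplit(lines[m], "\\s+")[[1]][2]
    lp <- m + which(startsWith(lines[(m + 1):length(lines)],
                               "letter-probability matrix"))[1]
    if (is.na(lp)) abort_format(paste0("motif ", id, ": no probability matrix"))
    w <- suppressWarnings(
      as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[lp])))
    rows <- list()
    i <- lp + 1
    while (i <= length(lines) && length(rows) < (w %||% Inf)) {
      if (!nzchar(lines[i])) { if (is.na(w)) break else { i <- i + 1; next } }
      if (grepl("^(MOTIF|URL)", lines[i])) break
      vals <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (anyNA(vals) || length(vals) != 4) break
      rows[[length(rows) + 1]] <- vals
      i <- i + 1
    }
    if (!is.na(w) && length(rows) != w) {
      abort_format(paste0("motif ", id, ": expected ", w, " rows, got ",
                          length(rows)))
    }
    prob <- do.call(rbind, rows)
    motifs[[id]] <- motif_model(id, prob, background, pseudocount)
  }
  if (length(motifs) == 0) abort_format("no MOTIF blocks found")
  motifs
}

#' Write motifs in MEME minimal text format
#' @param motifs A list of `motif_model` objects.
#' @param path Output path.
#' @return `motifs`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(m$prob)), con)
    writeLines(apply(m$prob, 1, function(r)
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(motifs)
}
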