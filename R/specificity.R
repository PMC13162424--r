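#' Tau tissue-specificity score
#'
#' Tau summarises how confined a gene's expression is across `n` categories:
#' \deqn{\tau = \frac{\sum_{i=1}^{n} (1 - e_i / \max(e))^2}{n - 1}}
#' Tau is 1 when expression is confined to a single category and 0 when it
#' is uniform. Tau is invariant to rescaling of the expression vector.
#'
#' @param e Non-negative expression vector over at least two categories.
#' @return Tau in `[0, 1]`, or `NA` (with a warning) for an all-zero vector.
#' @export
tau_score <- function(e) {
  if (length(e) < 2) abort_param("tau requires at least two categories")
  if (any(e < 0) || anyNA(e)) abort_param("expression must be non-negative")
  mx <- max(e)
  if (mx == 0) {
    warning("all-zero expression vector: tau undefined", call. = FALSE)
    return(NA_real_)
  }
  sum((1 - e / mx)^2) / (length(e) - 1)
}

#' Z-score tissue specificity
#'
#' Standardizes a gene's expression across categories using the sample
#' standard deviation (n - 1 denominator):
#' \deqn{x_i = (e_i - \bar e) / \mathrm{sd}(e)}
#' A positive component marks over-representation in that category, a
#' negative one under-representation. For a constant vector all components
#' are set to 0 and the result carries attribute `constant = TRUE`.
#'
#' @param e Expression vector over at least two categories.
#' @return Numeric vector of per-category z-scores.
#' @export
zscore_specificity <- function(e) {
  if (length(e) < 2) abort_param("z-score requires at least two categories")
  s <- stats::sd(e)
  if (is.na(s) || s == 0) {
    out <- rep(0, length(e))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (e - mean(e)) / s
}

#' Symmetric min-max rescaling to [-1, 1]
#'
#' Rescales a per-gene index so the maximum maps exactly to 1 and the
#' minimum to -1: `x' = 2 (x - min) / (max - min) - 1`. A constant vector
#' maps to all zeros with attribute `constant = TRUE`.
#'
#' @param x Numeric vector (at least two values for a meaningful range).
#' @return Rescaled vector in `[-1, 1]`.
#' @export
minmax_symmetric <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng))) abort_param("input has no finite values")
  if (rng[1] == rng[2]) {
    out <- ifelse(is.na(x), NA_real_, 0)
    attr(out, "constant") <- TRUE
    return(out)
  }
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

# per-gene z-score matrix across the columns of a gene x category matrix;
# constant rows become 0
row_zscore <- function(m) {
  s <- row_sds(m)
  z <- (m - rowMeans(m)) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[s == 0]
  z
}

#' Testis-specificity index from tissue expression atlases
#'
#' For each atlas, every gene's expression across tissues is z-scored, the
#' testis component is taken, and that per-gene index is min-max rescaled to
#' `[-1, 1]` over the genes of the atlas (1 = most testis-specific). The
#' final index (`tsp`) is the mean of the per-atlas rescaled indices over
#' the atlases in which the gene is present. Tau is computed per atlas the
#' same way and averaged.
#'
#' @param atlases A list of `expr_tbl` atlases (one column per tissue); each
#'   must contain a column whose `category` equals `testis_label`.
#' @param testis_label Category name of the testis column; default
#'   `"testis"`.
#' @param rescale `"per_atlas"` (default) rescales within each atlas before
#'   averaging; `"after_mean"` averages the raw testis z-scores first and
#'   rescales once.
#' @param log2_expression If `TRUE`, apply `log2(x + 1)` to atlas expression
#'   before z-scoring; default `FALSE`.
#' @return A tibble with columns `gene_id`, `tau`, `tsp`, and one
#'   `tsp_<atlas>` column per atlas (NA where the gene is absent).
#' @export
testis_specificity <- function(atlases, testis_label = "testis",
                               rescale = c("per_atlas", "after_mean"),
                               log2_expression = FALSE) {
  rescale <- match.arg(rescale)
  if (!length(atlases)) abort_param("at least one atlas is required")
  if (is.null(names(atlases)) || any(!nzchar(names(atlases)))) {
    names(atlases) <- paste0("atlas", seq_along(atlases))
  }
  genes <- unique(unlist(lapply(atlases, function(a) a$gene_id)))
  per_atlas_idx <- matrix(NA_real_, length(genes), length(atlases),
                          dimnames = list(genes, names(atlases)))
  per_atlas_z <- per_atlas_idx
  per_atlas_tau <- per_atlas_idx
  for (j in seq_along(atlases)) {
    a <- atlases[[j]]
    meta <- col_meta(a)
    tcol <- meta$column_id[meta$category == testis_label]
    if (length(tcol) != 1) {
      abort_param(paste0("atlas `", names(atlases)[j],
                         "` must have exactly one `", testis_label,
                         "` column"))
    }
    m <- expr_matrix(a)
    if (log2_expression) m <- log2(m + 1)
    z <- row_zscore(m)
    per_atlas_z[rownames(m), j] <- z[, tcol]
    per_atlas_tau[rownames(m), j] <-
      apply(m, 1, function(e) if (max(e) > 0) tau_score(e) else NA_real_)
    if (rescale == "per_atlas") {
      per_atlas_idx[rownames(m), j] <- minmax_symmetric(z[, tcol])
    }
  }
  if (rescale == "per_atlas") {
    tsp <- rowMeans(per_atlas_idx, na.rm = TRUE)
  } else {
    tsp <- minmax_symmetric(rowMeans(per_atlas_z, na.rm = TRUE))
  }
  tsp[is.nan(tsp)] <- NA_real_
  out <- tibble::tibble(
    gene_id = genes,
    tau = unname(rowMeans(per_atlas_tau, na.rm = TRUE)),
    tsp = unname(as.numeric(tsp)))
  out$tau[is.nan(out$tau)] <- NA_real_
  idx <- tibble::as_tibble(per_atlas_idx)
  names(idx) <- paste0("tsp_", names(atlases))
  dplyr::bind_cols(out, idx)
}
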