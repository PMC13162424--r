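#' Mean expression per annotated category
#'
#' Collapses an expression table to one column per category by averaging
#' the columns that share that category annotation. Category order follows
#' first appearance in the column metadata.
#'
#' @param x An `expr_tbl`.
#' @return A tibble: `gene_id` plus one numeric column per category.
#' @export
aggregate_categories <- function(x) {
  meta <- col_meta(x)
  m <- expr_matrix(x)
  cats <- unique(meta$category)
  out <- vapply(cats, function(cc) {
    cols <- meta$column_id[meta$category == cc]
    if (!length(cols)) abort_format(paste0("category `", cc, "` has no columns"))
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, cats))
  dplyr::bind_cols(tibble::tibble(gene_id = x$gene_id),
                   tibble::as_tibble(out))
}

#' Per-dataset specificity (row-wise z-score across categories)
#'
#' Applies [zscore_specificity()] per gene across one dataset's category
#' means, keeping every category as a dimension. Constant rows become
#' zeros; their gene ids are recorded in the `constant_rows` attribute.
#'
#' @param means A tibble from [aggregate_categories()] (`gene_id` + one
#'   column per category; at least two categories).
#' @return A tibble of the same shape with z-scores.
#' @export
dataset_specificity <- function(means) {
  cats <- setdiff(names(means), "gene_id")
  if (length(cats) < 2) abort_param("need at least two categories")
  m <- as.matrix(means[cats])
  rownames(m) <- means$gene_id
  z <- row_zscore(m)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = means$gene_id),
                          tibble::as_tibble(z))
  attr(out, "constant_rows") <- attr(z, "constant_rows")
  out
}

#' Per-dataset overall expression level
#'
#' Reduces one dataset's category means to a single expression dimension
#' per gene (arithmetic mean by default, maximum as an option), the single
#' column through which expression magnitude enters the feature table.
#'
#' @param means A tibble from [aggregate_categories()].
#' @param reduce `"mean"` (default) or `"max"`.
#' @return A tibble `gene_id`, `expression`.
#' @export
dataset_mean_expression <- function(means, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  m <- as.matrix(means[setdiff(names(means), "gene_id")])
  v <- if (reduce == "mean") rowMeans(m) else apply(m, 1, max)
  tibble::tibble(gene_id = means$gene_id, expression = as.numeric(v))
}

#' Assemble the gene-by-feature table from all testis sources
#'
#' For every source the feature block is its per-category specificity
#' z-scores (one dimension per category, named `{source}:{category}:z`)
#' plus a single overall-expression dimension (`{source}:mean`), so a
#' source with k categories contributes k + 1 features and higher-resolution
#' sources get proportionally more representation while raw expression
#' magnitude is confined to one dimension per source.
#'
#' @param sources Named list of `expr_tbl` objects, one per source.
#' @param gene_policy `"intersect"` (default) keeps genes present in every
#'   source; `"union"` keeps all genes, imputing a missing source block with
#'   zeros and recording the gene/source pair in the `imputed` attribute.
#' @param expression_reduce Passed to [dataset_mean_expression()].
#' @return A tibble `gene_id` + one named column per feature
#'   (unstandardized; see [standardize_features()]).
#' @export
assemble_features <- function(sources, gene_policy = c("intersect", "union"),
                              expression_reduce = c("mean", "max")) {
  gene_policy <- match.arg(gene_policy)
  expression_reduce <- match.arg(expression_reduce)
  if (!length(sources)) abort_param("at least one source is required")
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  gene_sets <- lapply(sources, function(s) s$gene_id)
  genes <- if (gene_policy == "intersect") {
    Reduce(intersect, gene_sets)
  } else {
    unique(unlist(gene_sets))
  }
  if (!length(genes)) abort_param("empty gene intersection across sources")
  blocks <- vector("list", length(sources))
  imputed <- list()
  for (j in seq_along(sources)) {
    sname <- names(sources)[j]
    means <- aggregate_categories(sources[[j]])
    z <- dataset_specificity(means)
    ex <- dataset_mean_expression(means, reduce = expression_reduce)
    cats <- setdiff(names(means), "gene_id")
    block <- matrix(0, length(genes), length(cats) + 1,
                    dimnames = list(genes,
                                    c(paste0(sname, ":", cats, ":z"),
                                      paste0(sname, ":mean"))))
    present <- intersect(genes, z$gene_id)
    block[present, seq_along(cats)] <-
      as.matrix(z[match(present, z$gene_id), cats])
    block[present, length(cats) + 1] <-
      ex$expression[match(present, ex$gene_id)]
    absent <- setdiff(genes, present)
    if (length(absent)) {
      imputed[[sname]] <- tibble::tibble(gene_id = absent, source_id = sname)
    }
    blocks[[j]] <- block
  }
  out <- dplyr::bind_cols(tibble::tibble(gene_id = genes),
                          tibble::as_tibble(do.call(cbind, blocks)))
  attr(out, "imputed") <- if (length(imputed)) {
    dplyr::bind_rows(imputed)
  } else {
    tibble::tibble(gene_id = character(), source_id = character())
  }
  out
}

#' Column-wise standard-score normalization of a feature table
#'
#' Standardizes every feature column to mean 0 and sample sd 1. Constant
#' columns become zeros and are listed in the `constant_columns` attribute.
#' The operation is idempotent up to floating-point error.
#'
#' @param features A tibble with `gene_id` plus numeric feature columns.
#' @return The standardized tibble.
#' @export
standardize_features <- function(features) {
  cols <- setdiff(names(features), "gene_id")
  m <- as.matrix(features[cols])
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  const <- s == 0 | is.na(s)
  s[const] <- 1
  z <- sweep(sweep(m, 2, mu), 2, s, "/")
  z[, const] <- 0
  out <- dplyr::bind_cols(features["gene_id"], tibble::as_tibble(z))
  attr(out, "constant_columns") <- cols[const]
  out
}
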