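#' Embed the feature table in two dimensions
#'
#' Runs t-SNE (default) or UMAP on the standardized gene-by-feature table.
#' The embedding algorithms are delegated to their reference R
#' implementations (Rtsne, uwot); this function fixes the parameters and
#' seed, validates the input, and returns a tidy coordinate table. Default
#' parameters: t-SNE with perplexity 100, early exaggeration 19, 1000
#' iterations; UMAP with 50 neighbours; seed 106 for both.
#'
#' @param features Tibble `gene_id` + numeric feature columns, no missing
#'   values.
#' @param method `"tsne"` or `"umap"`.
#' @param perplexity,early_exaggeration,n_iter t-SNE parameters. If the
#'   gene count is too small for the requested perplexity it is reduced
#'   with a warning.
#' @param n_neighbors UMAP neighbourhood size.
#' @param seed Integer seed (default 106).
#' @return A tibble `gene_id`, `dim1`, `dim2` with attributes `method`,
#'   `params`, `seed`.
#' @export
embed_genes <- function(features, method = c("tsne", "umap"),
                        perplexity = 100, early_exaggeration = 19,
                        n_iter = 1000, n_neighbors = 50, seed = 106) {
  method <- match.arg(method)
  m <- as.matrix(features[setdiff(names(features), "gene_id")])
  if (anyNA(m)) abort_param("feature table contains missing values")
  n <- nrow(m)
  if (method == "tsne") {
    max_perp <- floor((n - 1) / 3)
    if (perplexity > max_perp) {
      warning(sprintf("perplexity %g too large for %d genes; reduced to %d",
                      perplexity, n, max_perp), call. = FALSE)
      perplexity <- max_perp
    }
    coords <- withr::with_seed(seed, {
      Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                   exaggeration_factor = early_exaggeration,
                   max_iter = n_iter, check_duplicates = FALSE,
                   pca = FALSE, num_threads = 1)$Y
    })
    params <- list(perplexity = perplexity,
                   early_exaggeration = early_exaggeration, n_iter = n_iter)
  } else {
    coords <- withr::with_seed(seed, {
      uwot::umap(m, n_neighbors = n_neighbors, n_threads = 1,
                 n_sgd_threads = 1)
    })
    params <- list(n_neighbors = n_neighbors)
  }
  out <- tibble::tibble(gene_id = features$gene_id,
                        dim1 = coords[, 1], dim2 = coords[, 2])
  attr(out, "method") <- method
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' Min-max normalize embedding coordinates to the unit square
#'
#' Rescales each axis independently to `[0, 1]` so density-clustering radii
#' are comparable across embeddings of arbitrary scale. Idempotent.
#'
#' @param embedding Tibble with `dim1`, `dim2` columns (other columns kept).
#' @return The tibble with rescaled coordinates.
#' @export
normalize_embedding <- function(embedding) {
  for (cn in c("dim1", "dim2")) {
    v <- embedding[[cn]]
    rng <- range(v)
    if (rng[1] == rng[2]) abort_param("degenerate axis: all values equal")
    embedding[[cn]] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  embedding
}
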