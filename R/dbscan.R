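#' Density-based clustering (DBSCAN) labels
#'
#' Deterministic DBSCAN with Euclidean distances. A point is a core point
#' when at least `min_samples` points (itself included) lie within `eps`.
#' Clusters are grown from core points in row order; a border point is
#' claimed by the first cluster whose expansion reaches it, i.e. by the
#' lowest-numbered cluster containing a core point within `eps`. Points
#' reachable from no core point are noise, labelled `-1`. Cluster ids are
#' assigned in first-touch order starting at 0.
#'
#' @param x Numeric matrix (points in rows) or data frame of coordinates.
#' @param eps Neighbourhood radius (> 0).
#' @param min_samples Minimum neighbourhood size for a core point (>= 1).
#' @return Integer label vector, one per row; noise = -1.
#' @export
dbscan_labels <- function(x, eps, min_samples) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (eps <= 0) abort_param("eps must be positive")
  if (min_samples < 1) abort_param("min_samples must be >= 1")
  n <- nrow(x)
  eps2 <- eps^2
  sq <- rowSums(x^2)
  # neighbour lists computed block-wise to bound memory
  nbr <- vector("list", n)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(s + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    for (r in seq_along(idx)) {
      nbr[[idx[r]]] <- which(d2[r, ] <= eps2 + 1e-12)
    }
  }
  core <- lengths(nbr) >= min_samples
  labels <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr[[i]], i)
    qpos <- 1L
    while (qpos <= length(queue)) {
      j <- queue[qpos]
      qpos <- qpos + 1L
      if (is.na(labels[j]) || labels[j] == -1L) {
        first_visit <- is.na(labels[j])
        labels[j] <- cl
        if (first_visit && core[j]) {
          queue <- c(queue, setdiff(nbr[[j]], queue))
        }
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Cluster an embedding with DBSCAN
#'
#' Applies [dbscan_labels()] to 2-D embedding coordinates. By default the
#' coordinates are min-max normalized to the unit square first, so radii
#' such as 0.11/0.12 are meaningful regardless of the embedding's scale;
#' set `normalize = FALSE` to cluster raw coordinates.
#'
#' @param embedding Tibble `gene_id`, `dim1`, `dim2` (see [embed_genes()]).
#' @param eps Neighbourhood radius (default 0.11).
#' @param min_samples Core-point neighbourhood size (default 60).
#' @param normalize Normalize coordinates to `[0, 1]^2` first (default
#'   `TRUE`).
#' @return A `gene_clusters` tibble `gene_id`, `dim1`, `dim2`, `cluster`
#'   (noise = -1) with attributes `eps`, `min_samples`.
#' @export
cluster_embedding <- function(embedding, eps = 0.11, min_samples = 60,
                              normalize = TRUE) {
  pts <- if (normalize) normalize_embedding(embedding) else embedding
  labels <- dbscan_labels(as.matrix(pts[c("dim1", "dim2")]), eps, min_samples)
  out <- tibble::tibble(gene_id = embedding$gene_id,
                        dim1 = pts$dim1, dim2 = pts$dim2,
                        cluster = labels)
  attr(out, "eps") <- eps
  attr(out, "min_samples") <- min_samples
  class(out) <- unique(c("gene_clusters", class(out)))
  out
}

#' Profile cluster groups
#'
#' Summarises every DBSCAN group (noise included, as group -1) by its size,
#' mean testis-specificity index, and per-feature mean of the
#' (unstandardized) specificity dimensions — the numbers a group heatmap
#' displays.
#'
#' @param clusters A `gene_clusters` tibble (see [cluster_embedding()]).
#' @param features Unstandardized feature tibble from
#'   [assemble_features()]; only `:z` columns are profiled.
#' @param tsp Tibble `gene_id`, `tsp` (see [testis_specificity()]).
#' @return A tibble: `cluster`, `n`, `mean_tsp`, then one column per
#'   specificity feature.
#' @export
profile_groups <- function(clusters, features, tsp) {
  zcols <- grep(":z$", names(features), value = TRUE)
  df <- dplyr::left_join(
    dplyr::left_join(clusters[c("gene_id", "cluster")],
                     tsp[c("gene_id", "tsp")], by = "gene_id"),
    features[c("gene_id", zcols)], by = "gene_id")
  df |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_tsp = mean(.data$tsp, na.rm = TRUE),
      dplyr::across(dplyr::all_of(zcols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::arrange(.data$cluster)
}

#' Genes of one cluster group
#'
#' @param clusters A `gene_clusters` tibble.
#' @param group_id Cluster id (noise = -1).
#' @return Character vector of member gene ids.
#' @export
select_group_genes <- function(clusters, group_id) {
  if (!group_id %in% clusters$cluster) {
    abort_param(paste0("no such cluster group: ", group_id))
  }
  clusters$gene_id[clusters$cluster == group_id]
}
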