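#' Construct an annotated expression table
#'
#' An expression table is a tibble with a `gene_id` column followed by one
#' numeric, non-negative column per measured sample/category, plus a column
#' metadata table mapping every measurement column to a `(source_id,
#' category)` pair. The metadata travels with the tibble as the `col_meta`
#' attribute and is recovered with [col_meta()].
#'
#' @param values A data frame whose first column is `gene_id` (unique) and
#'   whose remaining columns are non-negative numerics.
#' @param metadata A data frame with columns `column_id`, `source_id`,
#'   `category` covering every measurement column of `values`.
#' @return A tibble of class `expr_tbl` with the metadata attached.
#' @export
expression_table <- function(values, metadata) {
  values <- tibble::as_tibble(values)
  metadata <- tibble::as_tibble(metadata)
  if (!identical(names(values)[1], "gene_id")) {
    abort_format("first column of an expression table must be `gene_id`")
  }
  if (anyDuplicated(values$gene_id)) {
    abort_format("duplicated gene ids in expression table")
  }
  need <- c("column_id", "source_id", "category")
  if (!all(need %in% names(metadata))) {
    abort_format("metadata must have columns column_id, source_id, category")
  }
  meas <- setdiff(names(values), "gene_id")
  missing_meta <- setdiff(meas, metadata$column_id)
  if (length(missing_meta)) {
    abort_format(paste0(
      "expression columns without metadata: ",
      paste(missing_meta, collapse = ", ")
    ))
  }
  metadata <- metadata[match(meas, metadata$column_id), need]
  if (any(!nzchar(metadata$source_id)) || any(!nzchar(metadata$category)) ||
      anyNA(metadata$source_id) || anyNA(metadata$category)) {
    abort_format("source_id and category must be non-empty for every column")
  }
  for (cn in meas) {
    v <- values[[cn]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      abort_format(paste0("column `", cn, "` must be numeric and non-negative"))
    }
  }
  attr(values, "col_meta") <- metadata
  class(values) <- unique(c("expr_tbl", class(values)))
  values
}

#' Column metadata of an expression table
#' @param x An `expr_tbl`.
#' @return A tibble with columns `column_id`, `source_id`, `category`.
#' @export
col_meta <- function(x) {
  m <- attr(x, "col_meta")
  if (is.null(m)) abort_format("not an annotated expression table")
  m
}

# expression values as a gene x column numeric matrix
expr_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read an expression table with its column metadata
#'
#' @param path TSV with gene ids in the first column (`gene_id`) and
#'   non-negative numeric expression values elsewhere.
#' @param metadata_path TSV with header `column_id`, `source_id`, `category`
#'   mapping every measurement column.
#' @return An `expr_tbl` (see [expression_table()]).
#' @export
read_expression_table <- function(path, metadata_path) {
  values <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(values)[1] <- "gene_id"
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                              progress = FALSE)
  expression_table(values, metadata)
}

#' Write an expression table and its column metadata
#' @param x An `expr_tbl`.
#' @param path,metadata_path Output TSV paths.
#' @return `x`, invisibly.
#' @export
write_expression_table <- function(x, path, metadata_path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  readr::write_tsv(col_meta(x), metadata_path, progress = FALSE)
  invisible(x)
}

#' Read transcription start sites from a BED6 file
#'
#' Coordinates stay 0-based half-open as on disk. The TSS base of a
#' plus-strand gene is `start`; of a minus-strand gene, `end - 1`.
#'
#' @param path BED6 file (chrom, start, end, gene_id, score, strand).
#' @return A tibble with columns `chrom`, `start`, `end`, `gene_id`,
#'   `strand`; empty input gives a zero-row tibble.
#' @export
read_tss_table <- function(path) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), gene_id = character(),
                          strand = character())
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(empty)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "character", "character"),
                         col.names = c("chrom", "start", "end", "gene_id",
                                       "score", "strand"))
  if (nrow(x) == 0) return(empty)
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort_format("BED records must satisfy 0 <= start < end")
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort_format("BED strand must be '+' or '-'")
  }
  if (anyDuplicated(x$gene_id)) {
    abort_format("duplicated gene_id in TSS table")
  }
  tibble::as_tibble(x[c("chrom", "start", "end", "gene_id", "strand")])
}

#' Write transcription start sites as BED6
#' @param x A TSS tibble as returned by [read_tss_table()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_tss_table <- function(x, path) {
  bed <- data.frame(x$chrom, x$start, x$end, x$gene_id, 0L, x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Read a gene set (one id per line)
#'
#' Lines starting with `#` and blank lines are ignored; ids are
#' de-duplicated. An empty result triggers a warning, not an error.
#'
#' @param path Plain-text file.
#' @return Character vector of unique gene ids.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (length(ids) == 0) warning("gene set file is empty", call. = FALSE)
  ids
}

#' Write a gene set (one id per line)
#' @param ids Character vector.
#' @param path Output path.
#' @return `ids`, invisibly.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(ids)
}

#' Read/write cluster assignment tables
#'
#' Cluster tables are TSV with columns `gene_id`, `dim1`, `dim2`, `cluster`
#' (noise = -1); hit tables are TSV with columns `gene_id`, `motif_id`,
#' `offset`, `strand`, `relative_score`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_cluster_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    dim1 = readr::col_double(),
                    dim2 = readr::col_double(),
                    cluster = readr::col_integer()))
}

#' @rdname read_cluster_table
#' @param x Tibble to write.
#' @export
write_cluster_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname read_cluster_table
#' @export
read_hits_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    motif_id = readr::col_character(),
                    offset = readr::col_integer(),
                    strand = readr::col_character(),
                    relative_score = readr::col_double()))
}

#' @rdname read_cluster_table
#' @export
write_hits_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}
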