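# Internal helpers: typed conditions and small utilities.

abort_format <- function(msg, ...) {
  rlang::abort(message = msg, class = "testistools_format_error", ...)
}

abort_param <- function(msg, ...) {
  rlang::abort(message = msg, class = "testistools_parameter_error", ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample standard deviation row-wise on a numeric matrix
row_sds <- function(m) {
  n <- ncol(m)
  ctr <- m - rowMeans(m)
  sqrt(rowSums(ctr^2) / (n - 1))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
}

# derive a child seed from a user seed, staying inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}
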