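# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a base seed and a stage label.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  val <- (as.double(seed) * 48271 + h * 16807 + as.double(index) * 69621) %% 2147483399
  as.integer(val + 1)
}

# Euclidean projection of each row of `m` onto the probability simplex
# (sort-and-threshold), fully vectorised across rows: one global order()
# call gives the row-wise descending sort, cumulative sums come from a
# triangular matrix product, and the per-row threshold rank is the count
# of positions satisfying the (monotone) support condition.
project_rows_simplex <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  n <- nrow(m); k <- ncol(m)
  if (k == 1L) return(matrix(1, n, 1L, dimnames = dimnames(m)))
  o <- order(row(m), -m)
  srt <- matrix(m[o], nrow = n, byrow = TRUE)
  tri <- upper.tri(matrix(0, k, k), diag = TRUE)
  css <- srt %*% tri
  cond <- srt + (1 - css) / rep(seq_len(k), each = n) > 0
  rho <- rowSums(cond)
  theta <- (css[cbind(seq_len(n), rho)] - 1) / rho
  out <- pmax(m - theta, 0)
  dimnames(out) <- dimnames(m)
  out
}

# Stop with a classed condition so callers/tests can match on class.
ds_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "dispersalscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-triangle (i < j) index pairs of an n x n matrix.
upper_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
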