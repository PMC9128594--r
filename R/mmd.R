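#' Class-wise MMD quadratic-form matrix
#'
#' Builds the matrix `Q` for which `tr(A Q t(A))` equals the squared Euclidean
#' distance between the source-column mean and the target-column mean of a
#' code matrix `A` whose columns are ordered sources-first.  Entries take only
#' three values: `1/ns^2` within source, `1/nt^2` within target, and
#' `-1/(ns*nt)` across; consequently `Q` is symmetric, positive semidefinite
#' of rank 1, and has zero row sums.  `Q` is the rank-1 outer product
#' `q t(q)` with `q = c(rep(1/ns, ns), rep(-1/nt, nt))`.
#'
#' @param n_source pooled source sample count for the class (`>= 1`).
#' @param n_target target sample count for the class (`>= 1`).
#' @return object of class `"mmd_matrix"`: list with `Q` (numeric matrix),
#'   `n_source`, `n_target`, `column_order` (`"source"`/`"target"` per column).
#' @examples
#' q <- mmd_matrix(2, 2)
#' q$Q                       # entries +-0.25
#' rowSums(q$Q)              # all zero
#' @seealso [mmd_value()]
#' @export
mmd_matrix <- function(n_source, n_target) {
  n_source <- as.integer(n_source); n_target <- as.integer(n_target)
  if (is.na(n_source) || n_source < 1L || is.na(n_target) || n_target < 1L)
    stop("class absent from a domain: the MMD term is undefined")
  v <- c(rep(1 / n_source, n_source), rep(-1 / n_target, n_target))
  structure(list(Q = tcrossprod(v),
                 n_source = n_source, n_target = n_target,
                 column_order = rep(c("source", "target"),
                                    c(n_source, n_target))),
            class = "mmd_matrix")
}

#' Evaluate the class-wise MMD of a code matrix
#'
#' Computes `tr(codes %*% Q %*% t(codes))`, the squared distance between the
#' mean source column and the mean target column of `codes`.
#'
#' @param codes numeric matrix, one column per sample, columns ordered to
#'   match `q$column_order` (sources first).
#' @param q an [mmd_matrix()].
#' @return a single nonnegative number.
#' @examples
#' q <- mmd_matrix(2, 2)
#' mmd_value(matrix(c(0, 0, 1, 1), 1), q)  # means 0 vs 1 -> 1
#' @export
mmd_value <- function(codes, q) {
  stopifnot(inherits(q, "mmd_matrix"))
  codes <- as.matrix(codes)
  if (ncol(codes) != nrow(q$Q))
    stop("codes have ", ncol(codes), " columns but Q is ", nrow(q$Q), "-square")
  sum(diag(codes %*% q$Q %*% t(codes)))
}

#' @export
print.mmd_matrix <- function(x, ...) {
  cat("MMD quadratic form: ", x$n_source, " source + ", x$n_target,
      " target columns\n", sep = "")
  invisible(x)
}
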