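#' Predict class labels with a fitted TDDPL model
#'
#' Applies the coding-free decision rule: the score of a sample `x` is
#' `s = sum_k W_k P_k Omega_k x` and the label is the argmax of `s`, ties
#' broken toward the smallest class index.  Only the classifier, analysis
#' dictionaries and projections are used — never the synthesis dictionary or
#' any training codes.
#'
#' @param object a fitted `"tddpl"` model.
#' @param newdata numeric matrix `d x M` (or a vector of length `d`), columns
#'   are samples.
#' @param type `"class"` for integer labels, `"score"` for the `K x M` score
#'   matrix.
#' @param ... unused.
#' @return integer labels in `1..K`, or the score matrix.
#' @export
predict.tddpl <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (is.null(dim(newdata))) matrix(newdata, ncol = 1) else
    as.matrix(newdata)
  if (nrow(X) != object$d)
    stop("newdata has ", nrow(X), " rows; model expects d = ", object$d)
  S <- coef(object) %*% X
  if (type == "score") return(S)
  max.col(t(S), ties.method = "first")
}

#' Effective linear classifier of a TDDPL model
#'
#' The stacked `K x d` matrix `sum_k W_k P_k Omega_k` whose rows score the
#' classes; prediction is `argmax` over its product with a sample.
#'
#' @param object a `"tddpl"` model.
#' @param ... unused.
#' @return numeric `K x d` matrix.
#' @export
coef.tddpl <- function(object, ...) {
  Reduce(`+`, lapply(seq_len(object$K), function(k)
    object$W[[k]] %*% object$P[[k]] %*% object$Omega[[k]]))
}

#' @export
print.tddpl <- function(x, ...) {
  cat("Transfer discriminative dictionary pair learning model\n")
  cat("  classes: ", x$K, ", feature dim: ", x$d, ", subspace dim: ",
      x$hp$m, ", atoms/class: ", x$hp$r, "\n", sep = "")
  cat("  sources: ", x$n_sources, if (x$hp$lambda2 > 0)
    "  (MMD alignment on)" else "  (no MMD term)", "\n", sep = "")
  cat("  ", x$report$iterations, " iterations, stopped on ",
      x$report$stop_reason, ", final objective ",
      format(tail_obj(x), digits = 6), "\n", sep = "")
  invisible(x)
}

tail_obj <- function(x) {
  tr <- x$report$objective
  if (length(tr)) tr[length(tr)] else NA_real_
}

#' @export
summary.tddpl <- function(object, ...) {
  out <- list(K = object$K, d = object$d, hp = object$hp,
              iterations = object$report$iterations,
              stop_reason = object$report$stop_reason,
              objective = object$report$objective,
              dict_col_norms = vapply(object$D, function(D)
                max(sqrt(colSums(D^2))), numeric(1)),
              code_rank = vapply(seq_len(object$K), function(k)
                qr(object$Lambda[[k]] %*% object$Theta[[k]])$rank,
                integer(1)))
  class(out) <- "summary.tddpl"
  out
}

#' @export
print.summary.tddpl <- function(x, ...) {
  cat("TDDPL fit: K =", x$K, ", d =", x$d, ", m =", x$hp$m,
      ", r =", x$hp$r, "\n")
  cat("lambda =", paste(unlist(x$hp[paste0("lambda", 1:5)]), collapse = "/"),
      " gamma =", x$hp$gamma, "\n")
  cat(x$iterations, "iterations (", x$stop_reason, "); objective",
      format(x$objective[1], digits = 6), "->",
      format(x$objective[length(x$objective)], digits = 6), "\n")
  cat("max dictionary column norms:",
      paste(format(x$dict_col_norms, digits = 4), collapse = " "), "\n")
  cat("rank of Lambda Theta per class:",
      paste(x$code_rank, collapse = " "), "\n")
  invisible(x)
}

#' Plot the objective trace of a TDDPL fit
#'
#' @param x a `"tddpl"` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tddpl <- function(x, ...) {
  obj <- x$report$objective
  plot(seq_along(obj), obj, type = "b", xlab = "iteration",
       ylab = "objective", main = "TDDPL objective trace", ...)
  invisible(x)
}
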