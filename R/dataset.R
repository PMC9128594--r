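#' Multi-domain labeled dataset
#'
#' Bundles feature matrices from `n` source domains (auxiliary subjects) and
#' one target domain (the subject to be decoded) into the container consumed
#' by [tddpl()].  Columns are samples, rows are feature dimensions; every
#' domain must share the feature dimension and every class must be present in
#' every block, because the per-class sub-dictionary and MMD terms are
#' undefined for a class absent from a domain.
#'
#' @param sources list of source blocks, each a list with elements `X`
#'   (numeric matrix, features x samples) and `labels` (integer vector of
#'   class labels in `1..K`).  May be empty for a single-domain (pooled) fit.
#' @param target target block, same structure as one source block.
#' @param n_classes number of classes `K`; defaults to the largest label seen.
#' @return an object of class `"multidomain"`: a list with `blocks` (named
#'   `source_1..source_n`, `target`), `d`, `K`, `n_sources`.
#' @examples
#' X <- matrix(rnorm(20), 4, 5)
#' dat <- multidomain_dataset(
#'   sources = list(list(X = X, labels = c(1, 1, 2, 2, 1))),
#'   target  = list(X = X + 1, labels = c(1, 2, 1, 2, 2)))
#' dat$K
#' @export
multidomain_dataset <- function(sources = list(), target, n_classes = NULL) {
  blocks <- c(sources, list(target))
  names(blocks) <- c(if (length(sources))
    paste0("source_", seq_along(sources)) else character(0), "target")
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!is.list(b) || is.null(b$X) || is.null(b$labels))
      stop("block '", nm, "' must be a list with elements X and labels")
    b$X <- as.matrix(b$X)
    b$labels <- as.integer(b$labels)
    if (ncol(b$X) != length(b$labels))
      stop("block '", nm, "': ncol(X) != length(labels)")
    if (!all(is.finite(b$X))) stop("block '", nm, "': non-finite features")
    blocks[[nm]] <- b
  }
  d <- unique(vapply(blocks, function(b) nrow(b$X), integer(1)))
  if (length(d) != 1L) stop("all blocks must share the feature dimension d")
  K <- n_classes %||% max(vapply(blocks, function(b) max(b$labels), integer(1)))
  for (nm in names(blocks)) {
    lab <- blocks[[nm]]$labels
    if (any(lab < 1L | lab > K))
      stop("block '", nm, "': labels outside 1..", K)
    missing <- setdiff(seq_len(K), unique(lab))
    if (length(missing))
      stop("class ", paste(missing, collapse = ", "),
           " absent from domain '", nm, "'")
  }
  structure(list(blocks = blocks, d = d, K = as.integer(K),
                 n_sources = length(sources)),
            class = "multidomain")
}

#' @export
print.multidomain <- function(x, ...) {
  cat("Multi-domain dataset: ", x$n_sources, " source(s) + target, d = ",
      x$d, ", K = ", x$K, "\n", sep = "")
  for (nm in names(x$blocks))
    cat("  ", nm, ": ", ncol(x$blocks[[nm]]$X), " samples\n", sep = "")
  invisible(x)
}

## class-k columns pooled over all domains, sources first then target;
## returns list(X, domain = "source"/"target" tag per column)
pool_class <- function(data, k) {
  xs <- list(); tags <- character(0)
  for (nm in names(data$blocks)) {
    b <- data$blocks[[nm]]
    sel <- b$labels == k
    if (any(sel)) {
      xs[[length(xs) + 1L]] <- b$X[, sel, drop = FALSE]
      tags <- c(tags, rep(if (nm == "target") "target" else "source", sum(sel)))
    }
  }
  list(X = do.call(cbind, xs), domain = tags)
}

## all non-class-k columns pooled over all domains
pool_complement <- function(data, k) {
  xs <- lapply(data$blocks, function(b) b$X[, b$labels != k, drop = FALSE])
  do.call(cbind, xs)
}

## pool every block into one single-domain dataset (no-transfer baseline input)
pool_domains <- function(data) {
  X <- do.call(cbind, lapply(data$blocks, `[[`, "X"))
  labels <- unlist(lapply(data$blocks, `[[`, "labels"), use.names = FALSE)
  multidomain_dataset(sources = list(),
                      target = list(X = X, labels = labels),
                      n_classes = data$K)
}

#' Write / read a multi-domain dataset as delimited text
#'
#' `write_domains()` stores a dataset as two tab-separated files in `dir`:
#' `features.tsv` (one row per feature dimension, one column per sample) and
#' `manifest.tsv` (columns `sample_id`, `domain_id`, `label`).
#' `read_domains()` reconstructs the dataset.
#'
#' @param data a `"multidomain"` object.
#' @param dir directory to write to / read from (created if needed).
#' @return `write_domains()` returns `dir` invisibly; `read_domains()` a
#'   `"multidomain"` object.
#' @export
write_domains <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- do.call(cbind, lapply(data$blocks, `[[`, "X"))
  ids <- paste0("s", seq_len(ncol(X)))
  colnames(X) <- ids
  man <- data.frame(
    sample_id = ids,
    domain_id = rep(names(data$blocks),
                    vapply(data$blocks, function(b) ncol(b$X), integer(1))),
    label = unlist(lapply(data$blocks, `[[`, "labels"), use.names = FALSE))
  write.table(X, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_domains
#' @export
read_domains <- function(dir) {
  X <- as.matrix(read.table(file.path(dir, "features.tsv"),
                            header = TRUE, sep = "\t", check.names = FALSE))
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  doms <- unique(man$domain_id)
  blocks <- lapply(doms, function(dm) {
    sel <- man$domain_id == dm
    list(X = unname(X[, man$sample_id[sel], drop = FALSE]),
         labels = man$label[sel])
  })
  names(blocks) <- doms
  multidomain_dataset(sources = blocks[doms != "target"],
                      target = blocks[["target"]])
}

## stratified index split: fraction per class into "in", rest "out"; at least
## one sample per class on each side requires >= 2 samples per class
split_stratified <- function(labels, fraction) {
  idx_in <- integer(0)
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    n_in <- max(1L, round(length(idx) * fraction))
    if (n_in >= length(idx)) n_in <- length(idx) - 1L
    if (n_in < 1L) stop("class ", k, " too small to split")
    idx_in <- c(idx_in, sample(idx, n_in))
  }
  sort(idx_in)
}
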