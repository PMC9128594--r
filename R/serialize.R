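#' Serialize / restore a fitted TDDPL model
#'
#' `write_tddpl()` stores a model as a directory holding `manifest.json`
#' (shapes, hyperparameters, matrix index) and `matrices.bin` (all matrix
#' entries as raw doubles, column-major, in manifest order).  The round trip
#' through `read_tddpl()` is bit-exact, so identical fits serialize to
#' identical bytes.
#'
#' @param model a `"tddpl"` object.
#' @param dir directory to write to / read from (created if needed).
#' @return `write_tddpl()` returns `dir` invisibly; `read_tddpl()` the
#'   restored `"tddpl"` object (without the original `call`).
#' @export
write_tddpl <- function(model, dir) {
  stopifnot(inherits(model, "tddpl"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- c("Omega", "D", "P", "W", "A", "Lambda", "Theta")
  index <- list(); vals <- list()
  for (g in groups) {
    for (k in seq_along(model[[g]])) {
      M <- model[[g]][[k]]
      index[[length(index) + 1L]] <-
        list(group = g, k = k, nrow = nrow(M), ncol = ncol(M))
      vals[[length(vals) + 1L]] <- as.double(M)
    }
  }
  manifest <- list(format = "tddpl-model", version = 1L,
                   d = model$d, K = model$K, n_sources = model$n_sources,
                   feature_order = "channel-major, band-minor",
                   hp = model$hp, report = model$report, matrices = index)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  con <- file(file.path(dir, "matrices.bin"), "wb")
  on.exit(close(con))
  writeBin(unlist(vals), con, size = 8)
  invisible(dir)
}

#' @rdname write_tddpl
#' @export
read_tddpl <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyDataFrame = FALSE)
  if (!identical(manifest$format, "tddpl-model"))
    stop("not a tddpl model directory: ", dir)
  n_tot <- sum(vapply(manifest$matrices, function(e) e$nrow * e$ncol,
                      numeric(1)))
  con <- file(file.path(dir, "matrices.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n_tot, size = 8)
  model <- list(Omega = list(), D = list(), P = list(), W = list(),
                A = list(), Lambda = list(), Theta = list())
  pos <- 0
  for (e in manifest$matrices) {
    len <- e$nrow * e$ncol
    model[[e$group]][[e$k]] <- matrix(vals[(pos + 1):(pos + len)],
                                      e$nrow, e$ncol)
    pos <- pos + len
  }
  hp <- manifest$hp
  hp$m <- as.integer(hp$m); hp$r <- as.integer(hp$r)
  hp$max_iter <- as.integer(hp$max_iter); hp$seed <- as.integer(hp$seed)
  model$hp <- hp
  model$d <- as.integer(manifest$d)
  model$K <- as.integer(manifest$K)
  model$n_sources <- as.integer(manifest$n_sources)
  model$report <- manifest$report
  model$report$objective <- as.numeric(unlist(model$report$objective))
  class(model) <- "tddpl"
  model
}
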