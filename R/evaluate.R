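#' Enumerate cross-subject transfer tasks
#'
#' `"o_to_o"` (one source to one target) yields every ordered pair of
#' subjects, `z * (z - 1)` tasks; `"m_to_o"` (all remaining subjects to one
#' target) yields `z` tasks.
#'
#' @param subject_ids character or integer vector of at least two subjects.
#' @param mode `"o_to_o"` or `"m_to_o"`.
#' @return list of tasks, each a list with `sources` (vector) and `target`.
#' @examples
#' length(enumerate_tasks(1:3, "o_to_o"))  # 6
#' length(enumerate_tasks(1:3, "m_to_o"))  # 3
#' @export
enumerate_tasks <- function(subject_ids, mode = c("o_to_o", "m_to_o")) {
  mode <- match.arg(mode)
  if (length(subject_ids) < 2) stop("need at least two subjects")
  if (mode == "o_to_o") {
    out <- list()
    for (tg in subject_ids) for (sc in subject_ids)
      if (!identical(sc, tg))
        out[[length(out) + 1L]] <- list(sources = sc, target = tg)
    out
  } else {
    lapply(subject_ids, function(tg)
      list(sources = subject_ids[subject_ids != tg], target = tg))
  }
}

#' Classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return fraction of equal entries, in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0 || length(predicted) != length(truth))
    stop("predicted and truth must be nonempty and of equal length")
  mean(predicted == truth)
}

## deterministic stratified source fold for repeat `rep`: indices of roughly
## fraction * n samples per class; folds across repeats are disjoint until the
## permutation is exhausted, so the union of repeats covers the source set
source_fold <- function(labels, fraction, rep, perm_seed) {
  if (fraction >= 1) return(seq_along(labels))
  nfolds <- ceiling(1 / fraction)
  set.seed(perm_seed)
  idx <- integer(0)
  for (k in sort(unique(labels))) {
    cls <- which(labels == k)
    perm <- sample(cls)
    cuts <- cut(seq_along(perm), breaks = nfolds, labels = FALSE)
    fold <- ((rep - 1) %% nfolds) + 1
    idx <- c(idx, perm[cuts == fold])
  }
  sort(idx)
}

#' Run a cross-subject transfer scenario
#'
#' For every task of the scenario and every repeat: subsample each source
#' subject by `source_fraction` (stratified, disjoint-as-possible folds
#' across repeats), split the target subject into a labeled training part
#' (`target_train_fraction`, stratified by class) and a held-out test part,
#' fit the model on sources + target-train, and score accuracy on the target
#' holdout.  Every row records the seed and a config hash sufficient to
#' regenerate it.
#'
#' @param subjects named list of per-subject datasets, each a list with `X`
#'   (features x samples) and `labels`.
#' @param mode `"o_to_o"` or `"m_to_o"`; see [enumerate_tasks()].
#' @param target_train_fraction fraction of each target class used as labeled
#'   target training data; the default 0.125 mirrors reserving a short
#'   labeled segment (about 30 s of a 4-minute recording) per trial.
#' @param source_fraction fraction of each source subject used per repeat.
#' @param repeats number of source-subsampling repeats per task.
#' @param method `"tddpl"` or `"dpl"` (pooled no-transfer baseline).
#' @param seed base seed; per-(task, repeat) seeds are derived from it.
#' @param ... hyperparameters forwarded to [tddpl()] / [dpl_pooled()]
#'   (e.g. `m`, `r`, `lambda2`, `max_iter`); scenario options after `...`
#'   must be passed by full name.
#' @return `data.frame` with one row per (task, repeat): `task`, `target`,
#'   `sources`, `rep`, `seed`, `method`, `accuracy`, `n_test`, `config`.
#'   Skipped tasks (a class lost in splitting) are reported via messages.
#' @export
run_scenario <- function(subjects, ..., mode = c("m_to_o", "o_to_o"),
                         target_train_fraction = 0.125, source_fraction = 1,
                         repeats = 1, method = c("tddpl", "dpl"), seed = 0) {
  mode <- match.arg(mode); method <- match.arg(method)
  stopifnot(target_train_fraction > 0, target_train_fraction < 1,
            source_fraction > 0, source_fraction <= 1, repeats >= 1)
  ids <- names(subjects) %||% as.character(seq_along(subjects))
  names(subjects) <- ids
  tasks <- enumerate_tasks(ids, mode)
  hp_extra <- list(...)
  cfg_hash <- fnv1a(paste(mode, target_train_fraction, source_fraction,
                          repeats, method, seed,
                          paste(names(hp_extra), unlist(hp_extra),
                                collapse = ","), sep = "|"))
  rows <- list()
  for (task in tasks) {
    tgt_idx <- match(task$target, ids)
    for (rp in seq_len(repeats)) {
      ts <- derive_seed(seed, tgt_idx, rp)
      res <- tryCatch({
        tgt <- subjects[[task$target]]
        set.seed(ts)
        tr_idx <- split_stratified(tgt$labels, target_train_fraction)
        te_idx <- setdiff(seq_along(tgt$labels), tr_idx)
        sources <- lapply(task$sources, function(sid) {
          sb <- subjects[[sid]]
          keep <- source_fold(sb$labels, source_fraction, rp,
                              derive_seed(seed, 1000L + match(sid, ids)))
          list(X = sb$X[, keep, drop = FALSE], labels = sb$labels[keep])
        })
        dat <- multidomain_dataset(
          sources = sources,
          target = list(X = tgt$X[, tr_idx, drop = FALSE],
                        labels = tgt$labels[tr_idx]))
        args <- c(list(data = dat, seed = ts), hp_extra)
        fit <- if (method == "tddpl") do.call(tddpl, args)
               else do.call(dpl_pooled, args)
        pred <- predict(fit, tgt$X[, te_idx, drop = FALSE])
        list(acc = accuracy(pred, tgt$labels[te_idx]), n_test = length(te_idx))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        message("task ", task$target, " rep ", rp, " skipped: ",
                conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        task = paste0(paste(task$sources, collapse = "+"), "->", task$target),
        target = task$target,
        sources = paste(task$sources, collapse = ","),
        rep = rp, seed = ts, method = method,
        accuracy = res$acc, n_test = res$n_test, config = cfg_hash,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("every task was skipped")
  out
}

#' Accuracy surface over subspace dimension and atom count
#'
#' Cross-product sweep of the subspace dimension `m` and atoms-per-class `r`
#' grids, one [run_scenario()] call per cell.
#'
#' @param subjects as in [run_scenario()].
#' @param m_grid,r_grid numeric grids (defaults follow the conventional
#'   search ranges `20..100` and `10..30`).
#' @param ... forwarded to [run_scenario()]; grid arguments after `...` must
#'   be passed by full name.
#' @return `data.frame` with columns `m`, `r`, `mean_acc`, `sd_acc`, `n_runs`.
#' @export
sweep_params <- function(subjects, ..., m_grid = seq(20, 100, by = 10),
                         r_grid = seq(10, 30, by = 5)) {
  stopifnot(length(m_grid) >= 1, length(r_grid) >= 1)
  grid <- expand.grid(m = m_grid, r = r_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tab <- run_scenario(subjects, m = grid$m[i], r = grid$r[i], ...)
    data.frame(m = grid$m[i], r = grid$r[i],
               mean_acc = mean(tab$accuracy),
               sd_acc = if (nrow(tab) > 1) sd(tab$accuracy) else 0,
               n_runs = nrow(tab))
  })
  do.call(rbind, res)
}

#' Paired transfer-gain comparison
#'
#' Runs the TDDPL model and the pooled no-transfer baseline on the same
#' scenario across several seeds and tests, by a one-sided sign test, whether
#' the per-seed mean target accuracy of TDDPL exceeds the baseline's.
#'
#' @param subjects_fn function(seed) returning the per-subject data list (so
#'   each seed draws its own dataset).
#' @param seeds integer vector of seeds.
#' @param ... forwarded to [run_scenario()] for both methods.
#' @return list with `table` (per-seed accuracies), `wins`, `n`, `p_value`
#'   (one-sided binomial sign test, ties dropped).
#' @export
transfer_gain <- function(subjects_fn, ..., seeds = 0:9) {
  per_seed <- lapply(seeds, function(s) {
    subjects <- subjects_fn(s)
    a_t <- mean(run_scenario(subjects, method = "tddpl", seed = s,
                             ...)$accuracy)
    a_d <- mean(run_scenario(subjects, method = "dpl", seed = s,
                             ...)$accuracy)
    data.frame(seed = s, tddpl = a_t, dpl = a_d)
  })
  tab <- do.call(rbind, per_seed)
  diffs <- tab$tddpl - tab$dpl
  n <- sum(diffs != 0); wins <- sum(diffs > 0)
  p <- if (n == 0) 1 else
    binom.test(wins, n, p = 0.5, alternative = "greater")$p.value
  list(table = tab, wins = wins, n = n, p_value = p)
}
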