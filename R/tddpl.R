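#' Fit a transfer discriminative dictionary pair learning model
#'
#' Learns, for each class `k`, a subspace transform `Omega_k` (`m x d`), a
#' synthesis sub-dictionary `D_k` (`m x r`, unit-bounded columns), an analysis
#' sub-dictionary `P_k` (`r x m`) and a classifier block `W_k` (`K x r`) by
#' alternating minimization of the relaxed objective
#'
#' \deqn{\sum_k \|B_k - D_k A_k\|_F^2 + \|D_k \hat A_k\|_F^2
#'   + \lambda_1(\|C_k - A_k\|_F^2 + \|\hat C_k\|_F^2)
#'   + \lambda_2\,\mathrm{tr}(A_k Q_k A_k^T)
#'   + \lambda_3\|A_k - \Lambda_k \Theta_k\|_F^2
#'   + \lambda_4\|H_k - W_k C_k\|_F^2
#'   + \lambda_5(\|B_k - \Omega_k Y_k\|_F^2 + \|C_k - P_k B_k\|_F^2)
#'   + \gamma\|W\|_F^2}
#'
#' where `Y_k` pools the class-`k` columns of every domain, `Q_k` is the
#' class-wise MMD quadratic form aligning source and target code means,
#' `Lambda_k Theta_k` is a rank-`K` factorization of the codes, `H_k` the
#' one-hot labels, and `B_k`, `C_k` relaxation auxiliaries for
#' `Omega_k Y_k` and `P_k B_k`.  Every update is the exact minimizer of its
#' subproblem (the coding step solves a Sylvester-type system; the `C` step
#' is a safeguarded gradient step).  Iteration stops when the relative
#' objective change drops below `tol` or after `max_iter` sweeps.
#'
#' Prediction (see [predict.tddpl()]) uses only `W`, `P` and `Omega`:
#' `label(x) = argmax_i (sum_k W_k P_k Omega_k x)_i` — no coding at test time.
#'
#' @param data a [multidomain_dataset()]: `n` source blocks plus one target
#'   block; every class must be present in every block, and the target block
#'   must contain labeled samples of every class.
#' @param m subspace dimension (`<= d`).
#' @param r atoms per class sub-dictionary.
#' @param lambda1,lambda2,lambda3,lambda4,lambda5 nonnegative weights of the
#'   analysis-consistency, MMD, low-rank, classifier and relaxation terms.
#' @param gamma ridge weight on the classifier.
#' @param theta small ridge added to matrix inversions.
#' @param alpha initial step size of the backtracked `C` update.
#' @param max_iter,tol outer iteration budget and relative-change tolerance.
#' @param seed RNG seed; the fit is a deterministic function of
#'   `(data, hyperparameters, seed)`.
#' @param update_omega set `FALSE` to keep the initial projections fixed
#'   (with `omega_init = "identity"` and `m = d` this reduces the model to a
#'   plain dictionary-pair system).
#' @param omega_init `"random"` (seeded orthonormal rows) or `"identity"`
#'   (requires `m = d`).
#' @param verbose print the objective each sweep.
#' @return an object of class `"tddpl"`: lists `Omega`, `D`, `P`, `W` (and
#'   the final `A`, `Lambda`, `Theta` codes for inspection), the
#'   hyperparameters `hp`, and a `report` with the per-sweep objective trace
#'   and stop reason.
#' @examples
#' dat <- generate_domains(synth_spec(seed = 1))
#' fit <- tddpl(dat, m = 10, r = 6, max_iter = 10)
#' fit
#' mean(predict(fit, dat$blocks$target$X) == dat$blocks$target$labels)
#' @seealso [dpl_pooled()] for the no-transfer baseline, [run_scenario()]
#' @export
tddpl <- function(data, m = 50, r = 20, lambda1 = 1, lambda2 = 1,
                  lambda3 = 1, lambda4 = 1, lambda5 = 1, gamma = 1,
                  theta = 1e-4, alpha = 1e-2, max_iter = 50, tol = 1e-4,
                  seed = 0, update_omega = TRUE,
                  omega_init = c("random", "identity"), verbose = FALSE) {
  cl <- match.call()
  hp <- tddpl_hyperparams(lambda1, lambda2, lambda3, lambda4, lambda5,
                          gamma, theta, alpha, m, r, max_iter, tol, seed,
                          update_omega, omega_init)
  ini <- init_state(data, hp)
  model <- ini$model; state <- ini$state
  trace <- numeric(0)
  stop_reason <- "max_iter"
  f_prev <- Inf
  for (it in seq_len(hp$max_iter)) {
    state <- update_coding(model, state, hp)
    model <- update_analysis(model, state, hp)
    ## complement codes follow the new analysis dictionary before the
    ## synthesis step consumes them
    state <- refresh_complements(model, state)
    model <- update_classifier(model, state, hp)
    model <- update_synthesis(model, state, hp)
    state <- update_lowrank(state)
    if (hp$update_omega) model <- update_projection(model, state, hp)
    state <- refresh_complements(model, state)
    state <- update_auxiliary_C(model, state, hp)
    state <- update_auxiliary_B(model, state, hp)
    terms <- tddpl_objective(model, state, hp, by_term = TRUE)
    f <- sum(terms)
    if (!is.finite(f)) {
      bad <- names(terms)[!is.finite(terms)]
      stop("non-finite objective at iteration ", it, " (term: ",
           paste(bad, collapse = ", "), ")")
    }
    trace <- c(trace, f)
    if (verbose) message(sprintf("iter %3d  objective %.6g", it, f))
    if (is.finite(f_prev) &&
        abs(f_prev - f) < hp$tol * max(1, abs(f_prev))) {
      stop_reason <- "tol"
      break
    }
    f_prev <- f
  }
  structure(list(Omega = model$Omega, D = model$D, P = model$P, W = model$W,
                 A = state$A, Lambda = state$Lambda, Theta = state$Theta,
                 hp = hp, d = data$d, K = data$K, n_sources = data$n_sources,
                 report = list(objective = trace, iterations = length(trace),
                               stop_reason = stop_reason),
                 call = cl),
            class = "tddpl")
}

#' Pooled no-transfer dictionary-pair baseline
#'
#' Classic projective dictionary pair learning fitted on all domains merged
#' into one training set, ignoring domain identity: per class, a synthesis
#' dictionary `D_k` (`d x r`, unit-bounded columns) and analysis dictionary
#' `P_k` (`r x d`) minimizing
#' `||X_k - D_k A_k||^2 + tau ||P_k X_k - A_k||^2 + mu ||P_k Xbar_k||^2`
#' by alternating closed forms, classifying by the class-wise reconstruction
#' residual `argmin_k ||x - D_k P_k x||`.  This is the "mix source and
#' target and ignore the shift" baseline that transfer learning is measured
#' against.
#'
#' @param data a [multidomain_dataset()]; all blocks are pooled.
#' @param r atoms per class.
#' @param tau weight of the code-consistency term.
#' @param mu weight of the complement-suppression term.
#' @param theta ridge added to inversions.
#' @param max_iter,tol iteration budget and relative objective tolerance.
#' @param seed RNG seed for the dictionary initialization.
#' @param ... absorbed and ignored (allows sharing hyperparameter lists with
#'   [tddpl()], e.g. in [run_scenario()]).
#' @return an object of class `"dpl"` with per-class `D`, `P` and a `report`.
#' @export
dpl_pooled <- function(data, r = 20, tau = 1, mu = 1, theta = 1e-4,
                       max_iter = 50, tol = 1e-4, seed = 0, ...) {
  pooled <- pool_domains(data)
  X <- pooled$blocks$target$X
  labels <- pooled$blocks$target$labels
  K <- pooled$K; d <- pooled$d
  set.seed(seed)
  D <- P <- A <- vector("list", K)
  obj <- function() {
    tot <- 0
    for (k in seq_len(K)) {
      Xk <- X[, labels == k, drop = FALSE]
      Xb <- X[, labels != k, drop = FALSE]
      tot <- tot + sum((Xk - D[[k]] %*% A[[k]])^2) +
        tau * sum((P[[k]] %*% Xk - A[[k]])^2) + mu * sum((P[[k]] %*% Xb)^2)
    }
    tot
  }
  for (k in seq_len(K)) {
    M <- matrix(rnorm(d * r), d, r)
    D[[k]] <- sweep(M, 2, pmax(sqrt(colSums(M^2)), 1e-12), "/")
    P[[k]] <- matrix(rnorm(r * d, sd = 0.01), r, d)
    A[[k]] <- P[[k]] %*% X[, labels == k, drop = FALSE]
  }
  trace <- numeric(0); f_prev <- Inf; stop_reason <- "max_iter"
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      Xk <- X[, labels == k, drop = FALSE]
      Xb <- X[, labels != k, drop = FALSE]
      A[[k]] <- solve_sym(crossprod(D[[k]]) + diag(tau, r),
                          crossprod(D[[k]], Xk) + tau * P[[k]] %*% Xk)
      P[[k]] <- tau * A[[k]] %*% t(Xk) %*%
        solve_sym(tau * tcrossprod(Xk) + mu * tcrossprod(Xb) +
                    diag(theta, d), diag(d))
      Dk <- project_columns(Xk %*% t(A[[k]]) %*%
        solve_sym(tcrossprod(A[[k]]) + diag(theta, r), diag(r)))
      ## feasible line search: the ball projection alone may not descend
      f_old <- sum((Xk - D[[k]] %*% A[[k]])^2)
      t_step <- 1
      for (tries in 1:30) {
        Dc <- (1 - t_step) * D[[k]] + t_step * Dk
        if (sum((Xk - Dc %*% A[[k]])^2) <= f_old) { D[[k]] <- Dc; break }
        t_step <- t_step / 2
      }
    }
    f <- obj()
    trace <- c(trace, f)
    if (is.finite(f_prev) && abs(f_prev - f) < tol * max(1, abs(f_prev))) {
      stop_reason <- "tol"; break
    }
    f_prev <- f
  }
  structure(list(D = D, P = P, d = d, K = K,
                 hyper = list(r = r, tau = tau, mu = mu, theta = theta,
                              max_iter = max_iter, tol = tol, seed = seed),
                 report = list(objective = trace, iterations = length(trace),
                               stop_reason = stop_reason)),
            class = "dpl")
}

#' @export
predict.dpl <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, ncol = 1) else
    as.matrix(newdata)
  if (nrow(X) != object$d)
    stop("newdata has ", nrow(X), " rows; model expects d = ", object$d)
  resid <- sapply(seq_len(object$K), function(k)
    colSums((X - object$D[[k]] %*% (object$P[[k]] %*% X))^2))
  resid <- matrix(resid, ncol = object$K)
  max.col(-resid, ties.method = "first")
}

#' @export
print.dpl <- function(x, ...) {
  cat("Pooled dictionary pair learning baseline (no transfer)\n")
  cat("  classes:", x$K, " feature dim:", x$d, " atoms/class:", x$hyper$r,
      "\n")
  cat("  ", x$report$iterations, " iterations (", x$report$stop_reason,
      ")\n", sep = "")
  invisible(x)
}
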