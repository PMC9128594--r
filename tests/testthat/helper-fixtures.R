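# Small in-code fixtures shared across tests.

# tiny two-source + target dataset with well-separated classes
tiny_dataset <- function(seed = 0, K = 3, d = 12, n = 8, sep = 3) {
  set.seed(seed)
  mu <- matrix(rnorm(d * K), d, K) * sep / sqrt(d)
  block <- function(shift = 0) {
    labels <- rep(seq_len(K), each = n)
    list(X = mu[, labels] + shift + matrix(rnorm(d * K * n, sd = 0.3), d),
         labels = labels)
  }
  multidomain_dataset(sources = list(block(), block(0.2)),
                      target = block(-0.2))
}

# a random consistent (model, state) pair for update-level tests;
# n_bar = 0 gives a state without complement columns
random_instance <- function(seed, m = 4, r = 3, K = 3, n_k = 10, n_bar = 8,
                            d = 6, lambda2 = 1, ...) {
  set.seed(seed)
  hp <- tddpl:::tddpl_hyperparams(m = m, r = r, lambda2 = lambda2, ...)
  model <- list(Omega = list(), D = list(), P = list(), W = list())
  state <- list(Yk = list(), Ybar = list(), A = list(), Ahat = list(),
                Lambda = list(), Theta = list(), B = list(), C = list(),
                Chat = list(), Q = list(), H = list())
  for (k in seq_len(K)) {
    model$Omega[[k]] <- matrix(rnorm(m * d), m, d)
    D <- matrix(rnorm(m * r), m, r)
    model$D[[k]] <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1), "/")
    model$P[[k]] <- matrix(rnorm(r * m), r, m)
    model$W[[k]] <- matrix(rnorm(K * r), K, r)
    state$Yk[[k]] <- matrix(rnorm(d * n_k), d, n_k)
    state$Ybar[[k]] <- matrix(rnorm(d * max(n_bar, 0)), d, max(n_bar, 0))
    state$A[[k]] <- matrix(rnorm(r * n_k), r, n_k)
    state$Ahat[[k]] <- model$P[[k]] %*% model$Omega[[k]] %*% state$Ybar[[k]]
    state$Lambda[[k]] <- matrix(rnorm(r * K), r, K)
    state$Theta[[k]] <- matrix(rnorm(K * n_k), K, n_k)
    state$B[[k]] <- matrix(rnorm(m * n_k), m, n_k)
    state$C[[k]] <- matrix(rnorm(r * n_k), r, n_k)
    state$Chat[[k]] <- model$P[[k]] %*% model$Omega[[k]] %*% state$Ybar[[k]]
    ns <- max(1, floor(n_k / 2))
    state$Q[[k]] <- if (lambda2 > 0) mmd_matrix(ns, n_k - ns) else NULL
    H <- matrix(0, K, n_k); H[k, ] <- 1
    state$H[[k]] <- H
  }
  list(model = model, state = state, hp = hp)
}

# central finite-difference gradient of f at matrix M
fd_gradient <- function(f, M, eps = 1e-6) {
  G <- matrix(0, nrow(M), ncol(M))
  for (i in seq_along(M)) {
    Mp <- M; Mm <- M
    Mp[i] <- Mp[i] + eps; Mm[i] <- Mm[i] - eps
    G[i] <- (f(Mp) - f(Mm)) / (2 * eps)
  }
  G
}

# straightforward term-by-term evaluator of the training objective,
# independent of tddpl:::tddpl_objective
naive_objective <- function(model, state, hp) {
  total <- 0
  for (k in seq_along(model$D)) {
    D <- model$D[[k]]; P <- model$P[[k]]; Om <- model$Omega[[k]]
    A <- state$A[[k]]; B <- state$B[[k]]; C <- state$C[[k]]
    Chat <- P %*% Om %*% state$Ybar[[k]]
    total <- total + sum((B - D %*% A)^2) + sum((D %*% Chat)^2) +
      hp$lambda1 * (sum((C - A)^2) + sum(Chat^2)) +
      hp$lambda3 * sum((A - state$Lambda[[k]] %*% state$Theta[[k]])^2) +
      hp$lambda4 * sum((state$H[[k]] - model$W[[k]] %*% C)^2) +
      hp$lambda5 * (sum((B - Om %*% state$Yk[[k]])^2) +
                      sum((C - P %*% B)^2)) +
      hp$gamma * sum(model$W[[k]]^2)
    if (hp$lambda2 > 0 && !is.null(state$Q[[k]])) {
      ns <- state$Q[[k]]$n_source
      ms <- rowMeans(A[, seq_len(ns), drop = FALSE])
      mt <- rowMeans(A[, -seq_len(ns), drop = FALSE])
      total <- total + hp$lambda2 * sum((ms - mt)^2)
    }
  }
  total
}
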