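# Each alternating update is checked against its defining subproblem:
# closed-form limits, independent oracles, and finite-difference
# stationarity at the returned point.

coding_subobj <- function(A, D, B, C, LT, Q, hp) {
  v <- sum((B - D %*% A)^2) + hp$lambda1 * sum((C - A)^2) +
    hp$lambda3 * sum((A - LT)^2)
  if (hp$lambda2 > 0 && !is.null(Q)) v <- v + hp$lambda2 * mmd_value(A, Q)
  v
}

test_that("coding update solves its stationarity condition", {
  # identity dictionary, no couplings -> A = B
  inst <- random_instance(1, m = 3, r = 3, lambda1 = 0, lambda2 = 0,
                          lambda3 = 0)
  inst$model$D <- lapply(inst$model$D, function(D) diag(3))
  st <- tddpl:::update_coding(inst$model, inst$state, inst$hp)
  expect_equal(st$A[[1]], inst$state$B[[1]], tolerance = 1e-8)

  # dominant lambda1 with a zero dictionary -> A -> C
  inst <- random_instance(2, lambda1 = 1e8, lambda2 = 0, lambda3 = 0)
  inst$model$D <- lapply(inst$model$D, function(D) D * 0)
  st <- tddpl:::update_coding(inst$model, inst$state, inst$hp)
  expect_equal(st$A[[2]], inst$state$C[[2]], tolerance = 1e-6)

  # finite-difference stationarity on random instances incl. the MMD term
  for (s in 1:5) {
    inst <- random_instance(10 + s, m = 4, r = 3, n_k = 8)
    st <- tddpl:::update_coding(inst$model, inst$state, inst$hp)
    for (k in 1:3) {
      f <- function(A) coding_subobj(A, inst$model$D[[k]],
                                     inst$state$B[[k]], inst$state$C[[k]],
                                     inst$state$Lambda[[k]] %*%
                                       inst$state$Theta[[k]],
                                     inst$state$Q[[k]], inst$hp)
      g <- fd_gradient(f, st$A[[k]])
      expect_lt(max(abs(g)), 1e-6)
    }
  }
})

test_that("analysis update matches its ridge oracle without complements", {
  # C = B square invertible, theta = 0 -> P = I
  inst <- random_instance(3, m = 4, r = 4, n_bar = 0)
  inst$state$C <- inst$state$B
  md <- tddpl:::update_analysis(inst$model, inst$state, inst$hp, theta = 0)
  expect_equal(md$P[[1]], diag(4), tolerance = 1e-8)

  # B = I, C = I, theta = 1 -> P = I/2
  inst <- random_instance(4, m = 4, r = 4, n_k = 4, n_bar = 0)
  inst$state$B <- lapply(inst$state$B, function(B) diag(4))
  inst$state$C <- lapply(inst$state$C, function(C) diag(4))
  md <- tddpl:::update_analysis(inst$model, inst$state, inst$hp, theta = 1)
  expect_equal(md$P[[2]], diag(4) / 2, tolerance = 1e-10)

  # ridge-regression oracle
  for (s in 1:5) {
    inst <- random_instance(20 + s, n_bar = 0)
    md <- tddpl:::update_analysis(inst$model, inst$state, inst$hp)
    for (k in 1:3) {
      B <- inst$state$B[[k]]; C <- inst$state$C[[k]]
      oracle <- C %*% t(B) %*%
        solve(tcrossprod(B) + diag(inst$hp$theta, nrow(B)))
      expect_lt(max(abs(md$P[[k]] - oracle)), 1e-10)
    }
  }
})

test_that("discriminative analysis update is stationary for its full
           subobjective", {
  for (s in 1:5) {
    inst <- random_instance(30 + s)
    md <- tddpl:::update_analysis(inst$model, inst$state, inst$hp)
    hp <- inst$hp
    for (k in 1:3) {
      Bbar <- inst$model$Omega[[k]] %*% inst$state$Ybar[[k]]
      f <- function(P) sum((inst$model$D[[k]] %*% P %*% Bbar)^2) +
        hp$lambda1 * sum((P %*% Bbar)^2) +
        hp$lambda5 * sum((inst$state$C[[k]] - P %*% inst$state$B[[k]])^2) +
        hp$theta * sum(P^2)
      g <- fd_gradient(f, md$P[[k]])
      expect_lt(max(abs(g)) / max(1, abs(f(md$P[[k]]))), 1e-6)
    }
  }
})

test_that("classifier update is the printed ridge solution", {
  inst <- random_instance(5, m = 4, r = 3, n_k = 3, lambda4 = 1, gamma = 0)
  inst$state$C <- lapply(inst$state$C, function(C) diag(3))
  md <- tddpl:::update_classifier(inst$model, inst$state, inst$hp)
  expect_equal(md$W[[1]], inst$state$H[[1]], tolerance = 1e-8)

  inst <- random_instance(6, m = 4, r = 3, n_k = 3, lambda4 = 1, gamma = 1)
  inst$state$C <- lapply(inst$state$C, function(C) diag(3))
  md <- tddpl:::update_classifier(inst$model, inst$state, inst$hp)
  expect_equal(md$W[[2]], inst$state$H[[2]] / 2, tolerance = 1e-10)

  for (s in 1:5) {
    inst <- random_instance(40 + s)
    md <- tddpl:::update_classifier(inst$model, inst$state, inst$hp)
    hp <- inst$hp
    for (k in 1:3) {
      C <- inst$state$C[[k]]; H <- inst$state$H[[k]]
      oracle <- t(solve(hp$lambda4 * tcrossprod(C) + diag(hp$gamma, nrow(C)),
                        hp$lambda4 * C %*% t(H)))
      expect_lt(max(abs(md$W[[k]] - oracle)), 1e-10)
    }
  }
})

test_that("synthesis update respects the unit ball and matches a
           projected-gradient oracle", {
  # empty complement, A = I, theta = 0, feasible B -> D = B
  inst <- random_instance(7, m = 4, r = 4, n_k = 4, n_bar = 0)
  inst$state$A <- lapply(inst$state$A, function(A) diag(4))
  inst$state$B <- lapply(inst$state$B, function(B)
    sweep(B, 2, 2 * pmax(sqrt(colSums(B^2)), 1), "/"))
  inst$state$Ahat <- lapply(inst$state$Ahat, function(A) A[, 0, drop = FALSE])
  md <- tddpl:::update_synthesis(inst$model, inst$state, inst$hp, theta = 0)
  expect_equal(md$D[[1]], inst$state$B[[1]], tolerance = 1e-8)

  for (s in 1:5) {
    inst <- random_instance(50 + s, m = 2, r = 2, n_k = 4, n_bar = 3)
    md <- tddpl:::update_synthesis(inst$model, inst$state, inst$hp)
    for (k in 1:3) {
      expect_lte(max(sqrt(colSums(md$D[[k]]^2))), 1 + 1e-9)
      # projected-gradient oracle on ||B - D A||^2 + ||D Ahat||^2
      A <- inst$state$A[[k]]; Ah <- inst$state$Ahat[[k]]
      B <- inst$state$B[[k]]
      obj <- function(D) sum((B - D %*% A)^2) + sum((D %*% Ah)^2)
      D <- md$D[[k]]
      L <- 2 * norm(tcrossprod(A) + tcrossprod(Ah), "2")
      for (i in 1:2000) {
        G <- 2 * (D %*% A - B) %*% t(A) + 2 * (D %*% Ah) %*% t(Ah)
        D <- tddpl:::project_columns(D - G / L)
      }
      expect_lt(obj(md$D[[k]]) - obj(D), 1e-6 * max(1, obj(D)))
    }
  }
})

test_that("low-rank factors perform alternating least squares", {
  inst <- random_instance(8, m = 4, r = 3, n_k = 3)  # Theta is 3x3
  inst$state$Theta <- lapply(inst$state$Theta, function(Th) diag(3))
  st <- tddpl:::update_lowrank(inst$state)
  expect_equal(st$Lambda[[1]], inst$state$A[[1]], tolerance = 1e-10)

  # exact rank-1 codes are recovered to numerical zero
  inst <- random_instance(9, m = 4, r = 3, n_k = 10)
  inst$state$A <- lapply(inst$state$A, function(A)
    tcrossprod(rnorm(nrow(A)), rnorm(ncol(A))))
  st <- inst$state
  for (i in 1:10) st <- tddpl:::update_lowrank(st)
  for (k in 1:3) {
    expect_lt(sqrt(sum((st$A[[k]] - st$Lambda[[k]] %*% st$Theta[[k]])^2)),
              1e-8)
    expect_lte(qr(st$Lambda[[k]] %*% st$Theta[[k]])$rank, 3)
  }

  # the paired step never increases the factorization residual
  for (s in 1:10) {
    inst <- random_instance(60 + s)
    st <- tddpl:::update_lowrank(inst$state)
    for (k in 1:3) {
      before <- sum((inst$state$A[[k]] -
                       inst$state$Lambda[[k]] %*% inst$state$Theta[[k]])^2)
      after <- sum((st$A[[k]] - st$Lambda[[k]] %*% st$Theta[[k]])^2)
      expect_lte(after, before + 1e-10)
    }
  }
})

test_that("projection update matches its ridge oracle without complements", {
  # B = Y, m = d, theta = 0 -> Omega = I
  inst <- random_instance(11, m = 5, r = 3, d = 5, n_k = 12, n_bar = 0)
  inst$state$B <- inst$state$Yk
  md <- tddpl:::update_projection(inst$model, inst$state, inst$hp, theta = 0)
  expect_equal(md$Omega[[1]], diag(5), tolerance = 1e-8)

  # overwhelming ridge -> Omega -> 0
  md <- tddpl:::update_projection(inst$model, inst$state, inst$hp,
                                  theta = 1e12)
  expect_lt(max(abs(md$Omega[[2]])), 1e-8)

  for (s in 1:5) {
    inst <- random_instance(70 + s, n_bar = 0)
    md <- tddpl:::update_projection(inst$model, inst$state, inst$hp)
    for (k in 1:3) {
      Y <- inst$state$Yk[[k]]; B <- inst$state$B[[k]]
      oracle <- B %*% t(Y) %*%
        solve(tcrossprod(Y) + diag(inst$hp$theta, nrow(Y)))
      expect_lt(max(abs(md$Omega[[k]] - oracle)), 1e-10)
    }
  }
})

test_that("projection update is stationary for its full subobjective", {
  for (s in 1:3) {
    inst <- random_instance(80 + s)
    md <- tddpl:::update_projection(inst$model, inst$state, inst$hp)
    hp <- inst$hp
    for (k in 1:3) {
      P <- inst$model$P[[k]]; D <- inst$model$D[[k]]
      f <- function(Om) hp$lambda5 *
        sum((inst$state$B[[k]] - Om %*% inst$state$Yk[[k]])^2) +
        sum((D %*% P %*% Om %*% inst$state$Ybar[[k]])^2) +
        hp$lambda1 * sum((P %*% Om %*% inst$state$Ybar[[k]])^2) +
        hp$theta * sum(Om^2)
      g <- fd_gradient(f, md$Omega[[k]])
      expect_lt(max(abs(g)) / max(1, abs(f(md$Omega[[k]]))), 1e-6)
    }
  }
})

test_that("C update: analytic gradient, stationarity, and backtracking
           contract", {
  # at the subproblem minimizer the step is a no-op
  inst <- random_instance(12)
  hp <- inst$hp
  for (k in 1:3) {
    W <- inst$model$W[[k]]
    PB <- inst$model$P[[k]] %*% inst$state$B[[k]]
    rhs <- hp$lambda1 * inst$state$A[[k]] +
      hp$lambda4 * crossprod(W, inst$state$H[[k]]) + hp$lambda5 * PB
    inst$state$C[[k]] <- solve((hp$lambda1 + hp$lambda5) * diag(nrow(PB)) +
                                 hp$lambda4 * crossprod(W), rhs)
  }
  st <- tddpl:::update_auxiliary_C(inst$model, inst$state, hp)
  for (k in 1:3)
    expect_lt(max(abs(st$C[[k]] - inst$state$C[[k]])), 1e-8)

  # analytic vs finite-difference gradient
  for (s in 1:5) {
    inst <- random_instance(90 + s)
    hp <- inst$hp
    for (k in 1:3) {
      PB <- inst$model$P[[k]] %*% inst$state$B[[k]]
      PBbar <- inst$model$P[[k]] %*% inst$model$Omega[[k]] %*%
        inst$state$Ybar[[k]]
      g <- tddpl:::c_gradients(inst$state$C[[k]], inst$state$Chat[[k]],
                               inst$state$A[[k]], inst$state$H[[k]],
                               inst$model$W[[k]], PB, PBbar, hp)
      fC <- function(C) tddpl:::c_subobjective(C, inst$state$Chat[[k]],
                                               inst$state$A[[k]],
                                               inst$state$H[[k]],
                                               inst$model$W[[k]], PB, PBbar,
                                               hp)
      gf <- fd_gradient(fC, inst$state$C[[k]])
      expect_lt(max(abs(g$C - gf)) / max(1, max(abs(gf))), 1e-6)
    }
  }

  # accepted steps never increase the C-subobjective
  for (s in 1:20) {
    inst <- random_instance(120 + s, alpha = 0.5)
    hp <- inst$hp
    before <- vapply(1:3, function(k)
      tddpl:::c_subobjective(inst$state$C[[k]], inst$state$Chat[[k]],
                             inst$state$A[[k]], inst$state$H[[k]],
                             inst$model$W[[k]],
                             inst$model$P[[k]] %*% inst$state$B[[k]],
                             inst$model$P[[k]] %*% inst$model$Omega[[k]] %*%
                               inst$state$Ybar[[k]], hp), numeric(1))
    st <- tddpl:::update_auxiliary_C(inst$model, inst$state, hp)
    after <- vapply(1:3, function(k)
      tddpl:::c_subobjective(st$C[[k]], st$Chat[[k]], st$A[[k]], st$H[[k]],
                             inst$model$W[[k]],
                             inst$model$P[[k]] %*% st$B[[k]],
                             inst$model$P[[k]] %*% inst$model$Omega[[k]] %*%
                               st$Ybar[[k]], hp), numeric(1))
    expect_true(all(after <= before + 1e-10))
  }
})

test_that("B update is the printed closed form", {
  # P = I and D A = Omega Y = C = Z -> B = Z (square invertible Y so that
  # Omega Y = Z exactly)
  inst2 <- random_instance(14, m = 3, r = 3, n_k = 3, d = 3)
  for (k in 1:3) {
    inst2$model$P[[k]] <- diag(3)
    Z <- matrix(rnorm(9), 3, 3)
    inst2$model$D[[k]] <- diag(3)
    inst2$state$A[[k]] <- Z
    inst2$state$C[[k]] <- Z
    inst2$model$Omega[[k]] <- Z %*% solve(inst2$state$Yk[[k]])
  }
  st <- tddpl:::update_auxiliary_B(inst2$model, inst2$state, inst2$hp)
  expect_equal(st$B[[1]], inst2$state$A[[1]], tolerance = 1e-8)

  # lambda5 = 0 -> B = D A
  inst <- random_instance(15, lambda5 = 0)
  st <- tddpl:::update_auxiliary_B(inst$model, inst$state, inst$hp)
  expect_equal(st$B[[2]], inst$model$D[[2]] %*% inst$state$A[[2]],
               tolerance = 1e-10)

  # finite-difference stationarity of the B-subobjective
  for (s in 1:5) {
    inst <- random_instance(140 + s)
    st <- tddpl:::update_auxiliary_B(inst$model, inst$state, inst$hp)
    hp <- inst$hp
    for (k in 1:3) {
      f <- function(B) sum((B - inst$model$D[[k]] %*% inst$state$A[[k]])^2) +
        hp$lambda5 * (sum((B - inst$model$Omega[[k]] %*%
                             inst$state$Yk[[k]])^2) +
                        sum((inst$state$C[[k]] -
                               inst$model$P[[k]] %*% B)^2))
      g <- fd_gradient(f, st$B[[k]])
      expect_lt(max(abs(g)), 1e-6)
    }
  }
})

test_that("objective matches an independent evaluator and scales
           quadratically", {
  # hand-made zero state
  inst <- random_instance(16, m = 3, r = 3, n_bar = 0, lambda1 = 0,
                          lambda2 = 0, lambda3 = 0, lambda4 = 0,
                          lambda5 = 0, gamma = 0)
  for (k in 1:3) {
    inst$state$B[[k]] <- inst$model$D[[k]] %*% inst$state$A[[k]]
    inst$state$Ahat[[k]] <- inst$state$Ahat[[k]][, 0, drop = FALSE]
  }
  expect_equal(sum(tddpl:::tddpl_objective(inst$model, inst$state, inst$hp)),
               0)

  # quadratic homogeneity of the low-rank term
  inst <- random_instance(17, lambda1 = 0, lambda2 = 0, lambda3 = 1,
                          lambda4 = 0, lambda5 = 0, gamma = 0, n_bar = 0)
  for (k in 1:3) {
    inst$model$D[[k]] <- inst$model$D[[k]] * 0
    inst$state$Lambda[[k]] <- inst$state$Lambda[[k]] * 0
    inst$state$Theta[[k]] <- inst$state$Theta[[k]] * 0
    inst$state$B[[k]] <- inst$state$B[[k]] * 0
  }
  f1 <- sum(tddpl:::tddpl_objective(inst$model, inst$state, inst$hp))
  inst$state$A <- lapply(inst$state$A, function(A) 2 * A)
  f2 <- sum(tddpl:::tddpl_objective(inst$model, inst$state, inst$hp))
  expect_equal(f2, 4 * f1, tolerance = 1e-12)

  # independent straightforward evaluator
  for (s in 1:10) {
    inst <- random_instance(160 + s)
    expect_lt(abs(sum(tddpl:::tddpl_objective(inst$model, inst$state,
                                              inst$hp)) -
                    naive_objective(inst$model, inst$state, inst$hp)),
              1e-10 * max(1, naive_objective(inst$model, inst$state,
                                             inst$hp)))
  }
})
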