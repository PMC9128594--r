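## Internal solver machinery for the TDDPL alternating scheme.
##
## Conventions, per class k (K classes):
##   Yk      d  x Nk    class-k columns pooled over all domains, sources first
##   Ybar    d  x Nbk   all non-class-k columns
##   Omega   m  x d     subspace transform (applied as Omega %*% x)
##   D       m  x r     synthesis sub-dictionary, column norms <= 1
##   P       r  x m     analysis sub-dictionary
##   W       K  x r     classifier block
##   A       r  x Nk    codes of class-k columns on sub-dictionary k
##   Ahat    r  x Nbk   codes of non-class-k columns on channel k, recomputed
##                      each sweep as P %*% Omega %*% Ybar
##   Lambda  r  x K, Theta K x Nk   low-rank factors, A ~ Lambda Theta
##   B       m  x Nk    auxiliary for Omega Yk;  C  r x Nk  auxiliary for P B
##   Chat    r  x Nbk   auxiliary complement codes (target zero)
##   Q       Nk x Nk    class-wise MMD quadratic form (NULL when lambda2 = 0)
##   H       K  x Nk    one-hot labels, the 1 in row k

tddpl_hyperparams <- function(lambda1 = 1, lambda2 = 1, lambda3 = 1,
                              lambda4 = 1, lambda5 = 1, gamma = 1,
                              theta = 1e-4, alpha = 1e-2, m = 50, r = 20,
                              max_iter = 50, tol = 1e-4, seed = 0,
                              update_omega = TRUE,
                              omega_init = c("random", "identity")) {
  hp <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
             lambda4 = lambda4, lambda5 = lambda5, gamma = gamma,
             theta = theta, alpha = alpha, m = as.integer(m),
             r = as.integer(r), max_iter = as.integer(max_iter), tol = tol,
             seed = as.integer(seed), update_omega = isTRUE(update_omega),
             omega_init = match.arg(omega_init))
  for (nm in c("lambda1", "lambda2", "lambda3", "lambda4", "lambda5", "gamma"))
    if (hp[[nm]] < 0) stop(nm, " must be nonnegative")
  stopifnot(hp$theta > 0, hp$alpha > 0, hp$m >= 1, hp$r >= 1,
            hp$max_iter >= 1, hp$tol > 0)
  hp
}

## project columns with Euclidean norm > 1 onto the unit sphere
project_columns <- function(D) {
  nrm <- sqrt(colSums(D^2))
  over <- nrm > 1
  if (any(over)) D[, over] <- sweep(D[, over, drop = FALSE], 2, nrm[over], "/")
  D
}

init_state <- function(data, hp) {
  stopifnot(inherits(data, "multidomain"))
  if (hp$m > data$d) stop("subspace dimension m exceeds feature dimension d")
  if (hp$lambda2 > 0 && data$n_sources < 1)
    stop("MMD term (lambda2 > 0) requires at least one source domain")
  set.seed(hp$seed)
  K <- data$K
  model <- list(Omega = vector("list", K), D = vector("list", K),
                P = vector("list", K), W = vector("list", K))
  state <- list(Yk = vector("list", K), Ybar = vector("list", K),
                A = vector("list", K), Ahat = vector("list", K),
                Lambda = vector("list", K), Theta = vector("list", K),
                B = vector("list", K), C = vector("list", K),
                Chat = vector("list", K), Q = vector("list", K),
                H = vector("list", K))
  for (k in seq_len(K)) {
    pc <- pool_class(data, k)
    Yk <- pc$X; Ybar <- pool_complement(data, k)
    Nk <- ncol(Yk)
    Omega <- if (hp$omega_init == "identity" && hp$m == data$d) diag(data$d)
             else t(rorth(data$d, hp$m))
    B <- Omega %*% Yk
    Bbar <- Omega %*% Ybar
    ## short no-transfer DPL pass: the module's own A/P/D updates with
    ## lambda2 = 0 and the classifier / low-rank terms frozen
    D <- matrix(rnorm(hp$m * hp$r), hp$m, hp$r)
    D <- sweep(D, 2, pmax(sqrt(colSums(D^2)), 1e-12), "/")
    P <- matrix(rnorm(hp$r * hp$m, sd = 0.01), hp$r, hp$m)
    A <- P %*% B
    for (it in 1:5) {
      A <- solve_sym(crossprod(D) + diag(hp$lambda1, hp$r),
                     crossprod(D, B) + hp$lambda1 * P %*% B)
      P <- A %*% t(B) %*% solve_sym(tcrossprod(B) + diag(hp$theta, hp$m),
                                    diag(hp$m))
      Ahat <- P %*% Bbar
      D <- B %*% t(A) %*%
        solve_sym(tcrossprod(A) + tcrossprod(Ahat) + diag(hp$theta, hp$r),
                  diag(hp$r))
      D <- project_columns(D)
    }
    model$Omega[[k]] <- Omega; model$D[[k]] <- D; model$P[[k]] <- P
    model$W[[k]] <- eye_pad(K, hp$r)
    H <- matrix(0, K, Nk); H[k, ] <- 1
    ns <- sum(pc$domain == "source"); nt <- sum(pc$domain == "target")
    state$Yk[[k]] <- Yk; state$Ybar[[k]] <- Ybar
    state$A[[k]] <- A; state$Ahat[[k]] <- P %*% Bbar
    state$Lambda[[k]] <- eye_pad(hp$r, K); state$Theta[[k]] <- eye_pad(K, Nk)
    state$B[[k]] <- B; state$C[[k]] <- P %*% B
    state$Chat[[k]] <- P %*% Bbar
    state$Q[[k]] <- if (hp$lambda2 > 0) mmd_matrix(ns, nt) else NULL
    state$H[[k]] <- H
  }
  list(model = model, state = state)
}

## objective of the relaxed TDDPL program; complement codes enter through
## their current analytic values Chat_k = P_k Omega_k Ybar_k
tddpl_objective <- function(model, state, hp, by_term = FALSE) {
  K <- length(model$D)
  terms <- c(synthesis = 0, separation = 0, analysis = 0, mmd = 0,
             lowrank = 0, classifier = 0, relaxation = 0, ridge_W = 0)
  for (k in seq_len(K)) {
    D <- model$D[[k]]; P <- model$P[[k]]; Om <- model$Omega[[k]]
    A <- state$A[[k]]; B <- state$B[[k]]; C <- state$C[[k]]
    Bbar <- Om %*% state$Ybar[[k]]
    Chat <- P %*% Bbar
    terms["synthesis"] <- terms["synthesis"] + fsq(B - D %*% A)
    terms["separation"] <- terms["separation"] + fsq(D %*% Chat)
    terms["analysis"] <- terms["analysis"] +
      hp$lambda1 * (fsq(C - A) + fsq(Chat))
    if (hp$lambda2 > 0 && !is.null(state$Q[[k]]))
      terms["mmd"] <- terms["mmd"] + hp$lambda2 * mmd_value(A, state$Q[[k]])
    terms["lowrank"] <- terms["lowrank"] +
      hp$lambda3 * fsq(A - state$Lambda[[k]] %*% state$Theta[[k]])
    terms["classifier"] <- terms["classifier"] +
      hp$lambda4 * fsq(state$H[[k]] - model$W[[k]] %*% C)
    terms["relaxation"] <- terms["relaxation"] +
      hp$lambda5 * (fsq(B - Om %*% state$Yk[[k]]) + fsq(C - P %*% B))
    terms["ridge_W"] <- terms["ridge_W"] + hp$gamma * fsq(model$W[[k]])
  }
  if (by_term) terms else sum(terms)
}

## A-step: exact stationarity of the coding subproblem,
##   (D'D + (l1+l3) I) A + l2 A Q = D'B + l1 C + l3 Lambda Theta,
## a Sylvester-type system solved through the eigendecomposition of Q
update_coding <- function(model, state, hp) {
  for (k in seq_along(model$D)) {
    D <- model$D[[k]]
    M <- crossprod(D) + diag(hp$lambda1 + hp$lambda3, hp$r)
    G <- crossprod(D, state$B[[k]]) + hp$lambda1 * state$C[[k]] +
      hp$lambda3 * state$Lambda[[k]] %*% state$Theta[[k]]
    if (hp$lambda2 > 0 && !is.null(state$Q[[k]])) {
      eg <- eigen(state$Q[[k]]$Q, symmetric = TRUE)
      Gt <- G %*% eg$vectors
      At <- matrix(0, nrow(G), ncol(G))
      for (j in seq_len(ncol(G)))
        At[, j] <- solve_sym(M + diag(hp$lambda2 * eg$values[j], nrow(M)),
                             Gt[, j])
      state$A[[k]] <- At %*% t(eg$vectors)
    } else {
      state$A[[k]] <- solve_sym(M, G)
    }
  }
  state
}

## P-step: exact minimizer of the P-subobjective
##   ||D P Bbar||^2 + l1 ||P Bbar||^2 + l5 ||C - P B||^2 + theta ||P||^2,
## i.e. the discriminative variant that maps the class block B to C and the
## full-width complement block Bbar toward zero.  Stationarity
##   (D'D + l1 I) P Bbar Bbar' + l5 P B B' + theta P = l5 C B'
## decouples row-wise after an eigendecomposition of D'D + l1 I.  With no
## complement columns this reduces to the plain ridge form
## P = C B'(B B' + theta I)^-1 (at l5 = 1).
update_analysis <- function(model, state, hp, theta = hp$theta) {
  for (k in seq_along(model$P)) {
    B <- state$B[[k]]
    m <- nrow(B)
    SB <- hp$lambda5 * tcrossprod(B)
    G <- hp$lambda5 * state$C[[k]] %*% t(B)
    Ybar <- state$Ybar[[k]]
    if (!is.null(Ybar) && ncol(Ybar) > 0) {
      Bbar <- model$Omega[[k]] %*% Ybar
      Sbar <- tcrossprod(Bbar)
      D <- model$D[[k]]
      eg <- eigen(crossprod(D) + diag(hp$lambda1, ncol(D)), symmetric = TRUE)
      Gt <- t(eg$vectors) %*% G
      Pt <- matrix(0, nrow(Gt), m)
      for (i in seq_len(nrow(Gt)))
        Pt[i, ] <- solve_sym(SB + eg$values[i] * Sbar + diag(theta, m),
                             Gt[i, ])
      model$P[[k]] <- eg$vectors %*% Pt
    } else {
      model$P[[k]] <- G %*% solve_sym(SB + diag(theta, m), diag(m))
    }
  }
  model
}

## W-step: ridge classifier on the auxiliary codes
update_classifier <- function(model, state, hp) {
  for (k in seq_along(model$W)) {
    C <- state$C[[k]]
    model$W[[k]] <- (hp$lambda4 * state$H[[k]] %*% t(C)) %*%
      solve_sym(hp$lambda4 * tcrossprod(C) + diag(hp$gamma, nrow(C)),
                diag(nrow(C)))
  }
  model
}

## D-step: ridge closed form (the ridge stands in for the Lagrange diagonal
## of the norm constraints), columns with norm > 1 projected onto the unit
## sphere, then a monotone projected-gradient polish to the KKT point
update_synthesis <- function(model, state, hp, theta = hp$theta) {
  for (k in seq_along(model$D)) {
    A <- state$A[[k]]; Ahat <- state$Ahat[[k]]
    S <- tcrossprod(A) + diag(theta, nrow(A))
    if (!is.null(Ahat) && length(Ahat)) S <- S + tcrossprod(Ahat)
    Dnew <- project_columns(state$B[[k]] %*% t(A) %*% solve_sym(S, diag(nrow(S))))
    ## the ball projection after the ridge closed form is only a heuristic;
    ## a short projected-gradient polish drives D to the KKT point of the
    ## column-constrained subproblem (monotone, so descent is guaranteed)
    dsub <- function(D) fsq(state$B[[k]] - D %*% A) +
      if (length(Ahat)) fsq(D %*% Ahat) else 0
    if (dsub(Dnew) > dsub(model$D[[k]])) Dnew <- model$D[[k]]
    Sg <- tcrossprod(A)
    if (length(Ahat)) Sg <- Sg + tcrossprod(Ahat)
    L <- 2 * norm(Sg, "2")
    if (L > 0) {
      GB <- state$B[[k]] %*% t(A)
      f_prev <- dsub(Dnew)
      for (i in 1:200) {
        Dnew <- project_columns(Dnew - (2 * (Dnew %*% Sg - GB)) / L)
        f_cur <- dsub(Dnew)
        if (f_prev - f_cur <= 1e-12 * max(1, f_prev)) break
        f_prev <- f_cur
      }
    }
    model$D[[k]] <- Dnew
  }
  model
}

## Lambda/Theta-step: alternating least squares on the rank-K factorization
update_lowrank <- function(state) {
  for (k in seq_along(state$A)) {
    A <- state$A[[k]]; Theta <- state$Theta[[k]]
    Lambda <- A %*% t(Theta) %*% MASS::ginv(tcrossprod(Theta))
    Theta <- MASS::ginv(crossprod(Lambda)) %*% t(Lambda) %*% A
    state$Lambda[[k]] <- Lambda; state$Theta[[k]] <- Theta
  }
  state
}

## Omega-step: exact minimizer of the Omega-subobjective
##   l5 ||B - Omega Y||^2 + ||D P Omega Ybar||^2 + l1 ||P Omega Ybar||^2
##   + theta ||Omega||^2,
## decoupled row-wise through the eigendecomposition of P'(D'D + l1 I)P.
## With no complement columns this is the plain ridge regression of B on Y,
## Omega = B Y'(Y Y' + theta I)^-1 (at l5 = 1).
update_projection <- function(model, state, hp, theta = hp$theta) {
  for (k in seq_along(model$Omega)) {
    Y <- state$Yk[[k]]
    d <- nrow(Y)
    SY <- hp$lambda5 * tcrossprod(Y)
    G <- hp$lambda5 * state$B[[k]] %*% t(Y)
    Ybar <- state$Ybar[[k]]
    if (!is.null(Ybar) && ncol(Ybar) > 0) {
      Sbar <- tcrossprod(Ybar)
      P <- model$P[[k]]; D <- model$D[[k]]
      M <- crossprod(P, (crossprod(D) + diag(hp$lambda1, ncol(D))) %*% P)
      eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
      Gt <- t(eg$vectors) %*% G
      Ot <- matrix(0, nrow(Gt), d)
      for (i in seq_len(nrow(Gt)))
        Ot[i, ] <- solve_sym(SY + max(eg$values[i], 0) * Sbar +
                               diag(theta, d), Gt[i, ])
      model$Omega[[k]] <- eg$vectors %*% Ot
    } else {
      model$Omega[[k]] <- G %*% solve_sym(SY + diag(theta, d), diag(d))
    }
  }
  model
}

## quadratic subobjective of the C-step (class block + complement block)
c_subobjective <- function(C, Chat, A, H, W, PB, PBbar, hp) {
  0.5 * (hp$lambda1 * (fsq(C - A) + fsq(Chat)) +
           hp$lambda4 * fsq(H - W %*% C) +
           hp$lambda5 * (fsq(C - PB) + fsq(Chat - PBbar)))
}

c_gradients <- function(C, Chat, A, H, W, PB, PBbar, hp) {
  list(C = hp$lambda1 * (C - A) +
         hp$lambda4 * (crossprod(W) %*% C - crossprod(W, H)) +
         hp$lambda5 * (C - PB),
       Chat = hp$lambda1 * Chat + hp$lambda5 * (Chat - PBbar))
}

## C-step: one safeguarded gradient step per class; the initial step size is
## capped by the inverse Lipschitz constant and halved (up to 50 times)
## until Armijo sufficient decrease holds
update_auxiliary_C <- function(model, state, hp) {
  for (k in seq_along(state$C)) {
    P <- model$P[[k]]; W <- model$W[[k]]
    PB <- P %*% state$B[[k]]
    PBbar <- P %*% (model$Omega[[k]] %*% state$Ybar[[k]])
    C <- state$C[[k]]; Chat <- state$Chat[[k]]
    g <- c_gradients(C, Chat, state$A[[k]], state$H[[k]], W, PB, PBbar, hp)
    ## class block and complement block backtrack independently so neither
    ## can pay for the other's increase
    fC0 <- c_subobjective(C, Chat * 0, state$A[[k]], state$H[[k]], W, PB,
                          PBbar * 0, hp)
    gC2 <- fsq(g$C)
    ## start at or below the inverse Lipschitz constant of the quadratic so
    ## every accepted step contracts every eigendirection
    L_C <- hp$lambda1 + hp$lambda5 + hp$lambda4 * norm(crossprod(W), "2")
    alpha <- min(hp$alpha, 1 / L_C)
    accepted <- FALSE
    for (tries in 1:50) {
      Cn <- C - alpha * g$C
      ## Armijo sufficient decrease (implies the subobjective cannot
      ## increase and damps edge-of-stability oscillation)
      if (c_subobjective(Cn, Chat * 0, state$A[[k]], state$H[[k]], W, PB,
                         PBbar * 0, hp) <= fC0 - 0.3 * alpha * gC2) {
        accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (accepted) state$C[[k]] <- Cn
    else if (sqrt(gC2) > 1e-10)
      warning("C-step: step size underflow for class ", k,
              "; class block skipped", call. = FALSE)
    fH0 <- 0.5 * (hp$lambda1 * fsq(Chat) + hp$lambda5 * fsq(Chat - PBbar))
    gH2 <- fsq(g$Chat)
    alpha <- min(hp$alpha, 1 / (hp$lambda1 + hp$lambda5))
    accepted <- FALSE
    for (tries in 1:50) {
      Chn <- Chat - alpha * g$Chat
      if (0.5 * (hp$lambda1 * fsq(Chn) + hp$lambda5 * fsq(Chn - PBbar)) <=
          fH0 - 0.3 * alpha * gH2) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (accepted) state$Chat[[k]] <- Chn
    else if (sqrt(gH2) > 1e-10)
      warning("C-step: step size underflow for class ", k,
              "; complement block skipped", call. = FALSE)
  }
  state
}

## B-step: closed form of the relaxed subproblem,
##   B = ((1+l5) I + l5 P'P)^-1 (D A + l5 Omega Y + l5 P'C)
update_auxiliary_B <- function(model, state, hp) {
  for (k in seq_along(state$B)) {
    P <- model$P[[k]]
    m <- ncol(P)
    S <- diag(1 + hp$lambda5, m) + hp$lambda5 * crossprod(P)
    rhs <- model$D[[k]] %*% state$A[[k]] +
      hp$lambda5 * model$Omega[[k]] %*% state$Yk[[k]] +
      hp$lambda5 * crossprod(P, state$C[[k]])
    state$B[[k]] <- solve_sym(S, rhs)
  }
  state
}

## recompute the complement codes from the current analysis dictionary and
## projections (start of every sweep)
refresh_complements <- function(model, state) {
  for (k in seq_along(state$Ahat)) {
    Bbar <- model$Omega[[k]] %*% state$Ybar[[k]]
    state$Ahat[[k]] <- model$P[[k]] %*% Bbar
    state$Chat[[k]] <- model$P[[k]] %*% Bbar
  }
  state
}
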