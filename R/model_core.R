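# Core of the sparse variational coregionalized GP-LVM.
#
# Per view v the model is
#   f_v ~ GP(0, k^A_v (x) k^B_v)   over (cell, feature) pairs,
#   y_t = f_t + eps,  eps ~ N(0, sigma_v^2),
# with k^A_v an ARD-RBF kernel on the shared cell embedding A (per-view ARD
# weights w_v -> manifold relevance determination) and k^B_v an RBF kernel on
# the view's feature embedding B_v. Matched inducing pairs (a_u, b_u) collapse
# the Kronecker-product kernel to a Hadamard product, giving the standard
# sparse variational bound at O(n m^2) per pass over n observed triples.
#
# q(u) = N(q_mu, S), S = Lq Lq', Lq lower triangular (non-whitened). The
# evidence lower bound for a minibatch T of the triples, scaled to the full
# store of size N, is
#   ELBO = (N/|T|) * sum_t E_q[log N(y_t | f_t, sigma^2)] - KL(q(u) || p(u))
# with E_q[log N] = log N(y_t | mu_t, sigma^2) - var_t / (2 sigma^2),
#   mu_t  = k_t' Kuu^{-1} q_mu,
#   var_t = kff + k_t' (Kuu^{-1} S Kuu^{-1} - Kuu^{-1}) k_t.
# All gradients below are derived analytically from this expression.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# ---- parameter containers ---------------------------------------------------

# Lower-triangular variational scale from its raw parameterization: the
# strict lower triangle is stored directly, the diagonal on log scale.
.build_Lq <- function(raw) {
  L <- raw
  L[upper.tri(L)] <- 0
  diag(L) <- exp(diag(raw))
  L
}

.raw_from_Lq <- function(L) {
  raw <- L
  raw[upper.tri(raw)] <- 0
  diag(raw) <- log(pmax(diag(L), 1e-12))
  raw
}

# Initialize all trainable parameters. Embedding tables ~ N(0, 0.1^2);
# inducing indices drawn uniformly without replacement (tied lookups: the
# inducing latents are re-read from the embedding tables every step).
.init_params <- function(I, Js, r1, r2s, m, seed, feature_ard = FALSE,
                         noise_init = rep(0.1, length(Js)),
                         inducing_cells = NULL, inducing_features = NULL) {
  V <- length(Js)
  if (is.null(inducing_cells)) {   # sampling without replacement needs m <= I, J
    if (m > I) stop("n_inducing (", m, ") exceeds the number of cells (", I, ")")
    for (v in seq_len(V))
      if (m > Js[v])
        stop("n_inducing (", m, ") exceeds the feature count of view ", v,
             " (", Js[v], ")")
  }
  .with_seed(seed, {
    A <- matrix(stats::rnorm(I * r1, sd = 0.1), I, r1)
    Zc <- if (is.null(inducing_cells)) sample.int(I, m) else as.integer(inducing_cells)
    views <- vector("list", V)
    Zf <- vector("list", V)
    for (v in seq_len(V)) {
      B <- matrix(stats::rnorm(Js[v] * r2s[v], sd = 0.1), Js[v], r2s[v])
      Zf[[v]] <- if (is.null(inducing_features)) sample.int(Js[v], m)
                 else as.integer(inducing_features[[v]])
      vp <- list(
        B = B,
        logwA = rep(0, r1),
        logvA = 0,
        logwB = if (feature_ard) rep(0, r2s[v]) else 0,
        logvB = 0,
        q_mu = rep(0, length(Zc)),
        Lq_raw = matrix(0, length(Zc), length(Zc)),
        lognoise = log(noise_init[v])
      )
      # start q(u) at the prior: S = Kuu => KL = 0
      Au <- A[Zc, , drop = FALSE]
      Bu <- B[Zf[[v]], , drop = FALSE]
      KA <- ard_rbf(Au, NULL, ard_kernel(1, rep(1, r1)))
      KB <- ard_rbf(Bu, NULL, ard_kernel(1, .expand_wB(vp, r2s[v])))
      Kuu <- .kuu_hadamard(KA, KB, 1e-6)
      vp$Lq_raw <- .raw_from_Lq(t(chol(Kuu)))
      views[[v]] <- vp
    }
    list(params = list(A = A, views = views),
         inducing = list(cells = Zc, features = Zf))
  })
}

.expand_wB <- function(vp, r2) {
  w <- exp(vp$logwB)
  if (length(w) == 1L && r2 > 1L) rep(w, r2) else w
}

# PCA warm start: cell embedding from unit-scaled principal-component scores
# of the column-concatenated (centered) views; each feature embedding from
# the view's right singular vectors. Deterministic given the data. Missing
# components (r beyond the data rank) keep their random N(0, 0.1^2) values.
.pca_init <- function(params, views, r1, r2s) {
  Yall <- do.call(cbind, lapply(views, function(v)
    scale(v$values, center = TRUE, scale = FALSE)))
  k <- min(r1, nrow(Yall) - 1L, ncol(Yall))
  if (k >= 1) {
    sv <- svd(Yall, nu = k, nv = 0)
    sc <- sv$u %*% diag(sv$d[seq_len(k)], k)
    sds <- apply(sc, 2, stats::sd)
    sds[sds < 1e-12] <- 1
    params$A[, seq_len(k)] <- sweep(sc, 2, sds, "/")
  }
  for (v in seq_along(views)) {
    Yc <- scale(views[[v]]$values, center = TRUE, scale = FALSE)
    kv <- min(r2s[v], nrow(Yc) - 1L, ncol(Yc))
    if (kv < 1) next
    sv <- svd(Yc, nu = 0, nv = kv)
    ld <- sv$v
    sds <- apply(ld, 2, stats::sd)
    sds[sds < 1e-12] <- 1
    params$views[[v]]$B[, seq_len(kv)] <- sweep(ld, 2, sds, "/")
  }
  params
}

# ---- ELBO and analytic gradients for one view -------------------------------

# Returns list(elbo, dA (I x r1), grads (same shapes as vp)).
.view_elbo_grad <- function(A, vp, Zc, Zf, bi, bj, by, total_n,
                            jitter_base = 1e-6, compute_grad = TRUE) {
  m <- length(Zc); r1 <- ncol(A); r2 <- ncol(vp$B)
  nb <- length(by)
  wA <- exp(vp$logwA); vA <- exp(vp$logvA)
  wB <- .expand_wB(vp, r2); vB <- exp(vp$logvB)
  sigma2 <- exp(vp$lognoise)
  kff <- vA * vB

  Au <- A[Zc, , drop = FALSE]
  Bu <- vp$B[Zf, , drop = FALSE]
  Ab <- A[bi, , drop = FALSE]
  Bb <- vp$B[bj, , drop = FALSE]

  kA <- ard_kernel(vA, wA); kB <- ard_kernel(vB, wB)
  KAuu <- ard_rbf(Au, NULL, kA)
  KBuu <- ard_rbf(Bu, NULL, kB)
  Kuu <- KAuu * KBuu
  ch <- .chol_escalate(.kuu_hadamard(KAuu, KBuu, jitter_base * kff), kff,
                       base = jitter_base)
  R <- ch$R                               # upper Cholesky, Kuu_j = R'R
  jit <- ch$jitter
  Q <- chol2inv(R)

  KAc <- ard_rbf(Au, Ab, kA)
  KBc <- ard_rbf(Bu, Bb, kB)
  Kuf <- KAc * KBc

  Lq <- .build_Lq(vp$Lq_raw)
  S <- tcrossprod(Lq)

  alpha <- drop(Q %*% vp$q_mu)
  mu <- drop(crossprod(Kuf, alpha))
  W <- Q %*% Kuf                          # m x nb
  SW <- S %*% W
  var_t <- kff - colSums(Kuf * W) + colSums(W * SW)
  var_t <- pmax(var_t, 1e-12)

  resid <- by - mu
  sw <- total_n / nb
  ell <- -0.5 * nb * log(2 * pi * sigma2) -
    (sum(resid^2) + sum(var_t)) / (2 * sigma2)
  logdetK <- 2 * sum(log(diag(R)))
  logdetS <- 2 * sum(diag(vp$Lq_raw))
  KL <- 0.5 * (sum(Q * S) + sum(vp$q_mu * alpha) - m + logdetK - logdetS)
  elbo <- sw * ell - KL
  if (!compute_grad)
    return(list(elbo = elbo, KL = KL, mu = mu, var = var_t, jitter = jit))

  g1 <- sw * resid / sigma2               # dELBO/dmu_t
  g2 <- -sw / (2 * sigma2)                # dELBO/dvar_t (constant over t)

  Kg1 <- Kuf %*% g1                       # m x 1
  u1 <- drop(Q %*% Kg1)
  d_qmu <- u1 - alpha

  WW <- tcrossprod(W)
  Sinv <- chol2inv(t(Lq))                 # S = t(U) U with U = t(Lq)
  dS <- g2 * WW - 0.5 * (Q - Sinv)
  dL_full <- (dS + t(dS)) %*% Lq
  d_Lq_raw <- dL_full
  d_Lq_raw[upper.tri(d_Lq_raw)] <- 0
  diag(d_Lq_raw) <- diag(dL_full) * diag(Lq)

  d_sigma2 <- sw * (-0.5 * nb / sigma2 +
                      (sum(resid^2) + sum(var_t)) / (2 * sigma2^2))
  d_lognoise <- d_sigma2 * sigma2

  P <- Q %*% S                            # = Kuu^-1 S
  dKuf <- tcrossprod(alpha, g1) + 2 * g2 * (P %*% W - W)

  # adjoint of Kuu (treating entries as independent; the kernel chain below
  # symmetrizes automatically because dK[p,q]/dtheta = dK[q,p]/dtheta)
  G_uu <- -tcrossprod(u1, alpha) +
    g2 * (WW - P %*% WW - WW %*% t(P)) +
    0.5 * (P %*% Q + tcrossprod(alpha) - Q)

  # chain through the Hadamard / elementwise products
  GA_uu <- G_uu * KBuu
  GB_uu <- G_uu * KAuu
  GA_c <- dKuf * KBc
  GB_c <- dKuf * KAc

  pu_A <- .ard_rbf_vjp(GA_uu, KAuu, Au, Au, wA)
  pc_A <- .ard_rbf_vjp(GA_c, KAc, Au, Ab, wA)
  pu_B <- .ard_rbf_vjp(GB_uu, KBuu, Bu, Bu, wB)
  pc_B <- .ard_rbf_vjp(GB_c, KBc, Bu, Bb, wB)

  dA <- matrix(0, nrow(A), r1)
  dAu <- pu_A$dX + pu_A$dZ + pc_A$dX
  rs <- rowsum(pc_A$dZ, bi)
  ridx <- as.integer(rownames(rs))
  dA[ridx, ] <- dA[ridx, ] + rs
  dA[Zc, ] <- dA[Zc, ] + dAu

  dB <- matrix(0, nrow(vp$B), r2)
  dBu <- pu_B$dX + pu_B$dZ + pc_B$dX
  rsB <- rowsum(pc_B$dZ, bj)
  ridxB <- as.integer(rownames(rsB))
  dB[ridxB, ] <- dB[ridxB, ] + rsB
  dB[Zf, ] <- dB[Zf, ] + dBu

  # amplitude terms: kernel entries scale with their variance, the noiseless
  # diagonal kff = vA * vB enters every var_t, and the jitter is relative
  d_logvA <- pu_A$dlogv + pc_A$dlogv + nb * g2 * kff + jit * sum(diag(G_uu))
  d_logvB <- pu_B$dlogv + pc_B$dlogv + nb * g2 * kff + jit * sum(diag(G_uu))
  d_logwA <- pu_A$dlogw + pc_A$dlogw
  d_logwB_full <- pu_B$dlogw + pc_B$dlogw
  d_logwB <- if (length(vp$logwB) == 1L) sum(d_logwB_full) else d_logwB_full

  list(elbo = elbo, KL = KL,
       dA = dA,
       grads = list(B = dB, logwA = d_logwA, logvA = d_logvA,
                    logwB = d_logwB, logvB = d_logvB,
                    q_mu = d_qmu, Lq_raw = d_Lq_raw,
                    lognoise = d_lognoise))
}

# Vector-Jacobian product of K = ard_rbf(X, Z) against adjoint G:
# accumulates into dX, dZ, d(log variance), d(log weights).
.ard_rbf_vjp <- function(G, K, X, Z, w) {
  GK <- G * K
  r <- ncol(X)
  dX <- matrix(0, nrow(X), r)
  dZ <- matrix(0, nrow(Z), r)
  dlogw <- numeric(r)
  for (d in seq_len(r)) {
    Dm <- outer(X[, d], Z[, d], "-")
    Tm <- GK * Dm
    dlogw[d] <- -0.5 * w[d] * sum(Tm * Dm)
    dX[, d] <- -w[d] * rowSums(Tm)
    dZ[, d] <- w[d] * colSums(Tm)
  }
  list(dX = dX, dZ = dZ, dlogv = sum(GK), dlogw = dlogw)
}

# ---- joint ELBO across views ------------------------------------------------

# batches: list over views of list(i, j, y); totals: full triple counts.
.joint_elbo_grad <- function(params, inducing, batches, totals,
                             view_weights, compute_grad = TRUE) {
  V <- length(params$views)
  dA <- if (compute_grad) matrix(0, nrow(params$A), ncol(params$A)) else NULL
  vgrads <- vector("list", V)
  elbo <- 0
  for (v in seq_len(V)) {
    b <- batches[[v]]
    out <- .view_elbo_grad(params$A, params$views[[v]], inducing$cells,
                           inducing$features[[v]], b$i, b$j, b$y, totals[v],
                           compute_grad = compute_grad)
    elbo <- elbo + view_weights[v] * out$elbo
    if (compute_grad) {
      dA <- dA + view_weights[v] * out$dA
      vgrads[[v]] <- lapply(out$grads, function(g) view_weights[v] * g)
    }
  }
  if (!compute_grad) return(list(elbo = elbo))
  list(elbo = elbo, grads = list(A = dA, views = vgrads))
}

# ---- Adam on nested parameter lists -----------------------------------------

.zeros_like <- function(x) {
  if (is.list(x)) lapply(x, .zeros_like) else x * 0
}

.adam_init <- function(params) {
  list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, mm, vv, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    mm <- beta1 * mm + (1 - beta1) * g
    vv <- beta2 * vv + (1 - beta2) * g^2
    mhat <- mm / (1 - beta1^t)
    vhat <- vv / (1 - beta2^t)
    list(p = p + lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# ---- training loop ----------------------------------------------------------

# stores: list of triple_store; returns params, trace, inducing.
.fit_core <- function(params, inducing, stores, epochs, batch_size,
                      learning_rate, seed, view_weights, verbose = FALSE,
                      ard_refine = 0) {
  V <- length(stores)
  totals <- vapply(stores, function(s) length(s$y), 0)
  state <- .adam_init(params)
  trace <- numeric(epochs + ard_refine)
  .with_seed(seed + 1L, {
    perm <- lapply(stores, function(s) sample.int(length(s$y)))
    pos <- rep(1L, V)
    steps <- max(ceiling(totals / batch_size))
    for (ep in seq_len(epochs + ard_refine)) {
      refine <- ep > epochs
      ep_elbo <- 0
      for (st in seq_len(steps)) {
        batches <- vector("list", V)
        for (v in seq_len(V)) {
          n_v <- totals[v]
          bs <- min(batch_size, n_v)
          if (pos[v] + bs - 1L > n_v) {
            perm[[v]] <- sample.int(n_v)
            pos[v] <- 1L
          }
          idx <- perm[[v]][pos[v]:(pos[v] + bs - 1L)]
          pos[v] <- pos[v] + bs
          s <- stores[[v]]
          batches[[v]] <- list(i = s$i[idx], j = s$j[idx], y = s$y[idx])
        }
        out <- .joint_elbo_grad(params, inducing, batches, totals,
                                view_weights)
        if (!is.finite(out$elbo))
          stop("non-finite ELBO at epoch ", ep, ", step ", st,
               " (noise variances: ",
               paste(sprintf("%.3g", vapply(params$views,
                 function(vp) exp(vp$lognoise), 0)), collapse = ", "),
               "); try a smaller learning rate")
        ep_elbo <- ep_elbo + out$elbo
        if (refine) {
          # ARD refinement: hold the embedding tables fixed and let the
          # kernel, variational and noise parameters settle (the weight
          # update the relevance-determination readout relies on)
          out$grads$A[] <- 0
          for (v in seq_len(V)) out$grads$views[[v]]$B[] <- 0
        }
        ad <- .adam_step(params, out$grads, state, learning_rate)
        params <- ad$params
        state <- ad$state
      }
      trace[ep] <- ep_elbo / steps
      if (verbose && (ep %% 10L == 0L || ep == 1L))
        message(sprintf("epoch %4d  ELBO %.4f", ep, trace[ep]))
    }
  })
  list(params = params, trace = trace, inducing = inducing)
}

# ---- closed-form optimal q(u) (collapsed bound optimum) ---------------------

# For fixed hyperparameters and the full triple store, the variational
# optimum of the Gaussian sparse-GP bound is available in closed form:
#   C     = Kuu + sigma^-2 Kuf Kfu
#   S*    = Kuu C^-1 Kuu
#   q_mu* = sigma^-2 Kuu C^-1 Kuf y
.optimal_q_view <- function(A, vp, Zc, Zf, store, jitter_base = 1e-6) {
  r1 <- ncol(A); r2 <- ncol(vp$B)
  wA <- exp(vp$logwA); vA <- exp(vp$logvA)
  wB <- .expand_wB(vp, r2); vB <- exp(vp$logvB)
  sigma2 <- exp(vp$lognoise); kff <- vA * vB
  Au <- A[Zc, , drop = FALSE]; Bu <- vp$B[Zf, , drop = FALSE]
  kA <- ard_kernel(vA, wA); kB <- ard_kernel(vB, wB)
  Kuu <- .kuu_hadamard(ard_rbf(Au, NULL, kA), ard_rbf(Bu, NULL, kB),
                       jitter_base * kff)
  Kuf <- coreg_cross_cov(A[store$i, , drop = FALSE],
                         vp$B[store$j, , drop = FALSE], Au, Bu, kA, kB)
  C <- Kuu + tcrossprod(Kuf) / sigma2
  Rc <- chol(C)
  Cinv_Kuu <- backsolve(Rc, forwardsolve(t(Rc), Kuu))
  Sstar <- Kuu %*% Cinv_Kuu
  Sstar <- (Sstar + t(Sstar)) / 2
  qmu <- drop(Kuu %*% backsolve(Rc, forwardsolve(t(Rc), Kuf %*% store$y))) / sigma2
  vp$q_mu <- qmu
  vp$Lq_raw <- .raw_from_Lq(t(chol(Sstar + diag(1e-10 * kff, nrow(Sstar)))))
  vp
}
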