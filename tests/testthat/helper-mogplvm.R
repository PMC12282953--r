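# Shared helpers: small random model builders and independent oracles.

# A tiny model with arbitrary (non-degenerate) parameters and an attached
# full-grid triple store, for bound/gradient/posterior checks.
tiny_model <- function(I = 3, J = 2, r1 = 2, r2 = 2, m = 2, seed = 1,
                       noise = 0.3, full_grid_inducing = FALSE) {
  set.seed(seed)
  Y <- matrix(rnorm(I * J), I, J)
  store <- build_triple_store(view_matrix(Y))
  if (full_grid_inducing) {
    init <- mogplvm:::.init_params(I, J, r1, r2, I * J, seed,
                                   inducing_cells = rep(seq_len(I), each = J),
                                   inducing_features = list(rep(seq_len(J), I)))
  } else {
    init <- mogplvm:::.init_params(I, J, r1, r2, m, seed)
  }
  model <- mogplvm_init(I, J, r_cells = r1, r_features = r2,
                        n_inducing = min(m, I, J), seed = seed)
  model$params <- init$params
  model$inducing <- init$inducing
  model$params$A <- matrix(rnorm(I * r1, sd = 0.6), I, r1)
  vp <- model$params$views[[1]]
  vp$B <- matrix(rnorm(J * r2, sd = 0.6), J, r2)
  vp$logwA <- rnorm(r1, sd = 0.3)
  vp$logvA <- rnorm(1, sd = 0.2)
  vp$logwB <- rnorm(length(vp$logwB), sd = 0.3)
  vp$logvB <- rnorm(1, sd = 0.2)
  mq <- length(model$inducing$cells)
  vp$q_mu <- rnorm(mq, sd = 0.5)
  L <- matrix(rnorm(mq * mq, sd = 0.2), mq, mq)
  L[upper.tri(L)] <- 0
  vp$Lq_raw <- L
  vp$lognoise <- log(noise)
  model$params$views[[1]] <- vp
  model$stores <- list(store)
  model$views <- list(view_matrix(Y))
  model
}

# Independent exact log marginal likelihood over a full-grid store, built
# from base kronecker() and dense linear algebra only (cell-major order).
oracle_log_marginal <- function(model, jitter = 1e-6) {
  s <- model$stores[[1]]
  vp <- model$params$views[[1]]
  r2 <- ncol(vp$B)
  wB <- exp(vp$logwB); if (length(wB) == 1) wB <- rep(wB, r2)
  KA <- ard_rbf(model$params$A, NULL, ard_kernel(exp(vp$logvA), exp(vp$logwA)))
  KB <- ard_rbf(vp$B, NULL, ard_kernel(exp(vp$logvB), wB))
  K <- kronecker(KA, KB)
  kff <- exp(vp$logvA) * exp(vp$logvB)
  y <- as.vector(t(triples_to_matrix(s)))   # cell-major vectorization
  Sigma <- K + diag(jitter * kff + exp(vp$lognoise), nrow(K))
  R <- chol(Sigma)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(R))) +
            sum(y * backsolve(R, forwardsolve(t(R), y))))
}

# Exact GP posterior mean/variance of f at every grid pair, via the full
# Kronecker kernel (independent of the sparse path).
oracle_posterior <- function(model, jitter = 1e-6) {
  s <- model$stores[[1]]
  vp <- model$params$views[[1]]
  r2 <- ncol(vp$B)
  wB <- exp(vp$logwB); if (length(wB) == 1) wB <- rep(wB, r2)
  KA <- ard_rbf(model$params$A, NULL, ard_kernel(exp(vp$logvA), exp(vp$logwA)))
  KB <- ard_rbf(vp$B, NULL, ard_kernel(exp(vp$logvB), wB))
  K <- kronecker(KA, KB)
  kff <- exp(vp$logvA) * exp(vp$logvB)
  Kj <- K + diag(jitter * kff, nrow(K))
  y <- as.vector(t(triples_to_matrix(s)))
  Sigma <- Kj + diag(exp(vp$lognoise), nrow(K))
  Sinv_y <- solve(Sigma, y)
  mean_vec <- Kj %*% Sinv_y
  cov_post <- Kj - Kj %*% solve(Sigma, Kj)
  list(mean = matrix(mean_vec, s$I, s$J, byrow = TRUE),
       var = matrix(pmax(diag(cov_post), 0), s$I, s$J, byrow = TRUE))
}

# Brute-force modal-label clustering accuracy (independent recomputation).
oracle_acc <- function(assignment, labels) {
  pred <- character(length(assignment))
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    counts <- table(labels[idx])
    best <- sort(names(counts)[counts == max(counts)])[1]
    pred[idx] <- best
  }
  100 * sum(pred == labels) / length(labels)
}

# Brute-force adjusted Rand index by looping over all pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    same_a <- a[p] == a[q]; same_b <- b[p] == b[q]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(0)
  (s11 - expected) / (maxi - expected)
}

# Hypergeometric upper tail by exhaustive enumeration of the pmf.
oracle_hyper_tail <- function(ov, K, N, g) {
  ks <- max(0, g - (N - K)):min(K, g)
  pmf <- choose(K, ks) * choose(N - K, g - ks) / choose(N, g)
  sum(pmf[ks >= ov])
}
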