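#' ARD kernel parameters
#'
#' Bundle the amplitude and per-dimension automatic relevance determination
#' (ARD) weights of a squared-exponential kernel
#' \deqn{k(x, x') = \sigma^2 \exp\{-\tfrac12 \sum_r w_r (x_r - x'_r)^2\}.}
#' A weight of zero removes that latent dimension's influence entirely, which
#' is what makes the learned weights readable as per-dimension relevances.
#'
#' @param variance Nonnegative scalar kernel amplitude \eqn{\sigma^2}.
#' @param weights Numeric vector of nonnegative per-dimension ARD weights; its
#'   length must equal the dimension of the latent points the kernel is
#'   applied to.
#' @return An object of class `"ard_kernel"`: a list with elements `variance`
#'   and `weights`.
#' @examples
#' k <- ard_kernel(1, c(1, 0.5))
#' ard_rbf(matrix(0, 1, 2), matrix(1, 1, 2), k)
#' @export
ard_kernel <- function(variance, weights) {
  stopifnot(is.numeric(variance), length(variance) == 1L, is.numeric(weights))
  if (variance < 0) stop("kernel variance must be nonnegative")
  if (any(weights < 0)) stop("ARD weights must be nonnegative")
  structure(list(variance = as.numeric(variance), weights = as.numeric(weights)),
            class = "ard_kernel")
}

#' ARD-RBF covariance matrix
#'
#' Evaluate the ARD squared-exponential kernel between two sets of latent
#' points. The diagonal of `ard_rbf(X, X, params)` equals `params$variance`.
#'
#' @param X Numeric matrix, `n x r`, one latent point per row.
#' @param X2 Numeric matrix, `n2 x r`, or `NULL` for `X2 = X`.
#' @param params An [ard_kernel()] object with `length(weights) == ncol(X)`.
#' @return An `n x n2` covariance matrix.
#' @export
ard_rbf <- function(X, X2 = NULL, params) {
  X <- as.matrix(X)
  if (is.null(X2)) X2 <- X else X2 <- as.matrix(X2)
  if (ncol(X) != ncol(X2))
    stop("X and X2 must have the same latent dimension")
  if (ncol(X) != length(params$weights))
    stop("length(params$weights) (", length(params$weights),
         ") does not match the latent dimension of X (", ncol(X), ")")
  params$variance * exp(-0.5 * .wsqdist(X, X2, params$weights))
}

# Weighted squared distances sum_r w_r (x_ir - x_jr)^2, n x n2.
# Computed per dimension with outer differences: exact (no catastrophic
# cancellation from the expanded-square trick) and fast at the r <= ~32
# latent dimensions this model uses.
.wsqdist <- function(X, X2, w) {
  D <- matrix(0, nrow(X), nrow(X2))
  for (r in seq_len(ncol(X))) {
    if (w[r] == 0) next
    D <- D + w[r] * outer(X[, r], X2[, r], "-")^2
  }
  D
}

#' Full coregionalization kernel (Kronecker oracle)
#'
#' The exact covariance over all `(cell, feature)` pairs is the Kronecker
#' product of the cell kernel and the feature kernel. Its row ordering is
#' cell-major, matching the triple-store vectorization `t = (i - 1) * J + j`,
#' so `coreg_kernel_full(KA, KB)[t, t'] = KA[i, i'] * KB[j, j']`. The matrix
#' is `(I * J) x (I * J)`; this function exists as an exact reference for
#' small problems and refuses to build matrices above `guard` rows.
#'
#' @param KA Square cell-cell covariance matrix (`I x I`).
#' @param KB Square feature-feature covariance matrix (`J x J`).
#' @param guard Maximum allowed value of `I * J` (default `1e4`).
#' @return The `(I * J) x (I * J)` Kronecker-product covariance.
#' @export
coreg_kernel_full <- function(KA, KB, guard = 1e4) {
  KA <- as.matrix(KA); KB <- as.matrix(KB)
  if (nrow(KA) != ncol(KA) || nrow(KB) != ncol(KB))
    stop("KA and KB must be square")
  n <- as.double(nrow(KA)) * nrow(KB)
  if (n > guard)
    stop("refusing to build a ", n, " x ", n,
         " coregionalization kernel (guard = ", guard,
         "); this path is an exact-reference oracle for small problems only")
  kronecker(KA, KB)
}

#' Cross-covariance via the Hadamard (matched inducing point) trick
#'
#' With the same number `m` of inducing points in the cell and feature latent
#' spaces, the inducing inputs are the matched pairs `(a_u, b_u)` and the
#' Kronecker product collapses to an elementwise product:
#' `K_uu = K^A(Au, Au) * K^B(Bu, Bu)` (Hadamard) and
#' `K_uf[u, t] = k^A(a_u, a_{i(t)}) * k^B(b_u, b_{j(t)})` for each observed
#' triple `t = (i, j, y_ij)`. This is what makes training cost linear in the
#' number of observed entries.
#'
#' @param cell_latents `n x r1` matrix of cell latent coordinates at the
#'   triples (row `t` is the latent of cell `i(t)`).
#' @param feat_latents `n x r2` matrix of feature latent coordinates at the
#'   triples.
#' @param Au,Bu `m x r1` and `m x r2` matrices of matched inducing latents.
#' @param paramsA,paramsB [ard_kernel()] parameters of the cell and feature
#'   kernels.
#' @return `m x n` cross-covariance matrix `K_uf`.
#' @seealso [coreg_kernel_full()] for the exact Kronecker reference.
#' @export
coreg_cross_cov <- function(cell_latents, feat_latents, Au, Bu,
                            paramsA, paramsB) {
  Au <- as.matrix(Au); Bu <- as.matrix(Bu)
  if (nrow(Au) != nrow(Bu))
    stop("Au and Bu must contain the same number m of matched inducing rows")
  if (nrow(as.matrix(cell_latents)) != nrow(as.matrix(feat_latents)))
    stop("cell_latents and feat_latents must have one row per triple")
  ard_rbf(Au, cell_latents, paramsA) * ard_rbf(Bu, feat_latents, paramsB)
}

# Hadamard inducing covariance with a PSD jitter proportional to the product
# amplitude on the diagonal.
.kuu_hadamard <- function(KAuu, KBuu, jitter) {
  K <- KAuu * KBuu
  diag(K) <- diag(K) + jitter
  K
}

# Cholesky with jitter escalation 1e-6 -> 1e-4 (relative to the kernel
# amplitude `kff`). Returns list(L = lower Cholesky factor, jitter used).
.chol_escalate <- function(K, kff, base = 1e-6, max_mult = 100) {
  jit <- base * kff
  for (level in 0:2) {
    Kj <- K
    diag(Kj) <- diag(Kj) + jit * 100^level - jit # base jitter already applied upstream
    R <- tryCatch(chol(Kj), error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = jit * 100^level))
  }
  stop("Cholesky factorization failed after jitter escalation to ",
       format(jit * 1e4), "; kernel amplitude = ", format(kff),
       ", min diagonal = ", format(min(diag(K))))
}
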