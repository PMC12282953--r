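#' Fit a multi-output GP latent variable model to one or more views
#'
#' Learns a shared low-dimensional embedding of cells and, per modality, an
#' embedding of that modality's features, by maximizing a sparse variational
#' evidence lower bound with Adam. The covariance over observed matrix
#' entries is the product of an ARD-RBF kernel on the cell embedding (with
#' per-view ARD weights, so dimensions can be shared between or private to
#' modalities) and an RBF kernel on the feature embedding; matched inducing
#' points keep each optimizer step linear in the number of observed entries.
#'
#' Observed values are modeled with a Gaussian likelihood (one noise variance
#' per view), so inputs should be on a log-like scale. All randomness
#' (initialization, inducing-point choice, minibatch order) is driven by
#' `seed`; two fits with identical inputs and seed are identical.
#'
#' @param views A numeric matrix (cells x features), a [view_matrix()], or a
#'   (optionally named) list of these over the *same* cells. Multiple views
#'   must agree on cell ids (use [intersect_cells()] first if they do not).
#' @param r_cells Dimension of the shared cell embedding (default 2).
#' @param r_features Dimension(s) of the feature embedding, scalar or one per
#'   view (default 2).
#' @param n_inducing Number m of matched inducing points (default 32; must
#'   not exceed the cell count or any view's feature count).
#' @param epochs Training epochs (full passes over the triples; default 200).
#' @param batch_size Minibatch size in triples (default 2048).
#' @param learning_rate Adam step size (default 0.01).
#' @param seed Integer seed controlling all randomness.
#' @param keep_zeros Keep zero entries as observations (default `TRUE`).
#' @param feature_ard Per-dimension ARD weights on the feature kernels
#'   (default `FALSE`: one weight tied across feature-latent dimensions).
#' @param init `"pca"` (default) starts the cell embedding at the unit-scaled
#'   principal-component scores of the column-concatenated views and each
#'   feature embedding at the view's loadings — the standard GP-LVM starting
#'   point, which avoids the collapsed local optima random starts are prone
#'   to; `"random"` starts all tables at N(0, 0.1^2).
#' @param view_weights Optional per-view weights on the summed ELBO (default
#'   all 1; the model integrates views of very different widths without
#'   variance normalization).
#' @param ard_refine Extra epochs appended after the main run during which
#'   the embedding tables are held fixed and only the kernel (ARD weights,
#'   amplitudes), variational and noise parameters are updated (default 0).
#'   With the latent geometry frozen, the per-view ARD weights of unused
#'   dimensions decay cleanly, which sharpens the shared/private/absent
#'   readout.
#' @param verbose Print the ELBO every 10 epochs.
#' @return An object of class `"mogplvm"`; see [coef.mogplvm()],
#'   [predict.mogplvm()], [summary.mogplvm()], [ard_weights()],
#'   [partition_dimensions()], [feature_relevance()].
#' @examples
#' sim <- make_marker_toy(n_types = 2, markers_per_type = 5,
#'                        cells_per_type = 20, seed = 1)
#' fit <- mogplvm(sim$view, n_inducing = 16, epochs = 20, seed = 1)
#' fit
#' @export
mogplvm <- function(views, r_cells = 2, r_features = 2, n_inducing = 32,
                    epochs = 200, batch_size = 2048, learning_rate = 0.01,
                    seed = 1, keep_zeros = TRUE, feature_ard = FALSE,
                    init = c("pca", "random"), view_weights = NULL,
                    ard_refine = 0, verbose = FALSE) {
  init <- match.arg(init)
  views <- .as_view_list(views)
  V <- length(views)
  I <- nrow(views[[1]]$values)
  for (v in views[-1]) {
    if (!identical(v$cell_ids, views[[1]]$cell_ids))
      stop("all views must share identical cell ids in identical order; ",
           "run intersect_cells() first")
  }
  Js <- vapply(views, function(v) ncol(v$values), 0L)
  r2s <- rep_len(r_features, V)
  if (is.null(view_weights)) view_weights <- rep(1, V)
  stopifnot(length(view_weights) == V, all(view_weights > 0),
            r_cells >= 1, all(r2s >= 1), epochs >= 1, batch_size >= 1,
            learning_rate > 0)

  stores <- lapply(views, build_triple_store, keep_zeros = keep_zeros)
  noise_init <- vapply(stores, function(s) max(0.1 * stats::var(s$y), 1e-4), 0)
  init0 <- .init_params(I, Js, r_cells, r2s, n_inducing, seed,
                        feature_ard = feature_ard, noise_init = noise_init)
  if (init == "pca")
    init0$params <- .pca_init(init0$params, views, r_cells, r2s)
  fitted <- .fit_core(init0$params, init0$inducing, stores, epochs, batch_size,
                      learning_rate, seed, view_weights, verbose,
                      ard_refine = ard_refine)

  structure(list(
    params = fitted$params,
    inducing = fitted$inducing,
    views = views,
    stores = stores,
    trace = fitted$trace,
    config = list(r_cells = r_cells, r_features = r2s,
                  n_inducing = n_inducing, epochs = epochs,
                  batch_size = batch_size, learning_rate = learning_rate,
                  seed = seed, keep_zeros = keep_zeros,
                  feature_ard = feature_ard, init = init,
                  view_weights = view_weights),
    view_names = vapply(views, function(v) v$view_name, "")
  ), class = "mogplvm")
}

.as_view_list <- function(views) {
  if (inherits(views, "view_matrix")) views <- list(views)
  if (is.matrix(views)) views <- list(view_matrix(views))
  if (!is.list(views)) stop("'views' must be a matrix, view_matrix or list")
  nm <- names(views)
  out <- lapply(seq_along(views), function(k) {
    v <- views[[k]]
    if (is.matrix(v)) v <- view_matrix(v, view_name =
        if (!is.null(nm) && nzchar(nm[k])) nm[k] else paste0("view", k))
    if (!inherits(v, "view_matrix")) stop("each view must be a matrix or view_matrix")
    if (!is.null(nm) && nzchar(nm[k])) v$view_name <- nm[k]
    v
  })
  out
}

.resolve_view <- function(object, view) {
  if (is.character(view)) {
    k <- match(view, object$view_names)
    if (is.na(k)) stop("unknown view '", view, "'; available: ",
                       paste(object$view_names, collapse = ", "))
    return(k)
  }
  k <- as.integer(view)
  if (k < 1 || k > length(object$params$views)) stop("view index out of range")
  k
}

#' Initialize an untrained model
#'
#' Exposes the initializer used by [mogplvm()]: embedding tables drawn from
#' N(0, 0.1^2), inducing indices sampled uniformly without replacement, and
#' the variational distribution started at the prior. Mostly useful for
#' testing and for custom training loops.
#'
#' @inheritParams mogplvm
#' @param I Number of cells.
#' @param J Feature count, scalar (single view) or vector (one per view).
#' @return An untrained `"mogplvm"` object (no data attached).
#' @export
mogplvm_init <- function(I, J, r_cells = 2, r_features = 2, n_inducing = 8,
                         seed = 1, feature_ard = FALSE) {
  r2s <- rep_len(r_features, length(J))
  init <- .init_params(I, J, r_cells, r2s, n_inducing, seed,
                       feature_ard = feature_ard,
                       noise_init = rep(0.1, length(J)))
  structure(list(params = init$params, inducing = init$inducing,
                 views = NULL, stores = NULL, trace = numeric(0),
                 config = list(r_cells = r_cells, r_features = r2s,
                               n_inducing = n_inducing, seed = seed,
                               feature_ard = feature_ard,
                               view_weights = rep(1, length(J))),
                 view_names = paste0("view", seq_along(J))),
            class = "mogplvm")
}

#' Evidence lower bound of a model
#'
#' Recomputes the stochastic evidence lower bound, by default over the full
#' attached triple stores. A minibatch can be supplied per view as integer
#' indices into the store's triples; the likelihood term is then rescaled by
#' `total / batch` as during training.
#'
#' @param object A `"mogplvm"` object.
#' @param stores Optional list of `triple_store`s (defaults to the stores the
#'   model was fitted on).
#' @param batch Optional list (per view) of integer indices into the triples,
#'   or a single vector for a one-view model.
#' @return The scalar ELBO (sum over views).
#' @export
model_elbo <- function(object, stores = NULL, batch = NULL) {
  stores <- stores %||% object$stores
  if (is.null(stores)) stop("no triple stores attached; supply 'stores'")
  if (inherits(stores, "triple_store")) stores <- list(stores)
  V <- length(stores)
  if (!is.null(batch) && !is.list(batch)) batch <- list(batch)
  totals <- vapply(stores, function(s) length(s$y), 0)
  batches <- lapply(seq_len(V), function(v) {
    s <- stores[[v]]
    idx <- if (is.null(batch)) seq_along(s$y) else batch[[v]]
    list(i = s$i[idx], j = s$j[idx], y = s$y[idx])
  })
  vw <- object$config$view_weights %||% rep(1, V)
  .joint_elbo_grad(object$params, object$inducing, batches, totals,
                   vw, compute_grad = FALSE)$elbo
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form optimal variational distribution
#'
#' For fixed kernel and noise parameters, replaces each view's variational
#' distribution q(u) with its full-batch optimum (the collapsed-bound
#' solution). Useful to tighten the bound without gradient steps, e.g. when
#' comparing the ELBO against an exact log marginal likelihood.
#'
#' @inheritParams model_elbo
#' @return The model with updated variational state.
#' @export
optimal_q <- function(object, stores = NULL) {
  stores <- stores %||% object$stores
  if (is.null(stores)) stop("no triple stores attached; supply 'stores'")
  if (inherits(stores, "triple_store")) stores <- list(stores)
  for (v in seq_along(stores)) {
    object$params$views[[v]] <- .optimal_q_view(
      object$params$A, object$params$views[[v]], object$inducing$cells,
      object$inducing$features[[v]], stores[[v]])
  }
  object
}

#' Exact log marginal likelihood (small-problem oracle)
#'
#' Evaluates log N(y | 0, K + sigma^2 I) with K the exact coregionalization
#' covariance over the observed triples (the same kernel, including its
#' relative jitter, whose inducing restriction the sparse bound uses). Dense
#' in the number of triples; refuses problems above `guard` triples.
#'
#' @inheritParams model_elbo
#' @param guard Maximum total triples (default 4000).
#' @return Scalar log marginal likelihood summed over views.
#' @export
exact_log_marginal <- function(object, stores = NULL, guard = 4000) {
  stores <- stores %||% object$stores
  if (inherits(stores, "triple_store")) stores <- list(stores)
  total <- 0
  for (v in seq_along(stores)) {
    s <- stores[[v]]
    n <- length(s$y)
    if (n > guard) stop("exact log marginal refused for ", n,
                        " triples (guard = ", guard, ")")
    vp <- object$params$views[[v]]
    r2 <- ncol(vp$B)
    kA <- ard_kernel(exp(vp$logvA), exp(vp$logwA))
    kB <- ard_kernel(exp(vp$logvB), .expand_wB(vp, r2))
    kff <- kA$variance * kB$variance
    KA <- ard_rbf(object$params$A, NULL, kA)
    KB <- ard_rbf(vp$B, NULL, kB)
    K <- KA[s$i, s$i] * KB[s$j, s$j]
    diag(K) <- diag(K) + 1e-6 * kff + exp(vp$lognoise)
    R <- chol(K)
    a <- backsolve(R, forwardsolve(t(R), s$y))
    total <- total - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) +
                              sum(s$y * a))
  }
  total
}

# Per-view posterior pieces used by predict and the relevance maps.
.view_posterior <- function(object, v) {
  vp <- object$params$views[[v]]
  A <- object$params$A
  Zc <- object$inducing$cells; Zf <- object$inducing$features[[v]]
  r2 <- ncol(vp$B)
  kA <- ard_kernel(exp(vp$logvA), exp(vp$logwA))
  kB <- ard_kernel(exp(vp$logvB), .expand_wB(vp, r2))
  kff <- kA$variance * kB$variance
  Au <- A[Zc, , drop = FALSE]; Bu <- vp$B[Zf, , drop = FALSE]
  Kuu <- .kuu_hadamard(ard_rbf(Au, NULL, kA), ard_rbf(Bu, NULL, kB),
                       1e-6 * kff)
  Q <- chol2inv(chol(Kuu))
  Lq <- .build_Lq(vp$Lq_raw)
  S <- tcrossprod(Lq)
  QSQ <- Q %*% S %*% Q
  list(vp = vp, A = A, Au = Au, Bu = Bu, kA = kA, kB = kB, kff = kff,
       Q = Q, S = S, M = Q - QSQ, alpha = drop(Q %*% vp$q_mu),
       sigma2 = exp(vp$lognoise))
}

#' Posterior mean and variance of the denoised signal
#'
#' Predicts the GP posterior mean and marginal variance of the noiseless
#' value f_ij for every requested (cell, feature) pair of one view
#' (observation noise excluded).
#'
#' @param object A fitted `"mogplvm"`.
#' @param cells Integer cell indices (default: all cells).
#' @param features Integer feature indices of the view (default: all).
#' @param view View index or name (default first view).
#' @param ... Unused.
#' @return List with matrices `mean` and `var`, cells x features.
#' @export
predict.mogplvm <- function(object, cells = NULL, features = NULL, view = 1,
                            ...) {
  v <- .resolve_view(object, view)
  post <- .view_posterior(object, v)
  I <- nrow(post$A); J <- nrow(post$vp$B)
  cells <- if (is.null(cells)) seq_len(I) else as.integer(cells)
  features <- if (is.null(features)) seq_len(J) else as.integer(features)
  if (any(cells < 1 | cells > I)) stop("cell index out of range 1..", I)
  if (any(features < 1 | features > J)) stop("feature index out of range 1..", J)
  KAc <- ard_rbf(post$Au, post$A[cells, , drop = FALSE], post$kA)   # m x nc
  KBc <- ard_rbf(post$Bu, post$vp$B[features, , drop = FALSE], post$kB)
  Hm <- KBc * post$alpha
  mean <- crossprod(KAc, Hm)                                        # nc x nf
  var <- matrix(0, length(cells), length(features))
  for (ci in seq_along(cells)) {
    Kt <- KAc[, ci] * KBc                                           # m x nf
    var[ci, ] <- post$kff - colSums(Kt * (post$M %*% Kt))
  }
  var <- pmax(var, 0)
  dimnames(mean) <- dimnames(var) <-
    list(object$views[[v]]$cell_ids[cells] %||% NULL,
         object$views[[v]]$feature_ids[features] %||% NULL)
  list(mean = mean, var = var)
}

#' @export
fitted.mogplvm <- function(object, view = 1, ...) {
  predict(object, view = view)$mean
}

#' @export
residuals.mogplvm <- function(object, view = 1, ...) {
  v <- .resolve_view(object, view)
  if (is.null(object$views)) stop("model has no attached data")
  object$views[[v]]$values - fitted(object, view = v)
}

#' Simulate replicate observations from the fitted model
#'
#' Draws from the posterior predictive at the observed (cell, feature) grid
#' of one view: posterior mean plus marginal posterior and observation noise.
#'
#' @param object A fitted `"mogplvm"`.
#' @param nsim Number of replicate matrices.
#' @param seed Optional seed.
#' @param view View index or name.
#' @param ... Unused.
#' @return A list of `nsim` cells x features matrices.
#' @export
simulate.mogplvm <- function(object, nsim = 1, seed = NULL, view = 1, ...) {
  v <- .resolve_view(object, view)
  p <- predict(object, view = v)
  sd <- sqrt(p$var + .view_posterior(object, v)$sigma2)
  draw <- function() p$mean + matrix(stats::rnorm(length(sd)), nrow(sd)) * sd
  if (!is.null(seed)) .with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

#' Extract model coefficients
#'
#' @param object A `"mogplvm"` object.
#' @param ... Unused.
#' @return List with `cell_embedding` (I x r1), `feature_embeddings` (list of
#'   J_v x r2 matrices), `ard_weights` (r1 x V), `kernel_variances`,
#'   `feature_weights`, and `noise_variances`.
#' @export
coef.mogplvm <- function(object, ...) {
  vnames <- object$view_names
  fe <- lapply(object$params$views, `[[`, "B")
  names(fe) <- vnames
  list(
    cell_embedding = object$params$A,
    feature_embeddings = fe,
    ard_weights = ard_weights(object),
    kernel_variances = stats::setNames(vapply(object$params$views,
      function(vp) exp(vp$logvA) * exp(vp$logvB), 0), vnames),
    feature_weights = stats::setNames(lapply(object$params$views,
      function(vp) exp(vp$logwB)), vnames),
    noise_variances = stats::setNames(vapply(object$params$views,
      function(vp) exp(vp$lognoise), 0), vnames)
  )
}

#' Learned cell-kernel ARD weights per view
#'
#' The per-view ARD weight of each cell-embedding dimension; large weights
#' mark dimensions the view actually uses, near-zero weights mark dimensions
#' the view ignores. This is the quantity the shared/private/absent
#' partition is computed from.
#'
#' @param object A `"mogplvm"` object.
#' @return `r_cells x V` matrix of nonnegative weights, one column per view.
#' @export
ard_weights <- function(object) {
  W <- vapply(object$params$views, function(vp) exp(vp$logwA),
              numeric(object$config$r_cells))
  W <- matrix(W, nrow = object$config$r_cells)
  colnames(W) <- object$view_names
  rownames(W) <- paste0("dim", seq_len(nrow(W)))
  W
}

#' @export
print.mogplvm <- function(x, ...) {
  V <- length(x$params$views)
  cat("Multi-output GP-LVM (", V, if (V == 1) " view" else " views", ")\n",
      sep = "")
  cat("  cells: ", nrow(x$params$A), ", cell-embedding dim: ",
      ncol(x$params$A), ", inducing points: ", length(x$inducing$cells),
      "\n", sep = "")
  for (v in seq_len(V)) {
    vp <- x$params$views[[v]]
    cat("  view '", x$view_names[v], "': ", nrow(vp$B), " features, dim ",
        ncol(vp$B), ", noise variance ", sprintf("%.4g", exp(vp$lognoise)),
        "\n", sep = "")
  }
  if (length(x$trace))
    cat("  final ELBO: ", sprintf("%.4f", utils::tail(x$trace, 1)), " after ",
        length(x$trace), " epochs\n", sep = "")
  invisible(x)
}

#' @export
summary.mogplvm <- function(object, delta = NULL, ...) {
  W <- ard_weights(object)
  part <- partition_dimensions(W, delta = delta)
  out <- list(model = object, ard = W, partition = part,
              final_elbo = if (length(object$trace))
                utils::tail(object$trace, 1) else NA_real_)
  class(out) <- "summary.mogplvm"
  out
}

#' @export
print.summary.mogplvm <- function(x, ...) {
  print(x$model)
  cat("\nARD weights of the shared cell embedding:\n")
  print(round(x$ard, 4))
  cat("\n")
  print(x$partition)
  invisible(x)
}

#' @export
plot.mogplvm <- function(x, type = c("cells", "features"), view = 1,
                         labels = NULL, dims = c(1, 2), ...) {
  type <- match.arg(type)
  E <- if (type == "cells") x$params$A
       else x$params$views[[.resolve_view(x, view)]]$B
  if (ncol(E) == 1L) E <- cbind(E, 0)
  dims <- dims[dims <= ncol(E)]
  if (length(dims) < 2) dims <- c(1, 2)
  col <- "grey30"
  if (!is.null(labels)) {
    f <- factor(labels)
    col <- grDevices::hcl.colors(nlevels(f), "Dark 3")[as.integer(f)]
  }
  graphics::plot(E[, dims[1]], E[, dims[2]], col = col, pch = 16,
                 cex = 0.7, xlab = paste0("latent dim ", dims[1]),
                 ylab = paste0("latent dim ", dims[2]),
                 main = paste0(type, " embedding"), ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = grDevices::hcl.colors(nlevels(factor(labels)),
                                                 "Dark 3"),
                     pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}

# ---- MRD dimension partition ------------------------------------------------

#' Partition latent dimensions into shared / private / absent
#'
#' A dimension of the shared cell embedding is *shared* when at least two
#' views' ARD weights exceed the threshold `delta` (for two views: both),
#' *private* to a view when only that view's weight exceeds `delta`, and
#' *absent* when no view uses it.
#'
#' @param w A `r x V` matrix of nonnegative ARD weights (as from
#'   [ard_weights()]) or a list of equal-length weight vectors.
#' @param delta Positive threshold "close to zero". Default: 5% of the
#'   largest weight over all views and dimensions (a relative default, since
#'   ARD weights are unnormalized).
#' @return An object of class `"dim_partition"`: list with integer vectors
#'   `shared`, `absent`, named list `private`, character vector `labels`
#'   (one per dimension) and the `delta` used.
#' @examples
#' partition_dimensions(cbind(v1 = c(0.9, 0, 0.5), v2 = c(0, 0.8, 0.6)),
#'                      delta = 0.01)
#' @export
partition_dimensions <- function(w, delta = NULL) {
  if (is.list(w) && !is.data.frame(w)) {
    lens <- lengths(w)
    if (length(unique(lens)) != 1) stop("weight vectors must share a length")
    w <- do.call(cbind, w)
  }
  w <- as.matrix(w)
  if (any(w < 0)) stop("ARD weights must be nonnegative")
  if (is.null(delta)) delta <- 0.05 * max(w, 1e-12)
  if (delta <= 0) stop("delta must be positive")
  V <- ncol(w)
  if (is.null(colnames(w))) colnames(w) <- paste0("view", seq_len(V))
  above <- w > delta
  nab <- rowSums(above)
  labels <- character(nrow(w))
  labels[nab == 0] <- "absent"
  labels[nab >= 2] <- "shared"
  for (d in which(nab == 1))
    labels[d] <- paste0("private:", colnames(w)[which(above[d, ])])
  private <- lapply(seq_len(V), function(v)
    which(above[, v] & nab == 1))
  names(private) <- colnames(w)
  structure(list(shared = which(nab >= 2), private = private,
                 absent = which(nab == 0), labels = labels,
                 delta = delta, weights = w),
            class = "dim_partition")
}

#' @export
print.dim_partition <- function(x, ...) {
  cat("Latent-dimension partition (delta = ", format(x$delta, digits = 4),
      ")\n", sep = "")
  for (d in seq_along(x$labels))
    cat(sprintf("  dim %d: %-16s [%s]\n", d, x$labels[d],
                paste(sprintf("%.3g", x$weights[d, ]), collapse = ", ")))
  invisible(x)
}

#' ARD weight report
#'
#' Tabulates the per-view ARD weights of every cell-embedding dimension with
#' its shared/private/absent label, optionally writing a TSV.
#'
#' @param object A `"mogplvm"` object.
#' @param file Optional TSV path to write.
#' @param delta Threshold passed to [partition_dimensions()].
#' @return A data.frame with one row per dimension, one weight column per
#'   view, and a `label` column.
#' @export
export_ard_report <- function(object, file = NULL, delta = NULL) {
  W <- ard_weights(object)
  part <- partition_dimensions(W, delta = delta)
  df <- data.frame(dimension = seq_len(nrow(W)), W, label = part$labels,
                   check.names = FALSE)
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

# ---- checkpoints ------------------------------------------------------------

#' Write a model checkpoint
#'
#' Serializes a fitted model as plain text: `cell_embedding.tsv`, a
#' `model.json` of scalars and variational state, per-view subdirectories
#' with `feature_embedding.tsv`, plus `ard_weights.tsv` and `partition.json`.
#'
#' @param object A `"mogplvm"` object.
#' @param dir Output directory (created if needed).
#' @param delta Partition threshold (see [partition_dimensions()]).
#' @return `dir`, invisibly.
#' @export
write_checkpoint <- function(object, dir, delta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  A <- object$params$A
  cell_ids <- if (!is.null(object$views)) object$views[[1]]$cell_ids
              else paste0("cell_", seq_len(nrow(A)))
  dfA <- data.frame(cell_id = cell_ids, A)
  names(dfA)[-1] <- paste0("dim", seq_len(ncol(A)))
  utils::write.table(dfA, file.path(dir, "cell_embedding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scal <- list(view_names = object$view_names, config = object$config,
               inducing_cells = object$inducing$cells,
               trace = object$trace, views = list())
  for (v in seq_along(object$params$views)) {
    vp <- object$params$views[[v]]
    vdir <- file.path(dir, object$view_names[v])
    dir.create(vdir, showWarnings = FALSE)
    fid <- if (!is.null(object$views)) object$views[[v]]$feature_ids
           else paste0("feat_", seq_len(nrow(vp$B)))
    dfB <- data.frame(feature_id = fid, vp$B)
    names(dfB)[-1] <- paste0("dim", seq_len(ncol(vp$B)))
    utils::write.table(dfB, file.path(vdir, "feature_embedding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scal$views[[object$view_names[v]]] <- list(
      logwA = vp$logwA, logvA = vp$logvA, logwB = vp$logwB, logvB = vp$logvB,
      lognoise = vp$lognoise, q_mu = vp$q_mu,
      Lq_raw = as.vector(vp$Lq_raw),
      inducing_features = object$inducing$features[[v]])
  }
  jsonlite::write_json(scal, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(export_ard_report(object, delta = delta),
                     file.path(dir, "ard_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  part <- partition_dimensions(ard_weights(object), delta = delta)
  jsonlite::write_json(list(shared = part$shared, private = part$private,
                            absent = part$absent, labels = part$labels,
                            delta = part$delta),
                       file.path(dir, "partition.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a model checkpoint
#'
#' @param dir Directory written by [write_checkpoint()].
#' @return A `"mogplvm"` object (without attached training data).
#' @export
read_checkpoint <- function(dir) {
  scal <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  dfA <- utils::read.table(file.path(dir, "cell_embedding.tsv"), sep = "\t",
                           header = TRUE)
  A <- as.matrix(dfA[, -1, drop = FALSE])
  vnames <- scal$view_names
  m <- length(scal$inducing_cells)
  views <- list(); indf <- list()
  for (v in seq_along(vnames)) {
    sv <- if (is.data.frame(scal$views)) as.list(scal$views[v, ])
          else scal$views[[vnames[v]]]
    dfB <- utils::read.table(file.path(dir, vnames[v],
                                       "feature_embedding.tsv"),
                             sep = "\t", header = TRUE)
    views[[v]] <- list(B = as.matrix(dfB[, -1, drop = FALSE]),
                       logwA = as.numeric(sv$logwA),
                       logvA = as.numeric(sv$logvA),
                       logwB = as.numeric(sv$logwB),
                       logvB = as.numeric(sv$logvB),
                       q_mu = as.numeric(sv$q_mu),
                       Lq_raw = matrix(as.numeric(sv$Lq_raw), m, m),
                       lognoise = as.numeric(sv$lognoise))
    indf[[v]] <- as.integer(sv$inducing_features)
  }
  structure(list(params = list(A = A, views = views),
                 inducing = list(cells = as.integer(scal$inducing_cells),
                                 features = indf),
                 views = NULL, stores = NULL,
                 trace = as.numeric(scal$trace),
                 config = scal$config, view_names = vnames),
            class = "mogplvm")
}
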