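# Forward sampler from the model's own generative process, plus a structured
# marker-block toy. Everything here is reproducible from the config seed and
# needs no external data.

#' Simulation configuration
#'
#' Describes a matched multi-view dataset drawn from the model's generative
#' process: cluster-structured cell latents, block-structured feature latents
#' per view, a per-view activity pattern over cell-latent dimensions (which
#' drives the shared/private ground truth), a GP draw per view with the
#' coregionalization kernel, and additive Gaussian observation noise.
#'
#' Cluster (and block) centers sit on a scaled simplex in latent space, the
#' maximal-separation arrangement at a given dimension; the default spread is
#' 0.15 of the center-to-center distance, chosen so that recovery is
#' nontrivial but solvable for a model that works.
#'
#' @param n_cells Number of cells I.
#' @param n_features Integer vector, features per view (names become view
#'   names).
#' @param r_cells,r_features Latent dimensions of the cell embedding and of
#'   each view's feature embedding (`r_features` recycled per view).
#' @param n_cell_clusters Number of cell clusters.
#' @param n_feature_blocks Feature blocks per view (recycled).
#' @param cluster_spread,block_spread Within-cluster/block standard deviation
#'   as a fraction of the center separation.
#' @param activity Optional 0/1 matrix (`V x r_cells`): which cell-latent
#'   dimensions each view uses. Default: all active. A dimension active in
#'   >= 2 views is shared ground truth, in exactly one view private, in none
#'   absent.
#' @param ard_weight ARD weight of active cell-latent dimensions.
#' @param feature_weight RBF weight of the feature kernels.
#' @param kernel_variance Amplitude of each view's product kernel.
#' @param noise_variance Observation noise variance per view (recycled).
#' @param center_scale Distance scale of the latent cluster centers.
#' @param seed Integer seed.
#' @param method `"auto"` (exact below `guard` triples, else low rank),
#'   `"exact"`, or `"lowrank"`.
#' @param n_inducing Inducing points for low-rank sampling.
#' @param guard Maximum I*J for exact Kronecker sampling.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 300, n_features = c(rna = 40),
                       r_cells = 2, r_features = 2,
                       n_cell_clusters = 3, n_feature_blocks = 3,
                       cluster_spread = 0.15, block_spread = 0.15,
                       activity = NULL, ard_weight = 1, feature_weight = 1,
                       kernel_variance = 1, noise_variance = 0.1,
                       center_scale = 2, seed = 1,
                       method = c("auto", "exact", "lowrank"),
                       n_inducing = 64, guard = 2500) {
  V <- length(n_features)
  if (is.null(names(n_features)))
    names(n_features) <- paste0("view", seq_len(V))
  if (is.null(activity)) activity <- matrix(1, V, r_cells)
  activity <- matrix(as.numeric(activity), V, r_cells)
  stopifnot(n_cells >= 1, all(n_features >= 1), n_cell_clusters >= 1,
            all(n_feature_blocks >= 1), ncol(activity) == r_cells)
  structure(list(n_cells = n_cells, n_features = n_features,
                 r_cells = r_cells,
                 r_features = rep_len(r_features, V),
                 n_cell_clusters = n_cell_clusters,
                 n_feature_blocks = rep_len(n_feature_blocks, V),
                 cluster_spread = cluster_spread, block_spread = block_spread,
                 activity = activity, ard_weight = ard_weight,
                 feature_weight = feature_weight,
                 kernel_variance = kernel_variance,
                 noise_variance = rep_len(noise_variance, V),
                 center_scale = center_scale, seed = seed,
                 method = match.arg(method), n_inducing = n_inducing,
                 guard = guard),
            class = "sim_config")
}

# k maximally separated centers in r dimensions: a regular simplex when
# r >= k - 1, otherwise points spread on the unit sphere.
.simplex_centers <- function(k, r, scale) {
  if (k == 1) return(matrix(0, 1, r))
  if (r >= k - 1) {
    E <- diag(k)
    E <- E - matrix(colMeans(E), k, k, byrow = TRUE)
    E <- E %*% svd(E)$v[, seq_len(k - 1), drop = FALSE]
    C <- cbind(E, matrix(0, k, r - (k - 1)))
  } else {
    C <- matrix(stats::rnorm(k * r), k, r)
  }
  C <- C / sqrt(rowSums(C^2))
  # unit-norm rows; rescale so nearest-neighbor center distance ~ scale
  d <- as.matrix(stats::dist(C))
  diag(d) <- Inf
  C * (scale / min(d))
}

#' Simulate matched multi-view data from the generative model
#'
#' Draws cell latents from a Gaussian-cluster mixture, per-view feature
#' latents from a block mixture, then per view a GP function value for every
#' (cell, feature) pair under the coregionalization kernel (the cell kernel
#' uses the view's activity-masked ARD weights) and adds Gaussian noise.
#' Exact Kronecker sampling is used for small grids; above the guard, a
#' low-rank draw through the matched-inducing-point construction (sample
#' u ~ N(0, K_uu), condition, add the residual marginal variance) keeps the
#' sampler inside the model family.
#'
#' @param config A [sim_config()].
#' @return List with `views` (list of [view_matrix()]) and `truth`: cell
#'   latents and cluster labels, per-view feature latents and block labels,
#'   per-view noiseless matrices `F`, and `dim_labels`
#'   (shared/private/absent per cell-latent dimension).
#' @export
simulate_views <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  V <- length(cf$n_features)
  .with_seed(cf$seed, {
    I <- cf$n_cells; r1 <- cf$r_cells
    centers <- .simplex_centers(cf$n_cell_clusters, r1, cf$center_scale)
    clusters <- sort(rep_len(seq_len(cf$n_cell_clusters), I))
    spread <- cf$cluster_spread * cf$center_scale
    A <- centers[clusters, , drop = FALSE] +
      matrix(stats::rnorm(I * r1, sd = spread), I, r1)

    views <- vector("list", V)
    truth_feats <- vector("list", V)
    truth_blocks <- vector("list", V)
    Fs <- vector("list", V)
    for (v in seq_len(V)) {
      J <- cf$n_features[v]; r2 <- cf$r_features[v]
      bcent <- .simplex_centers(cf$n_feature_blocks[v], r2, cf$center_scale)
      blocks <- sort(rep_len(seq_len(cf$n_feature_blocks[v]), J))
      B <- bcent[blocks, , drop = FALSE] +
        matrix(stats::rnorm(J * r2, sd = cf$block_spread * cf$center_scale),
               J, r2)
      wA <- cf$ard_weight * cf$activity[v, ]
      kA <- ard_kernel(cf$kernel_variance, wA)
      kB <- ard_kernel(1, rep(cf$feature_weight, r2))
      n <- as.double(I) * J
      method <- cf$method
      if (method == "auto") method <- if (n <= cf$guard) "exact" else "lowrank"
      if (method == "exact" && n > cf$guard)
        stop("exact sampling requested for ", n, " triples (guard = ",
             cf$guard, "); use method = 'lowrank'")
      Fv <- if (method == "exact") {
        KA <- ard_rbf(A, NULL, kA)
        KB <- ard_rbf(B, NULL, kB)
        K <- coreg_kernel_full(KA, KB, guard = cf$guard)
        diag(K) <- diag(K) + 1e-8
        f <- drop(t(chol(K)) %*% stats::rnorm(n))
        matrix(f, I, J, byrow = TRUE)   # cell-major vectorization
      } else {
        .lowrank_gp_draw(A, B, kA, kB, cf$n_inducing)
      }
      Y <- Fv + matrix(stats::rnorm(I * J, sd = sqrt(cf$noise_variance[v])),
                       I, J)
      views[[v]] <- view_matrix(Y,
        cell_ids = paste0("cell_", seq_len(I)),
        feature_ids = paste0(names(cf$n_features)[v], "_feat_", seq_len(J)),
        view_name = names(cf$n_features)[v])
      truth_feats[[v]] <- B
      truth_blocks[[v]] <- blocks
      Fs[[v]] <- Fv
    }
    nactive <- colSums(cf$activity > 0)
    dim_labels <- ifelse(nactive >= 2, "shared",
                         ifelse(nactive == 0, "absent",
                                paste0("private:",
                                       names(cf$n_features)[
                                         apply(cf$activity > 0, 2, which.max)])))
    names(truth_feats) <- names(truth_blocks) <- names(Fs) <- names(cf$n_features)
    list(views = views,
         truth = list(cell_latents = A, cell_clusters = clusters,
                      feature_latents = truth_feats,
                      feature_blocks = truth_blocks,
                      F = Fs, dim_labels = dim_labels,
                      config = cf))
  })
}

# Low-rank GP draw via matched inducing pairs: u ~ N(0, Kuu), conditional
# mean through Kfu Kuu^-1 u, independent residual with the exact marginal
# conditional variance.
.lowrank_gp_draw <- function(A, B, kA, kB, m) {
  I <- nrow(A); J <- nrow(B)
  m <- min(m, I, J)
  zc <- sample.int(I, m); zf <- sample.int(J, m)
  Au <- A[zc, , drop = FALSE]; Bu <- B[zf, , drop = FALSE]
  kff <- kA$variance * kB$variance
  Kuu <- .kuu_hadamard(ard_rbf(Au, NULL, kA), ard_rbf(Bu, NULL, kB),
                       1e-6 * kff)
  R <- chol(Kuu)
  u <- drop(t(R) %*% stats::rnorm(m))
  w <- backsolve(R, forwardsolve(t(R), u))
  KAc <- ard_rbf(Au, A, kA)               # m x I
  KBc <- ard_rbf(Bu, B, kB)               # m x J
  Fm <- crossprod(KAc, (KBc * w))         # I x J conditional mean
  # residual marginal variance per pair
  Vr <- matrix(0, I, J)
  Q <- chol2inv(R)
  for (ci in seq_len(I)) {
    Kt <- KAc[, ci] * KBc
    Vr[ci, ] <- pmax(kff - colSums(Kt * (Q %*% Kt)), 0)
  }
  Fm + matrix(stats::rnorm(I * J), I, J) * sqrt(Vr)
}

#' Marker-block toy dataset
#'
#' A small single-view dataset with planted structure: for each of
#' `n_types` cell types, a block of `markers_per_type` marker features is
#' elevated by `effect` in that type's cells; `n_noise_features` additional
#' features carry no signal (the "unknown"-class analogue of unlabeled
#' genes). Everything else is independent Gaussian noise.
#'
#' @param n_types Number of cell types.
#' @param markers_per_type Marker features per type.
#' @param cells_per_type Cells per type.
#' @param n_noise_features Unstructured features (default
#'   `markers_per_type`).
#' @param effect Elevation of a marker block within its own type.
#' @param noise_sd Standard deviation of the background noise.
#' @param seed Integer seed.
#' @return List with `view` (a [view_matrix()]), `labels` (data.frame
#'   `cell_id`, `cell_type`), and `markers` (named list: cell type ->
#'   character vector of its marker feature ids).
#' @export
make_marker_toy <- function(n_types = 3, markers_per_type = 10,
                            cells_per_type = 50,
                            n_noise_features = markers_per_type,
                            effect = 2, noise_sd = 0.5, seed = 1) {
  stopifnot(n_types >= 1, markers_per_type >= 1, cells_per_type >= 1)
  .with_seed(seed, {
    I <- n_types * cells_per_type
    J <- n_types * markers_per_type + n_noise_features
    Y <- matrix(stats::rnorm(I * J, sd = noise_sd), I, J)
    types <- rep(paste0("type_", seq_len(n_types)), each = cells_per_type)
    fid <- c(unlist(lapply(seq_len(n_types), function(t)
      paste0("type_", t, "_marker_", seq_len(markers_per_type)))),
      if (n_noise_features > 0) paste0("noise_", seq_len(n_noise_features)))
    markers <- list()
    for (t in seq_len(n_types)) {
      rows <- which(types == paste0("type_", t))
      cols <- (t - 1) * markers_per_type + seq_len(markers_per_type)
      Y[rows, cols] <- Y[rows, cols] + effect
      markers[[paste0("type_", t)]] <- fid[cols]
    }
    view <- view_matrix(Y, cell_ids = paste0("cell_", seq_len(I)),
                        feature_ids = fid, view_name = "toy")
    labels <- data.frame(cell_id = view$cell_ids, cell_type = types,
                         stringsAsFactors = FALSE)
    list(view = view, labels = labels, markers = markers)
  })
}
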