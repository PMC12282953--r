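# Interpretation layer: metagenes from the feature embedding, gradient-based
# relevance maps over the cell embedding, and threshold linking of feature
# groups to cell groups — all without clustering cells first.

#' Cluster the feature embedding into metagenes
#'
#' Groups features with nearby coordinates in the learned feature embedding
#' into metagenes using a Gaussian mixture. When `G` is `NULL` the number of
#' metagenes is chosen by BIC over `G = 2..15`.
#'
#' @param x A fitted `"mogplvm"` (uses the chosen view's feature embedding)
#'   or a numeric feature-latent matrix.
#' @param G Number of metagenes, or `NULL` for BIC selection.
#' @param view View index or name when `x` is a model.
#' @param seed Integer seed (the mixture fit is deterministic given data;
#'   kept for provenance).
#' @return Object of class `"metagene_assignment"`: integer `assignment`
#'   (one metagene id per feature), `G`, `method` metadata, and the feature
#'   ids when available.
#' @export
cluster_features <- function(x, G = NULL, view = 1, seed = 1) {
  if (inherits(x, "mogplvm")) {
    v <- .resolve_view(x, view)
    emb <- x$params$views[[v]]$B
    fid <- if (!is.null(x$views)) x$views[[v]]$feature_ids else NULL
  } else {
    emb <- as.matrix(x)
    fid <- rownames(emb)
  }
  J <- nrow(emb)
  if (!is.null(G) && G > J)
    stop("G (", G, ") exceeds the number of features (", J, ")")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  assignment <- .with_seed(seed, {
    if (!is.null(G) && G == 1L) rep(1L, J)
    else {
      Gs <- if (is.null(G)) 2:min(15, J) else G
      fit <- mclust::Mclust(emb, G = Gs, verbose = FALSE)
      if (is.null(fit)) stop("Gaussian mixture fit failed on the feature embedding")
      as.integer(fit$classification)
    }
  })
  structure(list(assignment = assignment,
                 G = length(unique(assignment)),
                 feature_ids = fid,
                 method = list(algorithm = "gmm",
                               G_requested = G %||% "BIC 2..15",
                               seed = seed)),
            class = "metagene_assignment")
}

#' @export
print.metagene_assignment <- function(x, ...) {
  cat("<metagene_assignment> ", length(x$assignment), " features in ",
      x$G, " metagenes\n", sep = "")
  print(table(metagene = x$assignment))
  invisible(x)
}

# Gradient of the posterior mean wrt a cell latent coordinate, for a set of
# evaluation cells and features of one view. Returns the n_cells x n_feats
# matrix of gradient L2 norms.
.relevance_grad_norm <- function(post, eval_cells, features) {
  A <- post$A
  Ae <- A[eval_cells, , drop = FALSE]
  KAc <- ard_rbf(post$Au, Ae, post$kA)                  # m x ne
  KBc <- ard_rbf(post$Bu, post$vp$B[features, , drop = FALSE], post$kB)
  H <- KBc * post$alpha                                 # m x nf
  wA <- post$kA$weights
  sq <- matrix(0, length(eval_cells), length(features))
  for (r in seq_along(wA)) {
    if (wA[r] == 0) next
    # d mu_ij / d a_i^r = sum_u alpha_u KB[u,j] * KA[u,i] * w_r (Au[u,r] - a_i^r)
    Gr <- KAc * (wA[r] * outer(post$Au[, r], Ae[, r], "-"))   # m x ne
    sq <- sq + crossprod(Gr, H)^2
  }
  sqrt(sq)
}

#' Relevance of a feature set across cells
#'
#' The local relevance of a feature set at a cell is the mean, over the
#' features in the set, of the L2 norm of the gradient of the GP posterior
#' mean prediction with respect to that cell's latent coordinate. It is
#' large where the predicted values of those features change fastest across
#' the cell embedding — the regions the feature set "drives". Scores are
#' scaled so the maximum over the evaluated cells is 100.
#'
#' @param object A fitted `"mogplvm"`.
#' @param features Integer indices (or feature-id strings) of the feature
#'   set within the view.
#' @param cells Integer cell indices to evaluate (default all cells).
#' @param view View index or name.
#' @param scale Scale the scores to max 100 (default `TRUE`; `FALSE` returns
#'   raw gradient norms).
#' @return Numeric vector of per-cell relevance scores.
#' @export
feature_relevance <- function(object, features, cells = NULL, view = 1,
                              scale = TRUE) {
  v <- .resolve_view(object, view)
  post <- .view_posterior(object, v)
  J <- nrow(post$vp$B)
  if (is.character(features)) {
    if (is.null(object$views)) stop("feature ids need attached data")
    features <- match(features, object$views[[v]]$feature_ids)
    if (anyNA(features)) stop("unknown feature id(s)")
  }
  features <- as.integer(features)
  if (length(features) == 0) stop("empty feature set")
  if (any(features < 1 | features > J)) stop("feature index out of range")
  cells <- if (is.null(cells)) seq_len(nrow(post$A)) else as.integer(cells)
  gn <- .relevance_grad_norm(post, cells, features)
  rel <- rowMeans(gn)
  if (scale) {
    mx <- max(rel)
    if (mx > 0) rel <- 100 * rel / mx
  }
  rel
}

#' Relevance map: cells x metagenes
#'
#' Computes the per-cell relevance of every metagene (each scaled to a
#' maximum of 100 over the evaluated cells) and stores the linking threshold
#' tau used downstream.
#'
#' @param object A fitted `"mogplvm"`.
#' @param metagenes A [cluster_features()] assignment, or a named list of
#'   feature index/id vectors (e.g. planted marker sets).
#' @param cells Cell indices to evaluate (default all).
#' @param view View index or name.
#' @param tau Default linking threshold on the 0-100 scale (default 30:
#'   cells above 30% of the metagene's peak relevance).
#' @return Object of class `"relevance_map"`: `scores` (cells x metagenes),
#'   `tau`, `view`, `cells`.
#' @export
relevance_map <- function(object, metagenes, cells = NULL, view = 1,
                          tau = 30) {
  v <- .resolve_view(object, view)
  sets <- if (inherits(metagenes, "metagene_assignment")) {
    split(seq_along(metagenes$assignment), metagenes$assignment)
  } else if (is.list(metagenes)) metagenes
  else stop("metagenes must be a metagene_assignment or a list of feature sets")
  if (is.null(names(sets))) names(sets) <- seq_along(sets)
  cells <- if (is.null(cells)) seq_len(nrow(object$params$A))
           else as.integer(cells)
  scores <- vapply(sets, function(fs)
    feature_relevance(object, fs, cells = cells, view = v, scale = TRUE),
    numeric(length(cells)))
  scores <- matrix(scores, nrow = length(cells),
                   dimnames = list(NULL, names(sets)))
  structure(list(scores = scores, tau = tau, view = v, cells = cells),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("<relevance_map> ", nrow(x$scores), " cells x ", ncol(x$scores),
      " metagenes (tau = ", x$tau, ")\n", sep = "")
  invisible(x)
}

#' Cells linked to a metagene
#'
#' The cells whose relevance score for a metagene exceeds the threshold tau
#' (on the 0-100 per-metagene scale).
#'
#' @param relevance A [relevance_map()].
#' @param metagene Metagene id (column name or index).
#' @param tau Threshold in `[0, 100]`; default the map's stored tau.
#' @return Integer vector of cell indices (into the evaluated cells).
#' @export
link_metagene_to_cells <- function(relevance, metagene, tau = NULL) {
  stopifnot(inherits(relevance, "relevance_map"))
  tau <- tau %||% relevance$tau
  if (tau < 0 || tau > 100) stop("tau must lie in [0, 100]")
  sc <- relevance$scores
  cn <- colnames(sc)
  idx <- if (is.character(metagene)) match(metagene, cn)
         else if (metagene >= 1 && metagene <= ncol(sc)) as.integer(metagene)
         else NA_integer_
  if (is.na(idx)) stop("unknown metagene id '", metagene, "'")
  relevance$cells[sc[, idx] > tau]
}

#' Majority cell type of a cell set
#'
#' Modal label among a set of cells and its percentage (ties broken
#' lexicographically).
#'
#' @param cells Integer cell indices.
#' @param labels Cell-type labels: character vector aligned with all cells,
#'   or a labels data.frame plus `cell_ids`.
#' @param cell_ids Optional cell ids aligning a labels data.frame.
#' @return List with `cell_type` and `coverage` (percentage).
#' @export
majority_celltype <- function(cells, labels, cell_ids = NULL) {
  if (length(cells) == 0) stop("empty cell set")
  lab <- if (is.data.frame(labels)) {
    if (is.null(cell_ids)) stop("cell_ids needed to align a labels data.frame")
    .align_labels(labels, cell_ids)
  } else as.character(labels)
  tab <- table(lab[cells])
  list(cell_type = names(tab)[which.max(tab)],
       coverage = round(100 * max(tab) / sum(tab), 2))
}

#' Marker-set enrichment of a metagene (over-representation test)
#'
#' For each cell type's marker set, reports (i) the coverage: the percentage
#' of the metagene's marker-labeled features that belong to that type's set,
#' and (ii) a hypergeometric upper-tail p-value for the overlap between the
#' metagene and the marker set given the feature universe (the standard
#' over-representation analysis).
#'
#' @param metagene_features Character/integer vector: the metagene's
#'   features.
#' @param marker_sets Named list, cell type -> marker feature vector; every
#'   marker must be in `universe`.
#' @param universe All features under consideration.
#' @return data.frame with columns `cell_type`, `n_overlap`, `coverage_pct`,
#'   `p_value`, sorted by p-value.
#' @export
metagene_enrichment <- function(metagene_features, marker_sets, universe) {
  if (length(universe) == 0) stop("empty feature universe")
  universe <- unique(universe)
  metagene_features <- intersect(unique(metagene_features), universe)
  bad <- !vapply(marker_sets, function(s) all(s %in% universe), TRUE)
  if (any(bad)) stop("marker set(s) not contained in the universe: ",
                     paste(names(marker_sets)[bad], collapse = ", "))
  labeled <- metagene_features[metagene_features %in% unlist(marker_sets)]
  N <- length(universe)
  g <- length(metagene_features)
  rows <- lapply(names(marker_sets), function(ct) {
    K <- length(unique(marker_sets[[ct]]))
    ov <- length(intersect(metagene_features, marker_sets[[ct]]))
    cov <- if (length(labeled)) 100 *
      length(intersect(labeled, marker_sets[[ct]])) / length(labeled) else 0
    p <- stats::phyper(ov - 1, K, N - K, g, lower.tail = FALSE)
    data.frame(cell_type = ct, n_overlap = ov,
               coverage_pct = round(cov, 2), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}
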