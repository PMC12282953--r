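# Embedding-quality metrics: unsupervised clustering of an embedding, modal-
# label clustering accuracy, and the adjusted Rand index.

#' Cluster an embedding
#'
#' Unsupervised clustering of embedded points with a Gaussian mixture (full
#' covariances, the default reporting choice) or k-means, with k set to the
#' number of expected groups (typically the number of cell types).
#'
#' @param embedding Numeric matrix, one row per entity.
#' @param k Number of clusters (`k <= nrow(embedding)`).
#' @param algorithm `"gmm"` or `"kmeans"`.
#' @param seed Integer seed (k-means starts; the GMM fit is deterministic
#'   given the data).
#' @return Object of class `"clustering_result"`: list with integer
#'   `assignment`, `k`, `algorithm`, `seed`.
#' @export
cluster_embedding <- function(embedding, k, algorithm = c("gmm", "kmeans"),
                              seed = 1) {
  algorithm <- match.arg(algorithm)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k > n) stop("k (", k, ") exceeds the number of entities (", n, ")")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  assignment <- .with_seed(seed, {
    if (k == 1L) rep(1L, n)
    else if (algorithm == "gmm") {
      fit <- mclust::Mclust(embedding, G = k, modelNames = "VVV",
                            verbose = FALSE)
      if (is.null(fit))   # degenerate data: fall back to a simpler covariance
        fit <- mclust::Mclust(embedding, G = k, verbose = FALSE)
      as.integer(fit$classification)
    } else {
      as.integer(stats::kmeans(embedding, centers = k, nstart = 10)$cluster)
    }
  })
  structure(list(assignment = assignment, k = as.integer(k),
                 algorithm = algorithm, seed = seed),
            class = "clustering_result")
}

.as_assignment <- function(clusters) {
  if (inherits(clusters, "clustering_result")) clusters$assignment
  else as.integer(factor(clusters))
}

#' Clustering accuracy by modal-label assignment
#'
#' Each cluster predicts the most frequent true label among its members
#' (ties broken lexicographically); ACC is the percentage of entities whose
#' predicted label equals their true label. Two clusters may predict the
#' same label — the assignment is independent per cluster, not one-to-one.
#'
#' @param clusters A [cluster_embedding()] result or an assignment vector.
#' @param labels True labels: character vector aligned with the entities, or
#'   a labels data.frame plus `cell_ids`.
#' @param cell_ids Optional cell ids used to align a labels data.frame.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
clustering_accuracy <- function(clusters, labels, cell_ids = NULL) {
  a <- .as_assignment(clusters)
  lab <- if (is.data.frame(labels)) {
    if (is.null(cell_ids)) stop("cell_ids needed to align a labels data.frame")
    .align_labels(labels, cell_ids)
  } else .align_labels(labels, cell_ids %||% seq_along(a))
  if (length(lab) != length(a))
    stop("labels cover ", length(lab), " entities but clustering has ",
         length(a))
  pred <- character(length(a))
  for (cl in unique(a)) {
    members <- a == cl
    tab <- table(lab[members])
    # which.max on a table takes the first maximum; names are sorted, so
    # ties break lexicographically
    pred[members] <- names(tab)[which.max(tab)]
  }
  100 * mean(pred == lab)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted for chance under
#' the permutation model: 1 for identical partitions, about 0 for unrelated
#' ones (a single all-in-one cluster scores 0 against anything).
#'
#' @param clusters First partition ([cluster_embedding()] result or vector).
#' @param labels Second partition (any vector coercible to a factor).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(clusters, labels) {
  a <- .as_assignment(clusters)
  b <- as.integer(factor(labels))
  if (length(a) != length(b))
    stop("partitions have different sizes (", length(a), " vs ", length(b), ")")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Evaluate an embedding against cell-type labels
#'
#' Convenience wrapper: cluster the embedding with k = number of distinct
#' labels, then report ACC and ARI.
#'
#' @inheritParams cluster_embedding
#' @param labels True labels aligned with the embedding rows.
#' @param k Number of clusters; default the number of distinct labels.
#' @return List of class `"metric_report"`: `acc`, `ari`, `k`, `algorithm`,
#'   `seed`, and the clustering.
#' @export
evaluate_embedding <- function(embedding, labels, k = NULL,
                               algorithm = c("gmm", "kmeans"), seed = 1) {
  algorithm <- match.arg(algorithm)
  lab <- .align_labels(labels, seq_len(nrow(as.matrix(embedding))))
  if (is.null(k)) k <- length(unique(lab))
  cl <- cluster_embedding(embedding, k = k, algorithm = algorithm,
                          seed = seed)
  structure(list(acc = clustering_accuracy(cl, lab),
                 ari = adjusted_rand_index(cl, lab),
                 k = k, algorithm = algorithm, seed = seed, clustering = cl),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  ARI %.4f  (k = %d, %s)\n", x$acc, x$ari, x$k,
              x$algorithm))
  invisible(x)
}
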