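test_that("cluster_features recovers separated blocks and respects G", {
  set.seed(12)
  B <- rbind(matrix(rnorm(30, 0, 0.3), 15), matrix(rnorm(30, 5, 0.3), 15))
  mg <- cluster_features(B, G = 2, seed = 1)
  expect_equal(adjusted_rand_index(mg$assignment, rep(1:2, each = 15)), 1)
  mg2 <- cluster_features(B, G = 2, seed = 1)
  expect_identical(mg$assignment, mg2$assignment)
  expect_equal(cluster_features(B, G = 1)$assignment, rep(1L, 30))
  expect_error(cluster_features(B, G = 50), "exceeds")
  # BIC default finds the two blocks as well
  mg3 <- cluster_features(B, seed = 1)
  expect_equal(adjusted_rand_index(mg3$assignment, rep(1:2, each = 15)), 1)
})

test_that("relevance is zero for a constant-prediction model", {
  model <- tiny_model(I = 5, J = 4, m = 3, seed = 3)
  # a flat posterior mean (q_mu = 0 => mu identically 0) has zero gradient
  model$params$views[[1]]$q_mu <- rep(0, 3)
  rel <- feature_relevance(model, features = 1:4, scale = FALSE)
  expect_equal(rel, rep(0, 5), tolerance = 1e-10)
  expect_error(feature_relevance(model, features = integer(0)), "empty")
})

test_that("analytic relevance gradients match central finite differences", {
  for (seed in 1:4) {
    model <- tiny_model(I = 6, J = 5, m = 3, seed = seed)
    post <- mogplvm:::.view_posterior(model, 1)
    mu_at <- function(a, j) {
      KAc <- ard_rbf(post$Au, matrix(a, 1), post$kA)
      KBc <- ard_rbf(post$Bu, post$vp$B[j, , drop = FALSE], post$kB)
      sum(post$alpha * KAc * KBc)
    }
    for (ci in c(1, 4)) for (j in c(2, 5)) {
      a <- model$params$A[ci, ]
      fd <- vapply(seq_along(a), function(r) {
        ap <- a; ap[r] <- ap[r] + 1e-4
        am <- a; am[r] <- am[r] - 1e-4
        (mu_at(ap, j) - mu_at(am, j)) / 2e-4
      }, 0)
      an <- mogplvm:::.relevance_grad_norm(post, ci, j)[1, 1]
      expect_equal(an, sqrt(sum(fd^2)), tolerance = 1e-3)
    }
  }
})

test_that("relevance maps scale each metagene to a maximum of 100", {
  model <- tiny_model(I = 8, J = 6, m = 3, seed = 5)
  rmap <- relevance_map(model, list(g1 = 1:3, g2 = 4:6))
  expect_true(all(rmap$scores >= 0))
  expect_equal(unname(apply(rmap$scores, 2, max)), c(100, 100))
})

test_that("metagene-cell links are threshold-nested", {
  model <- tiny_model(I = 8, J = 6, m = 3, seed = 6)
  rmap <- relevance_map(model, list(g1 = 1:3))
  all_pos <- link_metagene_to_cells(rmap, "g1", tau = 0)
  at30 <- link_metagene_to_cells(rmap, "g1", tau = 30)
  at50 <- link_metagene_to_cells(rmap, "g1", tau = 50)
  top <- link_metagene_to_cells(rmap, "g1", tau = 100)
  expect_true(all(at50 %in% at30))
  expect_true(all(at30 %in% all_pos))
  expect_length(top, 0)   # strict threshold excludes even the argmax
  expect_setequal(all_pos, which(rmap$scores[, 1] > 0))
  expect_error(link_metagene_to_cells(rmap, "nope"), "unknown metagene")
  expect_error(link_metagene_to_cells(rmap, "g1", tau = 120), "\\[0, 100\\]")
})

test_that("majority_celltype counts modes with lexicographic ties", {
  lab <- c("A", "A", "B", "C")
  expect_equal(majority_celltype(1:2, lab), list(cell_type = "A", coverage = 100))
  expect_equal(majority_celltype(c(1, 2, 3), lab)$coverage, 66.67)
  # tie between A and B -> lexicographically first
  expect_equal(majority_celltype(c(1, 3), lab)$cell_type, "A")
  expect_error(majority_celltype(integer(0), lab), "empty")
  set.seed(8)
  for (rep in 1:10) {
    lab2 <- sample(LETTERS[1:3], 12, replace = TRUE)
    cells <- sample(12, 6)
    got <- majority_celltype(cells, lab2)
    tab <- table(lab2[cells])
    expect_equal(got$cell_type, sort(names(tab)[tab == max(tab)])[1])
    expect_equal(got$coverage, round(100 * max(tab) / 6, 2))
  }
})

test_that("metagene enrichment reproduces the hypergeometric tail", {
  universe <- paste0("g", 1:10)
  sets <- list(T = paste0("g", 1:4), B = paste0("g", 5:7))
  # metagene equal to one marker set: full coverage, minimal p
  res <- metagene_enrichment(paste0("g", 1:4), sets, universe)
  rT <- res[res$cell_type == "T", ]
  expect_equal(rT$coverage_pct, 100)
  expect_equal(rT$p_value, oracle_hyper_tail(4, 4, 10, 4), tolerance = 1e-12)
  expect_equal(rT$p_value, 1 / choose(10, 4), tolerance = 1e-12)
  # disjoint metagene: zero coverage, p = 1
  res0 <- metagene_enrichment(paste0("g", 8:10), sets, universe)
  expect_true(all(res0$coverage_pct == 0))
  expect_true(all(res0$p_value == 1))
  # brute-force tail sums across random draws on the 10-feature universe
  set.seed(31)
  for (rep in 1:10) {
    mg <- sample(universe, sample(2:6, 1))
    res2 <- metagene_enrichment(mg, sets, universe)
    for (ct in names(sets)) {
      ov <- length(intersect(mg, sets[[ct]]))
      expect_equal(res2$p_value[res2$cell_type == ct],
                   oracle_hyper_tail(ov, length(sets[[ct]]), 10, length(mg)),
                   tolerance = 1e-12)
    }
  }
  expect_error(metagene_enrichment("g1", sets, character(0)), "empty")
  expect_error(metagene_enrichment("g1", list(X = "not_there"), universe),
               "not contained")
})

test_that("planted marker blocks link to their own cell type", {
  # end-to-end pipeline on a compact planted toy: relevance of each planted
  # marker block peaks among that type's own cells
  toy <- make_marker_toy(n_types = 3, markers_per_type = 10,
                         cells_per_type = 50, seed = 2)
  fit <- mogplvm(toy$view, n_inducing = 40, epochs = 400, batch_size = 2048,
                 learning_rate = 0.03, seed = 2)
  labels <- toy$labels$cell_type
  msets <- lapply(toy$markers, function(m) match(m, toy$view$feature_ids))
  rmap <- relevance_map(fit, msets)
  for (g in names(msets)) {
    inside <- labels == g
    sc <- rmap$scores[, g]
    # one-sided Wilcoxon: relevance inside the planted type exceeds outside
    p <- stats::wilcox.test(sc[inside], sc[!inside],
                            alternative = "greater")$p.value
    expect_lt(p, 0.01)
  }
})
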