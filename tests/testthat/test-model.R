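test_that("initialization is deterministic and shaped correctly", {
  m1 <- mogplvm_init(100, 30, r_cells = 2, r_features = 3, n_inducing = 8,
                     seed = 7)
  m2 <- mogplvm_init(100, 30, r_cells = 2, r_features = 3, n_inducing = 8,
                     seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$inducing, m2$inducing)
  expect_equal(dim(m1$params$A), c(100L, 2L))
  expect_equal(dim(m1$params$views[[1]]$B), c(30L, 3L))
  # m = I = J: inducing sets are permutations of all indices
  m3 <- mogplvm_init(5, 5, n_inducing = 5, seed = 1)
  expect_setequal(m3$inducing$cells, 1:5)
  expect_setequal(m3$inducing$features[[1]], 1:5)
  expect_error(mogplvm_init(4, 10, n_inducing = 5), "exceeds the number of cells")
  expect_error(mogplvm_init(10, 4, n_inducing = 5), "feature count")
})

test_that("KL vanishes when q(u) equals the prior", {
  model <- tiny_model(seed = 2)
  vp <- model$params$views[[1]]
  Zc <- model$inducing$cells; Zf <- model$inducing$features[[1]]
  Au <- model$params$A[Zc, , drop = FALSE]
  Bu <- vp$B[Zf, , drop = FALSE]
  wB <- exp(vp$logwB); if (length(wB) == 1) wB <- rep(wB, ncol(vp$B))
  kff <- exp(vp$logvA) * exp(vp$logvB)
  Kuu <- ard_rbf(Au, NULL, ard_kernel(exp(vp$logvA), exp(vp$logwA))) *
    ard_rbf(Bu, NULL, ard_kernel(exp(vp$logvB), wB))
  diag(Kuu) <- diag(Kuu) + 1e-6 * kff
  vp$q_mu <- rep(0, length(Zc))
  vp$Lq_raw <- mogplvm:::.raw_from_Lq(t(chol(Kuu)))
  s <- model$stores[[1]]
  out <- mogplvm:::.view_elbo_grad(model$params$A, vp, Zc, Zf, s$i, s$j, s$y,
                                   length(s$y), compute_grad = FALSE)
  expect_equal(out$KL, 0, tolerance = 1e-9)
})

test_that("the ELBO lower-bounds the exact log marginal likelihood", {
  for (seed in 1:6) {
    model <- tiny_model(I = 3, J = 2, seed = seed)
    expect_lte(model_elbo(model), oracle_log_marginal(model) + 1e-8)
  }
})

test_that("optimal q with full-grid inducing closes the bound gap", {
  model <- tiny_model(I = 3, J = 2, seed = 4, full_grid_inducing = TRUE)
  model <- optimal_q(model)
  gap <- oracle_log_marginal(model) - model_elbo(model)
  expect_gte(gap, -1e-8)   # still a lower bound
  expect_lt(gap, 1e-3)     # and tight once q is at its optimum
})

test_that("full-batch ELBO is invariant to triple ordering", {
  model <- tiny_model(I = 4, J = 3, seed = 5)
  s <- model$stores[[1]]
  perm <- sample(length(s$y))
  s2 <- s; s2$i <- s$i[perm]; s2$j <- s$j[perm]; s2$y <- s$y[perm]
  expect_equal(model_elbo(model, stores = list(s2)), model_elbo(model),
               tolerance = 1e-10)
})

test_that("analytic ELBO gradients match central finite differences", {
  model <- tiny_model(I = 6, J = 4, r1 = 2, r2 = 2, m = 3, seed = 8)
  s <- model$stores[[1]]
  batch <- list(list(i = s$i, j = s$j, y = s$y))
  f <- function(p) mogplvm:::.joint_elbo_grad(p, model$inducing, batch,
                                              length(s$y), 1,
                                              compute_grad = FALSE)$elbo
  out <- mogplvm:::.joint_elbo_grad(model$params, model$inducing, batch,
                                    length(s$y), 1)
  eps <- 1e-6
  fd_check <- function(get, set, analytic) {
    x <- get(model$params)
    g <- x * 0
    for (k in seq_along(x)) {
      xp <- x; xp[k] <- xp[k] + eps
      xm <- x; xm[k] <- xm[k] - eps
      g[k] <- (f(set(model$params, xp)) - f(set(model$params, xm))) / (2 * eps)
    }
    expect_equal(as.vector(analytic), as.vector(g), tolerance = 1e-5)
  }
  fd_check(function(p) p$A, function(p, x) { p$A <- matrix(x, 6, 2); p },
           out$grads$A)
  fd_check(function(p) p$views[[1]]$B,
           function(p, x) { p$views[[1]]$B <- matrix(x, 4, 2); p },
           out$grads$views[[1]]$B)
  fd_check(function(p) p$views[[1]]$logwA,
           function(p, x) { p$views[[1]]$logwA <- x; p },
           out$grads$views[[1]]$logwA)
  fd_check(function(p) c(p$views[[1]]$logvA, p$views[[1]]$logvB,
                         p$views[[1]]$logwB, p$views[[1]]$lognoise),
           function(p, x) {
             p$views[[1]]$logvA <- x[1]; p$views[[1]]$logvB <- x[2]
             p$views[[1]]$logwB <- x[3]; p$views[[1]]$lognoise <- x[4]; p
           },
           c(out$grads$views[[1]]$logvA, out$grads$views[[1]]$logvB,
             out$grads$views[[1]]$logwB, out$grads$views[[1]]$lognoise))
  fd_check(function(p) p$views[[1]]$q_mu,
           function(p, x) { p$views[[1]]$q_mu <- x; p },
           out$grads$views[[1]]$q_mu)
  lt <- which(lower.tri(diag(3), diag = TRUE))
  fd_check(function(p) p$views[[1]]$Lq_raw[lt],
           function(p, x) { p$views[[1]]$Lq_raw[lt] <- x; p },
           out$grads$views[[1]]$Lq_raw[lt])
})

test_that("training increases the smoothed ELBO and is seed-reproducible", {
  sim <- simulate_views(sim_config(n_cells = 20, n_features = c(rna = 10),
                                   n_cell_clusters = 3, seed = 2,
                                   guard = 4000))
  fit <- mogplvm(sim$views[[1]], n_inducing = 10, epochs = 100,
                 batch_size = 1e6, learning_rate = 0.01, seed = 1)
  sm <- vapply(split(fit$trace, ceiling(seq_along(fit$trace) / 10)), mean, 0)
  expect_true(all(diff(sm) >= -1e-3))
  fit2 <- mogplvm(sim$views[[1]], n_inducing = 10, epochs = 100,
                  batch_size = 1e6, learning_rate = 0.01, seed = 1)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$params, fit2$params)
})

test_that("posterior predictions match the exact GP on a dense toy", {
  model <- tiny_model(I = 3, J = 2, seed = 6, full_grid_inducing = TRUE)
  model <- optimal_q(model)
  p <- predict(model)
  expect_true(all(p$var >= 0))
  ex <- oracle_posterior(model)
  expect_equal(p$mean, ex$mean, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(p$var, ex$var, tolerance = 1e-4, ignore_attr = TRUE)
  expect_error(predict(model, cells = 99), "out of range")
})

test_that("with vanishing noise the posterior interpolates the observations", {
  model <- tiny_model(I = 3, J = 2, seed = 9, noise = 1e-6,
                      full_grid_inducing = TRUE)
  model <- optimal_q(model)
  p <- predict(model)
  Y <- triples_to_matrix(model$stores[[1]])
  expect_equal(p$mean, Y, tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("a one-view multi-view fit equals the single-view fit", {
  sim <- simulate_views(sim_config(n_cells = 15, n_features = c(rna = 8),
                                   seed = 3, guard = 4000))
  f1 <- mogplvm(sim$views[[1]], n_inducing = 6, epochs = 30, seed = 2)
  f2 <- mogplvm(list(sim$views[[1]]), n_inducing = 6, epochs = 30, seed = 2)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$params, f2$params)
})

test_that("views share one cell embedding: perturbing it moves every view's ELBO", {
  sim <- simulate_views(sim_config(n_cells = 12, n_features = c(a = 6, b = 5),
                                   seed = 4, guard = 4000))
  fit <- mogplvm(sim$views, n_inducing = 5, epochs = 20, seed = 1)
  per_view_elbo <- function(m) vapply(seq_along(m$stores), function(v) {
    s <- m$stores[[v]]
    mogplvm:::.view_elbo_grad(m$params$A, m$params$views[[v]],
                              m$inducing$cells, m$inducing$features[[v]],
                              s$i, s$j, s$y, length(s$y),
                              compute_grad = FALSE)$elbo
  }, 0)
  base <- per_view_elbo(fit)
  fit$params$A[3, ] <- fit$params$A[3, ] + 0.5
  moved <- per_view_elbo(fit)
  expect_true(all(abs(moved - base) > 1e-8))
})

test_that("fit rejects views with mismatched cells", {
  v1 <- view_matrix(matrix(rnorm(20), 4, 5), cell_ids = paste0("c", 1:4))
  v2 <- view_matrix(matrix(rnorm(15), 3, 5), cell_ids = paste0("c", 1:3))
  expect_error(mogplvm(list(v1, v2), n_inducing = 2, epochs = 1),
               "identical cell ids")
})

test_that("checkpoints round-trip the model through plain text", {
  sim <- simulate_views(sim_config(n_cells = 12, n_features = c(a = 6, b = 5),
                                   seed = 5, guard = 4000))
  fit <- mogplvm(sim$views, n_inducing = 4, epochs = 15, seed = 3)
  d <- tempfile()
  write_checkpoint(fit, d)
  expect_true(file.exists(file.path(d, "cell_embedding.tsv")))
  expect_true(file.exists(file.path(d, "partition.json")))
  back <- read_checkpoint(d)
  expect_equal(back$params$A, fit$params$A, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(predict(back, view = 2)$mean, predict(fit, view = 2)$mean,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(model_elbo(back, stores = fit$stores), model_elbo(fit),
               tolerance = 1e-8)
  # ARD report round-trips as floats with consistent labels
  rep1 <- export_ard_report(fit, file = file.path(d, "ard2.tsv"))
  rep2 <- utils::read.table(file.path(d, "ard2.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE)
  expect_equal(as.matrix(rep2[2:3]), as.matrix(rep1[2:3]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(rep2$label,
                   partition_dimensions(ard_weights(fit))$labels)
})

test_that("model accessors expose coherent components", {
  sim <- simulate_views(sim_config(n_cells = 12, n_features = c(a = 6),
                                   seed = 6, guard = 4000))
  fit <- mogplvm(sim$views[[1]], n_inducing = 4, epochs = 10, seed = 1)
  co <- coef(fit)
  expect_equal(dim(co$cell_embedding), c(12L, 2L))
  expect_equal(names(co$feature_embeddings), "a")
  expect_true(all(co$noise_variances > 0))
  r <- residuals(fit)
  expect_equal(r, sim$views[[1]]$values - fitted(fit), ignore_attr = TRUE)
  reps <- simulate(fit, nsim = 2, seed = 1)
  expect_length(reps, 2)
  expect_equal(dim(reps[[1]]), c(12L, 6L))
  expect_output(print(fit), "Multi-output GP-LVM")
  expect_output(print(summary(fit)), "ARD weights")
})
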