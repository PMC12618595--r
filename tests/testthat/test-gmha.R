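make_small_graph <- function(n = 7, seed = 1) {
  set.seed(seed)
  W <- random_connected_graph(n, p = 0.6)
  ed <- as.matrix(dist(matrix(rnorm(n * 3, sd = 20), ncol = 3)))
  list(W = W, ed = ed)
}

test_that("node features match hand computation and the documented layout", {
  edm <- matrix(0, 3, 3)
  edm[1, 2] <- edm[2, 1] <- 3; edm[1, 3] <- edm[3, 1] <- 4
  edm[2, 3] <- edm[3, 2] <- 5
  W <- toy_graph()
  X <- build_node_features(edm, W, zscore = FALSE)
  # node 1: distances {3, 4} -> mean 3.5, sample SD 0.7071, min 3
  expect_equal(X[1, 1], 3.5)
  expect_equal(X[1, 2], sqrt(0.5), tolerance = 1e-10)
  expect_equal(X[1, 3], 3)
  expect_equal(X[, 4], rowSums(W))       # strength
  expect_equal(X[, 5], c(2, 2, 2))       # degree

  # complete SC with equal weights: constant strength column (n-1)*w
  K <- matrix(2, 4, 4); diag(K) <- 0
  edk <- as.matrix(dist(matrix(rnorm(12), 4)))
  XK <- build_node_features(edk, K, zscore = FALSE)
  expect_equal(XK[, 4], rep(6, 4))

  expect_equal(ncol(build_node_features(edm, W, include_sc_row = TRUE)), 8)
  Xz <- build_node_features(edm, W)
  expect_equal(colMeans(Xz), rep(0, 5), tolerance = 1e-12)
  expect_error(build_node_features(edm[1:2, 1:2], W[1:2, 1:2]),
               class = "scfc_dimension_error")
})

test_that("attention rows are a distribution over each neighbourhood", {
  g <- make_small_graph()
  cfg <- gmha_config(heads = 2, hidden = 8, latent = 4, seed = 5)
  X <- build_node_features(g$ed, g$W)
  params <- scfcmap:::init_gmha_params(ncol(X), cfg)
  out <- attention_layer(X, g$W, params$layers[[1]], mode = "concat",
                         return_attention = TRUE)
  mask <- g$W > 0; diag(mask) <- TRUE
  for (A in attr(out, "attention")) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
    expect_true(all(A[!mask] == 0))
  }

  # self-loop-only node: attention collapses to alpha_ii = 1 and the head
  # output is elu(W x_i)
  W2 <- g$W; W2[3, ] <- 0; W2[, 3] <- 0
  out2 <- attention_layer(X, W2, params$layers[[1]][1], mode = "concat",
                          return_attention = TRUE)
  A <- attr(out2, "attention")[[1]]
  expect_equal(A[3, 3], 1)
  pp <- params$layers[[1]][[1]]
  expect_equal(out2[3, ],
               as.numeric(scfcmap:::elu(X[3, , drop = FALSE] %*% pp$W)),
               tolerance = 1e-12)
})

test_that("encoder is permutation-equivariant and the decoder consistent", {
  g <- make_small_graph(n = 8, seed = 3)
  cfg <- gmha_config(heads = 2, hidden = 8, latent = 4, decoder_hidden = 6,
                     include_sc_row = FALSE, seed = 7)
  X <- build_node_features(g$ed, g$W)
  params <- scfcmap:::init_gmha_params(ncol(X), cfg)
  fw <- scfcmap:::gmha_forward(params, X, g$W, cfg)

  set.seed(9)
  perm <- sample(8)
  Xp <- build_node_features(g$ed[perm, perm], g$W[perm, perm])
  fwp <- scfcmap:::gmha_forward(params, Xp, g$W[perm, perm], cfg)
  expect_equal(fwp$Z, fw$Z[perm, ], tolerance = 1e-10)

  # decoded matrices are related by the same relabeling
  M <- scfcmap:::from_upper_triangle(fw$yhat, 8)
  Mp <- scfcmap:::from_upper_triangle(fwp$yhat, 8)
  expect_equal(Mp, M[perm, perm], tolerance = 1e-10)
})

test_that("decoder output is symmetric with zero diagonal", {
  cfg <- gmha_config(heads = 2, hidden = 8, latent = 4, decoder_hidden = 6,
                     seed = 2)
  parc <- parcellation(letters[1:6])
  params <- scfcmap:::init_gmha_params(5, cfg)
  Z <- matrix(rnorm(6 * 4), 6, 4)
  fm <- list(params = params, config = cfg)
  pfc <- decode(fm, Z, parc, band = "alpha")
  expect_equal(pfc$values, t(pfc$values))
  expect_equal(unname(diag(pfc$values)), rep(0, 6))
  # identical latent rows zero out the |z_i - z_j| block; prediction equals
  # that of the product features alone -- check invariance to row swap
  Z2 <- Z; Z2[2, ] <- Z[1, ]
  pfc2 <- decode(fm, Z2, parc, band = "alpha")
  expect_equal(pfc2$values[1, 3], pfc2$values[2, 3], tolerance = 1e-12)
})

test_that("the loss is MSE over edges plus the L2 penalty", {
  o <- c(0.5, 0.7)
  expect_equal(gmha_loss(o, o, gamma = 0), 0)
  expect_equal(gmha_loss(o + c(0.1, -0.1), o, gamma = 0), 0.01)
  cfg <- gmha_config(heads = 2, hidden = 4, latent = 2, decoder_hidden = 3,
                     seed = 1)
  params <- scfcmap:::init_gmha_params(4, cfg)
  expect_equal(gmha_loss(o, o, params, gamma = 0.01),
               0.01 * sum(unlist(params)^2))
})

test_that("hand-derived gradients match numerical differentiation", {
  g <- make_small_graph(n = 6, seed = 11)
  cfg <- gmha_config(layers = 2, heads = 2, hidden = 6, latent = 4,
                     decoder_hidden = 5, gamma = 0, include_sc_row = TRUE,
                     seed = 3)
  X <- build_node_features(g$ed, g$W, include_sc_row = TRUE)
  set.seed(12)
  y <- runif(15)
  fwbw <- function(params) {
    fw <- scfcmap:::gmha_forward(params, X, g$W, cfg)
    dy <- matrix(2 * (fw$yhat - y) / length(y), ncol = 1)
    list(loss = mean((fw$yhat - y)^2),
         g = scfcmap:::flatten_params(
           scfcmap:::gmha_backward(params, fw, dy, cfg)))
  }
  params <- scfcmap:::init_gmha_params(ncol(X), cfg)
  theta <- scfcmap:::flatten_params(params)
  analytic <- fwbw(params)$g
  eps <- 1e-6
  set.seed(13)
  idx <- sample(length(theta), 60)   # spot-check a random parameter subset
  for (k in idx) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    num <- (fwbw(scfcmap:::unflatten_params(tp, params))$loss -
              fwbw(scfcmap:::unflatten_params(tm, params))$loss) / (2 * eps)
    expect_equal(analytic[k], num, tolerance = 1e-5)
  }
})

test_that("folds partition subjects with the documented sizes", {
  ids <- sprintf("S%03d", 1:126)
  folds <- make_folds(ids, k = 5, seed = 4)
  sizes <- vapply(folds$folds, function(f) length(f$test), 0L)
  expect_equal(sort(sizes, decreasing = TRUE), c(26, 25, 25, 25, 25))
  all_test <- unlist(lapply(folds$folds, `[[`, "test"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0)
  for (f in folds$folds) {
    expect_length(intersect(f$test, c(f$train, f$val)), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$test, f$train, f$val), ids)
  }
  expect_identical(make_folds(ids, k = 5, seed = 4)$folds, folds$folds)
  expect_error(make_folds(ids[1:3], k = 5, seed = 1),
               class = "scfc_config_error")
})

test_that("training improves reconstruction and is reproducible", {
  coh <- cached("gmha_micro", function()
    generate_cohort(synth_config(seed = 31, n_healthy = 10, n_patients = 2,
                                 n_nodes = 16, mapping = noiseless_mapping())))
  cfg <- gmha_config(epochs = 30, batch_size = 2, lr = 5e-3, gamma = 1e-4,
                     include_sc_row = TRUE, hidden = 16, latent = 8,
                     decoder_hidden = 16, seed = 21)
  folds <- make_folds(coh, k = 2, seed = 21)
  mdl <- cached("gmha_micro_model", function()
    train_gmha(coh, "beta", "FA", cfg, folds))
  # loss decreases substantially from initialization
  el <- mdl$fold_models[[1]]$epoch_loss
  expect_lt(el[length(el)], 0.25 * el[1])
  # mostly monotone descent on noiseless data
  expect_gte(mean(diff(el) <= 1e-6), 0.8)
  # held-out predictions beat a trivial baseline by a wide margin
  expect_gt(mean(mdl$records$r), 0.5)
  # same seed end-to-end gives identical out-of-fold records
  mdl2 <- train_gmha(coh, "beta", "FA", cfg, folds)
  expect_identical(mdl$records$r, mdl2$records$r)
})

test_that("external prediction guards leakage and averages fold models", {
  coh <- cached("gmha_micro", function()
    generate_cohort(synth_config(seed = 31, n_healthy = 10, n_patients = 2,
                                 n_nodes = 16, mapping = noiseless_mapping())))
  cfg <- gmha_config(epochs = 30, batch_size = 2, lr = 5e-3, gamma = 1e-4,
                     include_sc_row = TRUE, hidden = 16, latent = 8,
                     decoder_hidden = 16, seed = 21)
  folds <- make_folds(coh, k = 2, seed = 21)
  mdl <- cached("gmha_micro_model", function()
    train_gmha(coh, "beta", "FA", cfg, folds))
  expect_error(predict_external(mdl, coh, "H001"),
               class = "scfc_leakage_error")
  ext <- predict_external(mdl, coh, c("P01", "P02"))
  expect_equal(nrow(ext$records), 2)
  expect_true(all(ext$records$model == "gmha"))
  expect_equal(ext$pfc$P01$values, t(ext$pfc$P01$values))

  lat <- export_latent(mdl, coh)
  expect_equal(nrow(lat$latent), 10 * 16)    # subjects x nodes
  expect_equal(ncol(lat$latent), 2 + 8)      # subject, node, z1..z8
  expect_true(all(lat$errors$error >= 0 & lat$errors$error <= 2))
})
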