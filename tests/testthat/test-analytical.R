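test_that("length transform and transition matrix follow their definitions", {
  W <- toy_graph()
  L <- to_lengths(W)
  expect_equal(L[1, 2], 1)
  expect_equal(L[1, 3], 4)   # 1/0.25
  expect_equal(diag(L), rep(0, 3))
  W0 <- W; W0[2, 3] <- W0[3, 2] <- 0
  expect_true(is.infinite(to_lengths(W0)[2, 3]))

  P <- transition_matrix(W)
  expect_equal(P[1, 2], 0.8)
  expect_equal(P[1, 3], 0.2)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-12)
  two <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(transition_matrix(two)[1, 2], 1)
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_error(transition_matrix(iso), class = "scfc_isolated_node_error")
})

test_that("toy-graph SPL and SI match hand computation", {
  W <- toy_graph()
  res <- shortest_paths(W, return_paths = TRUE)
  expect_equal(res$spl[1, 3], 2)          # path 1-2-3 beats direct length 4
  expect_equal(res$paths(1, 3), c(1, 2, 3))
  expect_equal(diag(res$spl), rep(0, 3))
  expect_equal(res$si[1, 3], -log2(0.4), tolerance = 1e-12)  # 1.3219 bits
  mem <- shortest_paths(W, memory = TRUE)
  expect_equal(mem$si[1, 3], -log2(0.8), tolerance = 1e-12)  # 0.3219 bits
  # a node whose only continuation is the target contributes certainty:
  # memory walker at node 2 (arrived from 1) must go to 3, Pr step = 1
  expect_equal(mem$si_directed[1, 3], -log2(0.8), tolerance = 1e-12)

  # disconnected pairs are flagged
  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 1; iso[3, 4] <- iso[4, 3] <- 1
  res2 <- shortest_paths(iso)
  expect_false(res2$connected)
  expect_true(is.infinite(res2$spl[1, 3]))
})

test_that("compiled SPL/SI agree with brute-force enumeration on random graphs", {
  set.seed(404)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    W <- random_connected_graph(n, p = 0.55)
    oracle <- enum_paths_oracle(W)
    res <- shortest_paths(W)
    resm <- shortest_paths(W, memory = TRUE)
    expect_equal(res$spl, oracle$spl, tolerance = 1e-12)
    expect_equal(res$si, oracle$si_nomem, tolerance = 1e-10)
    expect_equal(resm$si, oracle$si_mem, tolerance = 1e-10)
  }
})

test_that("raising a weight on the unique shortest path shortens it", {
  W <- toy_graph()
  base <- shortest_paths(W)$spl[1, 3]
  W2 <- W; W2[1, 2] <- W2[2, 1] <- 2   # length 1 -> 0.5 on the 1-2-3 path
  expect_lt(shortest_paths(W2)$spl[1, 3], base)
})

test_that("build_predictors assembles edge vectors and rejects disconnection", {
  W <- toy_graph()
  parc <- toy_parcellation()
  sc <- conn_matrix(W, "SC", "FA", parc)
  edm <- matrix(0, 3, 3); edm[1, 2] <- edm[2, 1] <- 3
  edm[1, 3] <- edm[3, 1] <- 4; edm[2, 3] <- edm[3, 2] <- 5
  ed <- conn_matrix(edm, "ED", parc = parc)
  pred <- build_predictors(sc, ed)
  expect_length(pred$spl, 3)
  expect_equal(pred$ed, c(3, 4, 5))          # passthrough
  expect_equal(pred$spl, c(1, 2, 1))
  expect_equal(pred$source_weight, "FA")

  # complete graph with equal weights: SPL constant
  K <- matrix(1, 4, 4); diag(K) <- 0
  p4 <- parcellation(letters[1:4])
  predK <- build_predictors(conn_matrix(K, "SC", "FA", p4),
                            conn_matrix(as.matrix(dist(matrix(rnorm(12), 4))),
                                        "ED", parc = p4))
  expect_equal(length(unique(predK$spl)), 1)

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_error(build_predictors(conn_matrix(iso, "SC", "FA", parc), ed),
               class = "scfc_disconnected_error")
})

test_that("OLS fit recovers exact linear targets and behaves like OLS", {
  set.seed(11)
  m <- 45
  pred <- structure(list(spl = runif(m, 1, 4), si = runif(m, 0, 8),
                         ed = runif(m, 5, 90), source_weight = "FA"),
                    class = "scfc_predictors")
  y <- 0.3 - 0.5 * pred$spl - 0.1 * pred$si - 0.01 * pred$ed
  fit <- fit_fc(pred, y + rnorm(m, sd = 1e-9))
  expect_gte(fit$pearson_r, 0.999)
  expect_equal(unname(fit$coefficients),
               c(0.3, -0.5, -0.1, -0.01), tolerance = 1e-4)

  # toy y = 2x through the full interface: r exactly 1
  pr2 <- structure(list(spl = c(1, 2, 3, 4, 5), si = rep(0, 5),
                        ed = rep(0, 5), source_weight = "FA"),
                   class = "scfc_predictors")
  expect_warning(f2 <- fit_fc(pr2, 2 * (1:5)))  # collinear si/ed columns
  expect_equal(f2$pearson_r, 1, tolerance = 1e-12)
  expect_equal(f2$fitted, c(2, 4, 6, 8, 10), tolerance = 1e-10)
  # fewer than 5 edges is rejected outright
  tiny <- structure(list(spl = 1:3, si = rep(0, 3), ed = rep(0, 3),
                         source_weight = "FA"), class = "scfc_predictors")
  expect_error(fit_fc(tiny, c(2, 4, 6)), class = "scfc_dimension_error")

  # r never decreases when predictors are added (nested-model property):
  # compare against the spl-only simple regression
  y2 <- 0.2 - 0.4 * pred$spl + rnorm(m, sd = 0.3)
  r_full <- fit_fc(pred, y2)$pearson_r
  r_spl <- abs(cor(y2, pred$spl))
  expect_gte(r_full + 1e-12, r_spl)

  expect_error(fit_fc(pred, rep(1, m)), class = "scfc_degenerate_error")
  short <- structure(list(spl = 1:3, si = 1:3, ed = 1:3,
                          source_weight = "FA"), class = "scfc_predictors")
  expect_error(fit_fc(short, c(1, 2)), class = "scfc_dimension_error")
})

test_that("multiple-R of pure-noise targets concentrates near the null level", {
  set.seed(21)
  geo <- generate_parcellation(84, seed = 6)
  sc <- generate_sc(geo$ed, subject_jitter = 0.05, seed = 7)
  pred <- build_predictors(sc$FA, geo$ed)
  m <- length(pred$spl)   # 3486 edges
  rs <- vapply(1:200, function(i) fit_fc(pred, rnorm(m))$pearson_r, 0)
  # null multiple-R concentrates near sqrt(3/(m-1)); far below 0.1
  expect_gte(mean(rs < 0.1), 0.95)
})

test_that("per-subject prediction yields one record per condition and is deterministic", {
  coh <- noiseless_cohort()
  res <- predict_subject(coh, "H001", "FA", "beta")
  expect_equal(res$record$model, "analytical")
  expect_gte(res$record$r, 0.999)            # noiseless: exact by construction
  expect_equal(unname(diag(res$pfc$values)), rep(0, 32))
  res2 <- predict_subject(coh, "H001", "FA", "beta")
  expect_identical(res$pfc$values, res2$pfc$values)

  rec <- predict_cohort_analytical(coh, weights = sc_variants(),
                                   bands = fc_bands(), ids = c("H001"))
  expect_equal(nrow(rec), 20)    # 4 bands x 5 weights
  expect_error(predict_subject(coh, "nope", "FA", "beta"),
               class = "scfc_missing_matrix_error")
})
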