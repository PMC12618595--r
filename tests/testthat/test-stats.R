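test_that("edge correlation behaves like Pearson on the canonical ordering", {
  parc <- toy_parcellation(4)
  m1 <- from_upper_triangle(c(1, 2, 3, 4, 5, 6), 4)
  a <- conn_matrix(m1, "FC", "alpha", parc)
  expect_equal(pearson_edges(a, a), 1)
  b <- conn_matrix(from_upper_triangle(7 - c(1, 2, 3, 4, 5, 6), 4),
                   "FC", "alpha", parc)
  expect_equal(pearson_edges(a, b), -1)
  const <- conn_matrix(from_upper_triangle(rep(1, 6), 4), "FC", "alpha", parc)
  expect_error(pearson_edges(a, const), class = "scfc_degenerate_error")
})

test_that("Mann-Whitney matches enumeration, exactly for small samples", {
  # complete separation, 5 vs 5: exact two-sided p = 2/252
  a <- c(6, 7, 8, 9, 10); b <- c(1, 2, 3, 4, 5)
  mw <- mannwhitney(a, b)
  expect_true(mw$exact)
  expect_equal(mw$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(mw$U, 25)

  # identical samples: p = 1 (ties force the corrected approximation)
  expect_warning(mw2 <- mannwhitney(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(mw2$p_value, 1)

  # random small inputs agree with full enumeration
  set.seed(77)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- round(rnorm(na), 2); y <- round(rnorm(nb, 0.5), 2)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mannwhitney(x, y)$p_value, enum_mannwhitney_p(x, y),
                 tolerance = 1e-10)
  }

  expect_error(mannwhitney(numeric(0), 1), class = "scfc_config_error")
})

test_that("Cohen's d uses the pooled Bessel-corrected SD", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  x <- rnorm(20)
  expect_equal(cohens_d(x, x), 0)
  # means one pooled SD apart -> d = 1
  a <- c(1, 2, 3); b <- a - 1
  expect_equal(cohens_d(a, b), 1)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "scfc_degenerate_error")
  expect_error(cohens_d(1, c(1, 2)), class = "scfc_config_error")
})

test_that("label permutation is exact and matches enumeration", {
  a <- 1:5; b <- 6:10
  one <- exact_label_permutation(b, a, sided = "one")
  expect_true(one$exact)
  expect_equal(one$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(one$n_relabelings, 252)

  same <- exact_label_permutation(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  set.seed(31)
  x <- rnorm(5); y <- rnorm(5, 1)
  res <- exact_label_permutation(x, y)
  # attainable p-values are multiples of 1/252
  expect_equal(res$p_value * 252, round(res$p_value * 252), tolerance = 1e-9)
  expect_equal(res$p_value, enum_permutation_p(x, y), tolerance = 1e-12)
  res1 <- exact_label_permutation(x, y, sided = "one")
  expect_equal(res1$p_value, enum_permutation_p(x, y, "one"),
               tolerance = 1e-12)

  # Monte-Carlo fallback for large groups: p bounded away from zero
  big <- exact_label_permutation(rnorm(30), rnorm(30, 3), n_mc = 500)
  expect_false(big$exact)
  expect_gte(big$p_value, 1 / 501)
})

test_that("Spearman symptom correlations use mid-ranks and exact small-n p", {
  panss <- data.frame(id = sprintf("P%02d", 1:5),
                      total = c(37L, 59L, 49L, 41L, 56L))
  # error strictly increasing in PANSS total -> rho = 1
  rec <- data.frame(subject = panss$id, model = "analytical", band = "alpha",
                    weight = "FA", r = 1 - order(order(panss$total)) / 10)
  sp <- spearman_panss(rec, panss)
  expect_equal(sp$rho, 1)

  # mid-rank handling under ties agrees with direct computation on ranks
  rec2 <- rec; rec2$r <- 1 - c(0.1, 0.1, 0.3, 0.4, 0.5)
  sp2 <- suppressWarnings(spearman_panss(rec2, panss))
  expect_equal(sp2$rho, cor(rank(c(0.1, 0.1, 0.3, 0.4, 0.5)),
                            rank(panss$total)))

  # exact p for n = 5 distinct values agrees with enumeration over all 120
  # rank permutations
  set.seed(5)
  err <- c(0.12, 0.55, 0.31, 0.44, 0.27)
  rec3 <- rec; rec3$r <- 1 - err
  sp3 <- spearman_panss(rec3, panss)
  rho_obs <- cor(err, panss$total, method = "spearman")
  perms <- do.call(rbind, combinat_perms(5))
  rhos <- apply(perms, 1, function(p) cor(err, panss$total[p],
                                          method = "spearman"))
  expect_equal(sp3$p_value, mean(abs(rhos) >= abs(rho_obs) - 1e-12),
               tolerance = 1e-10)

  expect_error(spearman_panss(rec[1:2, ], panss), class = "scfc_config_error")
})

test_that("BH step-up flags the documented sets and stays monotone", {
  res <- bh_fdr(c(0.005, 0.01, 0.03, 0.04), alpha = 0.05)
  expect_true(all(res$significant))
  expect_equal(res$threshold, 0.04)

  expect_false(any(bh_fdr(c(0.9, 0.8))$significant))
  one <- bh_fdr(0.04, alpha = 0.05)
  expect_true(one$significant)
  expect_equal(one$threshold, 0.04)

  # agreement with p.adjust and monotonicity on random vectors
  set.seed(99)
  for (i in 1:100) {
    p <- runif(sample(3:25, 1))^sample(1:3, 1)
    res <- bh_fdr(p, alpha = 0.05)
    expect_equal(res$significant, p.adjust(p, "BH") <= 0.05)
    ord <- order(p)
    flags <- res$significant[ord]
    if (any(flags)) expect_true(all(flags[seq_len(max(which(flags)))]))
  }
  # BY is more conservative
  set.seed(100)
  p <- runif(20)^2
  expect_lte(sum(bh_fdr(p, variant = "by")$significant),
             sum(bh_fdr(p)$significant))
  expect_error(bh_fdr(c(0.5, 0)), class = "scfc_value_error")
})

test_that("cohort similarity, strength and variability summaries", {
  coh <- tiny_cohort()
  ids <- vapply(coh$subjects, function(s) s$id, "")
  mats <- lapply(ids[1:4], function(id) get_matrix(coh, id, "FC", "alpha"))
  sim <- matrix_cohort_similarity(mats[[1]], mats)
  expect_equal(sim$r[1], 1)
  expect_true(is.finite(sim$reference_mean))

  m3 <- from_upper_triangle(c(1, 2, 3), 3)
  cm3 <- conn_matrix(m3, "SC", "NS", toy_parcellation())
  expect_equal(total_strength(cm3), 6)
  expect_equal(total_strength(conn_matrix(2 * m3, "SC", "NS",
                                          toy_parcellation())), 12)

  st <- compare_total_strength(coh)
  expect_equal(nrow(st), 9)   # 5 SC variants + 4 FC bands
  expect_true(all(st$p_value > 0 & st$p_value <= 1))

  # identical FC across subjects -> zero edge variability
  parc <- coh$parcellation
  same <- get_matrix(coh, ids[1], "FC", "beta")
  clone <- list(ED = get_matrix(coh, ids[1], "ED"))
  subs <- lapply(ids[1:3], function(id) subject(id, 30, "healthy"))
  for (id in ids[1:3]) clone[[paste(id, "FC", "beta", sep = ".")]] <- same
  coh0 <- cohort(subs, clone, parc)
  ev0 <- edge_variability(coh0, bands = "beta")
  expect_equal(max(ev0$sd$beta), 0)
  expect_equal(ev0$median[["beta"]], 0)

  # scale invariance through max-normalization
  ev1 <- edge_variability(coh, bands = c("delta", "beta"))
  doubled <- coh
  for (id in ids) {
    key <- paste(id, "FC", "delta", sep = ".")
    doubled$matrices[[key]]$values <- 2 * doubled$matrices[[key]]$values
  }
  ev2 <- edge_variability(doubled, bands = c("delta", "beta"))
  expect_equal(ev1$median[["delta"]], ev2$median[["delta"]], tolerance = 1e-12)
  expect_s3_class(ev1$tests, "data.frame")
})

test_that("paired weight comparison detects shifts and rejects degeneracy", {
  set.seed(17)
  n <- 40
  subj <- sprintf("S%02d", 1:n)
  base <- runif(n, 0.3, 0.6)
  rec <- rbind(
    data.frame(subject = subj, model = "analytical", band = "alpha",
               weight = "FA", r = base + 0.1 + rnorm(n, sd = 0.05)),
    data.frame(subject = subj, model = "analytical", band = "alpha",
               weight = "NS", r = base))
  res <- paired_ttest_weights(rec, "alpha", "FA", "NS")
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$n, n)

  same <- rbind(
    data.frame(subject = subj, model = "analytical", band = "alpha",
               weight = "FA", r = base),
    data.frame(subject = subj, model = "analytical", band = "alpha",
               weight = "NS", r = base))
  expect_error(paired_ttest_weights(same, "alpha", "FA", "NS"),
               class = "scfc_degenerate_error")
})

test_that("age correlations flag exact linear trends and control FDR", {
  set.seed(23)
  n <- 30
  subj <- sprintf("S%02d", 1:n)
  ages <- setNames(seq(18, 50, length.out = n), subj)
  rec <- rbind(
    data.frame(subject = subj, model = "analytical", band = "alpha",
               weight = "FA", r = 0.9 - 0.01 * ages[subj]),
    data.frame(subject = subj, model = "analytical", band = "beta",
               weight = "FA", r = rnorm(n, 0.5, 0.05)))
  ac <- age_correlation(rec, ages)
  row_alpha <- ac[ac$band == "alpha", ]
  expect_equal(row_alpha$r, -1, tolerance = 1e-9)
  expect_true(row_alpha$significant)
  expect_error(age_correlation(rec, setNames(rep(30, n), subj)),
               class = "scfc_degenerate_error")
})

test_that("shuffling is a no-op when all subjects share SC and FC", {
  geo <- generate_parcellation(16, seed = 2)
  sc <- generate_sc(geo$ed, subject_jitter = 0, seed = 3, topo_flip = 0)
  fc <- generate_fc(sc, geo$ed, gt_mapping(), seed = 4)
  subs <- lapply(sprintf("S%d", 1:4), function(id) subject(id, 30, "healthy"))
  mats <- list(ED = geo$ed)
  for (s in subs) {
    mats[[paste(s$id, "SC", "FA", sep = ".")]] <- sc$FA
    mats[[paste(s$id, "FC", "alpha", sep = ".")]] <- fc$alpha
  }
  coh <- cohort(subs, mats, geo$parcellation)
  sh <- shuffle_individuality(coh, weight = "FA", band = "alpha",
                              n_perm = 20, seed = 5, ids = sprintf("S%d", 1:4))
  expect_equal(sh$r_shuffled_mean, sh$r_unshuffled, tolerance = 1e-12)
  expect_error(shuffle_individuality(coh, n_perm = 0),
               class = "scfc_config_error")
})
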