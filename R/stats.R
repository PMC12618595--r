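# The evaluation battery: correlation records, individuality shuffling,
# paired edge-weight tests, age trends, group comparisons with effect
# sizes, symptom correlations, exact label-permutation model comparison,
# Benjamini-Hochberg FDR, matrix-similarity, strength and edge-variability
# summaries.

#' Pearson correlation between two connectomes' edges
#'
#' Computed on the canonical upper-triangle edge vectors; this is the
#' accuracy metric relating observed and predicted FC.
#'
#' @param a,b `scfc_matrix` objects over the same parcellation (or plain
#'   symmetric matrices of equal size).
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_edges <- function(a, b) {
  va <- upper_triangle(a); vb <- upper_triangle(b)
  if (length(va) != length(vb))
    stop_scfc("scfc_dimension_error", "matrices have different sizes")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop_scfc("scfc_degenerate_error", "constant edge vector; r undefined")
  stats::cor(va, vb)
}

#' Individuality of the SC-FC relationship via shuffling
#'
#' Repeatedly permutes the assignment of structural (and distance) matrices
#' across subjects while keeping each subject's observed FC fixed, re-runs
#' the analytical prediction, and returns, per subject, the mean over
#' permutations of the observed-vs-predicted correlation. If the mapping is
#' shared across subjects the shuffled mean tracks the unshuffled r; a drop
#' indicates subject-specific structure in the relationship. Predictor sets
#' (and their QR decompositions) are cached per structural matrix, so the
#' permutations only re-project each subject's FC.
#'
#' @param coh An `scfc_cohort`.
#' @param weight,band Condition to evaluate.
#' @param n_perm Number of shuffles (default 500).
#' @param seed Integer seed.
#' @param ids Subjects to include (default: all healthy subjects).
#' @param memory,transform Passed to [build_predictors()].
#' @return data.frame with columns subject, r_unshuffled, r_shuffled_mean.
#' @export
shuffle_individuality <- function(coh, weight = "FA", band = "alpha",
                                  n_perm = 500, seed = 1, ids = NULL,
                                  memory = FALSE, transform = "inv") {
  if (n_perm < 1) stop_scfc("scfc_config_error", "n_perm must be >= 1")
  if (is.null(ids))
    ids <- vapply(Filter(function(s) s$group == "healthy", coh$subjects),
                  function(s) s$id, "")
  ns <- length(ids)
  if (ns < 2) stop_scfc("scfc_config_error", "need >= 2 subjects to shuffle")
  qrs <- vector("list", ns)
  ys <- vector("list", ns)
  for (i in seq_len(ns)) {
    sc <- get_matrix(coh, ids[i], "SC", weight)
    ed <- get_matrix(coh, ids[i], "ED")
    pred <- build_predictors(sc, ed, memory = memory, transform = transform)
    qrs[[i]] <- qr(cbind(1, pred$spl, pred$si, pred$ed))
    ys[[i]] <- upper_triangle(get_matrix(coh, ids[i], "FC", band))
  }
  r_of <- function(qi, yi) {
    f <- qr.fitted(qrs[[qi]], ys[[yi]])
    if (stats::sd(f) == 0) 0 else stats::cor(ys[[yi]], f)
  }
  r_un <- vapply(seq_len(ns), function(i) r_of(i, i), 0)
  set.seed(seed)
  acc <- numeric(ns)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(ns)
    acc <- acc + vapply(seq_len(ns), function(i) r_of(perm[i], i), 0)
  }
  data.frame(subject = ids, r_unshuffled = r_un, r_shuffled_mean = acc / n_perm,
             stringsAsFactors = FALSE)
}

#' Paired t-test between two edge weights' accuracy distributions
#'
#' Two-sided paired t-test on the per-subject difference of
#' observed-vs-predicted correlations between two structural edge-weight
#' variants, within one band and model.
#'
#' @param records Correlation records (data.frame with subject, model, band,
#'   weight, r).
#' @param band Band to compare within.
#' @param weightA,weightB The two variants.
#' @param model Which model's records to use.
#' @return List with `statistic`, `p_value`, `n`.
#' @export
paired_ttest_weights <- function(records, band, weightA, weightB,
                                 model = "analytical") {
  sub <- records[records$band == band & records$model == model, ]
  a <- sub$r[sub$weight == weightA][order(sub$subject[sub$weight == weightA])]
  b <- sub$r[sub$weight == weightB][order(sub$subject[sub$weight == weightB])]
  if (length(a) != length(b) || length(a) < 3)
    stop_scfc("scfc_config_error", "need >= 3 paired subjects (got %d vs %d)",
              length(a), length(b))
  d <- a - b
  if (stats::sd(d) == 0)
    stop_scfc("scfc_degenerate_error",
              "zero-variance paired differences; t-test undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value, n = length(a))
}

#' Age dependence of prediction accuracy
#'
#' Pearson correlation (with two-sided p) between subject age and the
#' observed-vs-predicted FC correlation, per (band, weight) condition, with
#' Benjamini-Hochberg FDR across conditions.
#'
#' @param records Correlation records.
#' @param ages Named numeric vector, names = subject ids.
#' @param alpha FDR level.
#' @return data.frame with band, weight, r, p_value, significant flag, and
#'   attribute `"threshold"` (realized FDR threshold).
#' @export
age_correlation <- function(records, ages, alpha = 0.05) {
  if (length(unique(ages)) < 2)
    stop_scfc("scfc_degenerate_error", "ages are constant")
  conds <- unique(records[, c("band", "weight")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sub <- records[records$band == conds$band[i] &
                     records$weight == conds$weight[i], ]
    if (nrow(sub) < 3)
      stop_scfc("scfc_config_error", "need >= 3 subjects per condition")
    ct <- stats::cor.test(ages[sub$subject], sub$r)
    data.frame(band = conds$band[i], weight = conds$weight[i],
               r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # exactly linear trends underflow to p = 0; clamp to the smallest
  # representable positive p before the (strictly positive) FDR step
  fdr <- bh_fdr(pmax(out$p_value, .Machine$double.xmin), alpha = alpha)
  out$significant <- fdr$significant
  attr(out, "threshold") <- fdr$threshold
  out
}

#' Mann-Whitney U comparison of two groups with Cohen's d
#'
#' Two-sided Mann-Whitney U test: exact null distribution when the smaller
#' group has at most 8 observations and there are no ties (the patient
#' group size of 5 demands the exact test), otherwise the tie-corrected
#' normal approximation (with a warning when exactness was requested but
#' ties prevent it). Cohen's d (pooled Bessel-corrected SD, sign convention
#' `a - b`) is reported alongside.
#'
#' @param a,b Numeric vectors (e.g. healthy and patient correlation values).
#' @return List with `U`, `p_value`, `cohens_d`, `n` (group sizes), `exact`.
#' @export
mannwhitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1)
    stop_scfc("scfc_config_error", "both groups must be non-empty")
  want_exact <- min(length(a), length(b)) <= 8
  has_ties <- anyDuplicated(c(a, b)) > 0
  wt <- suppressWarnings(stats::wilcox.test(a, b,
                                            exact = want_exact && !has_ties,
                                            correct = TRUE))
  if (want_exact && has_ties)
    warning("ties present; falling back to tie-corrected normal approximation")
  d <- if (length(a) >= 2 && length(b) >= 2) cohens_d(a, b) else NA_real_
  list(U = unname(wt$statistic), p_value = wt$p.value, cohens_d = d,
       n = c(length(a), length(b)), exact = want_exact && !has_ties)
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, with the pooled SD using Bessel's
#' correction.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop_scfc("scfc_config_error", "need >= 2 observations per group")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop_scfc("scfc_degenerate_error", "zero pooled SD")
  (mean(a) - mean(b)) / sp
}

#' Spearman correlation between symptom severity and prediction error
#'
#' Spearman rank correlation (exact p for n <= 9, mid-ranks for ties)
#' between each PANSS component and the prediction error `1 - r` of the
#' requested model, per (band, weight).
#'
#' @param records Correlation records for the patients.
#' @param panss data.frame with columns id, total, positive, negative,
#'   general.
#' @param model Model whose records to use.
#' @param score PANSS component (default `"total"`).
#' @return data.frame with band, weight, rho, p_value.
#' @export
spearman_panss <- function(records, panss, model = "analytical",
                           score = "total") {
  recs <- records[records$model == model, ]
  if (length(unique(recs$subject)) < 3)
    stop_scfc("scfc_config_error", "need >= 3 patients")
  conds <- unique(recs[, c("band", "weight")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sub <- recs[recs$band == conds$band[i] & recs$weight == conds$weight[i], ]
    err <- 1 - sub$r
    sc <- panss[[score]][match(sub$subject, panss$id)]
    ct <- suppressWarnings(stats::cor.test(err, sc, method = "spearman"))
    data.frame(band = conds$band[i], weight = conds$weight[i],
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact label-permutation test for a difference of group means
#'
#' Enumerates all `choose(n_a + n_b, n_a)` relabelings when that count is at
#' most `max_enum` (default 184756), otherwise uses seeded Monte-Carlo with
#' at least 1e4 draws. The p-value is the fraction of relabelings whose
#' difference of means is as or more extreme than observed; for 5-vs-5
#' groups the attainable p-values are exactly the multiples of 1/252.
#'
#' @param a,b Numeric vectors.
#' @param sided `"two"` (default) or `"one"` (tests mean(a) > mean(b)).
#' @param max_enum Enumeration cutoff.
#' @param n_mc Monte-Carlo draws past the cutoff.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return List with `observed`, `p_value`, `n_relabelings`, `exact`,
#'   `sided`.
#' @export
exact_label_permutation <- function(a, b, sided = c("two", "one"),
                                    max_enum = 184756, n_mc = 10000,
                                    seed = 1) {
  sided <- match.arg(sided)
  if (length(a) < 1 || length(b) < 1)
    stop_scfc("scfc_config_error", "both groups must be non-empty")
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  obs <- mean(a) - mean(b)
  stat_of <- function(idx) {
    mean(pool[idx]) - mean(pool[-idx])
  }
  total <- choose(n, na)
  eps <- 1e-12 * (1 + abs(obs))
  if (total <= max_enum) {
    idxs <- utils::combn(n, na)
    stats_all <- apply(idxs, 2, stat_of)
    hits <- if (sided == "one") sum(stats_all >= obs - eps)
    else sum(abs(stats_all) >= abs(obs) - eps)
    list(observed = obs, p_value = hits / total, n_relabelings = total,
         exact = TRUE, sided = sided)
  } else {
    set.seed(seed)
    draws <- vapply(seq_len(n_mc), function(i) stat_of(sample.int(n, na)), 0)
    hits <- if (sided == "one") sum(draws >= obs - eps)
    else sum(abs(draws) >= abs(obs) - eps)
    # add-one so p >= 1/(n_mc + 1), never exactly zero
    list(observed = obs, p_value = (hits + 1) / (n_mc + 1),
         n_relabelings = n_mc + 1, exact = FALSE, sided = sided)
  }
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with ordered p-values `p(1) <= ... <= p(m)`, find the
#' largest `k` with `p(k) <= k * alpha / m` and declare all `p <= p(k)`
#' significant. The realized threshold is `p(k)` (NA when nothing is
#' flagged). The Benjamini-Yekutieli variant divides alpha by the harmonic
#' sum for arbitrary dependence.
#'
#' @param p Numeric p-values in (0, 1]; upper bounds such as printed
#'   "<1e-10" entries are entered as their bound.
#' @param alpha FDR level (default 0.05).
#' @param labels Optional condition labels.
#' @param variant `"bh"` (default) or `"by"`.
#' @return List with `p`, `labels`, `significant` (logical, monotone in p),
#'   `threshold`, `alpha`.
#' @export
bh_fdr <- function(p, alpha = 0.05, labels = NULL, variant = c("bh", "by")) {
  variant <- match.arg(variant)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_scfc("scfc_value_error", "p-values must lie in (0, 1]")
  m <- length(p)
  alpha_eff <- if (variant == "by") alpha / sum(1 / seq_len(m)) else alpha
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * alpha_eff / m)
  if (length(k) == 0) {
    sig <- rep(FALSE, m); thr <- NA_real_
  } else {
    thr <- ps[max(k)]
    sig <- p <= thr
  }
  list(p = p, labels = labels, significant = sig, threshold = thr,
       alpha = alpha)
}

#' Similarity of one connectome to a cohort of connectomes
#'
#' Pearson edge correlation of a target matrix against every matrix of the
#' same kind/variant in a reference set, plus the mean of the reference
#' set's own pairwise correlations (the healthy-vs-healthy baseline shown
#' as dashed lines in cohort-similarity figures).
#'
#' @param target An `scfc_matrix`.
#' @param reference List of `scfc_matrix` of the same kind/variant.
#' @return List with `r` (vector, one per reference matrix) and
#'   `reference_mean` (mean pairwise r within the reference set).
#' @export
matrix_cohort_similarity <- function(target, reference) {
  rs <- vapply(reference, function(m) pearson_edges(target, m), 0)
  nref <- length(reference)
  pair_r <- c()
  if (nref >= 2) {
    vecs <- vapply(reference, upper_triangle, numeric(length(upper_triangle(reference[[1]]))))
    cm <- stats::cor(vecs)
    pair_r <- cm[upper.tri(cm)]
  }
  list(r = rs, reference_mean = if (length(pair_r)) mean(pair_r) else NA_real_)
}

#' Total connection strength
#'
#' Sum over the unique (upper-triangle) edges of a connectivity matrix.
#'
#' @param m An `scfc_matrix` (or plain symmetric matrix).
#' @return Scalar total strength.
#' @export
total_strength <- function(m) sum(upper_triangle(m))

#' Group comparison of total strength across conditions
#'
#' For every SC variant and FC band present, compares healthy vs patient
#' total connection strengths with [mannwhitney()] and applies [bh_fdr()]
#' across the conditions.
#'
#' @param coh An `scfc_cohort`.
#' @param alpha FDR level.
#' @return data.frame with kind, variant, p_value, cohens_d, significant;
#'   attribute `"threshold"`.
#' @export
compare_total_strength <- function(coh, alpha = 0.05) {
  ids_h <- vapply(Filter(function(s) s$group == "healthy", coh$subjects),
                  function(s) s$id, "")
  ids_p <- vapply(Filter(function(s) s$group == "psychosis", coh$subjects),
                  function(s) s$id, "")
  conds <- rbind(data.frame(kind = "SC", variant = SC_VARIANTS),
                 data.frame(kind = "FC", variant = FC_BANDS))
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    st <- function(ids) vapply(ids, function(id)
      total_strength(get_matrix(coh, id, conds$kind[i], conds$variant[i])), 0)
    mw <- mannwhitney(st(ids_h), st(ids_p))
    data.frame(kind = conds$kind[i], variant = conds$variant[i],
               p_value = mw$p_value, cohens_d = mw$cohens_d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p_value, alpha = alpha)
  out$significant <- fdr$significant
  attr(out, "threshold") <- fdr$threshold
  out
}

#' Across-subject edge-strength variability per band
#'
#' Max-normalizes each subject's FC, then computes for every edge the
#' sample SD across subjects; returns the distribution over edges and its
#' median per band, plus two-sided t-tests between the bands' edge-SD
#' distributions.
#'
#' @param coh An `scfc_cohort`.
#' @param bands Bands to include.
#' @param ids Subjects (default: healthy).
#' @return List with `sd` (named list of per-edge SD vectors), `median`
#'   (named vector) and `tests` (data.frame band_a, band_b, p_value).
#' @export
edge_variability <- function(coh, bands = fc_bands(), ids = NULL) {
  if (is.null(ids))
    ids <- vapply(Filter(function(s) s$group == "healthy", coh$subjects),
                  function(s) s$id, "")
  if (length(ids) < 3)
    stop_scfc("scfc_config_error", "need >= 3 subjects")
  sds <- list()
  for (b in bands) {
    vecs <- vapply(ids, function(id)
      upper_triangle(normalize_matrix(get_matrix(coh, id, "FC", b))),
      numeric(coh$parcellation$n * (coh$parcellation$n - 1) / 2))
    sds[[b]] <- apply(vecs, 1, stats::sd)
  }
  meds <- vapply(sds, stats::median, 0)
  tests <- list()
  if (length(bands) >= 2) {
    cmb <- utils::combn(bands, 2)
    tests <- lapply(seq_len(ncol(cmb)), function(i) {
      tt <- stats::t.test(sds[[cmb[1, i]]], sds[[cmb[2, i]]])
      data.frame(band_a = cmb[1, i], band_b = cmb[2, i], p_value = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
  }
  list(sd = sds, median = meds, tests = tests)
}
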