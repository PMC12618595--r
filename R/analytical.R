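# Analytical communication model: weighted shortest-path length (SPL),
# search information (SI) and Euclidean distance (ED) as edge-wise
# predictors of functional connectivity, fitted per subject by OLS.

#' Convert structural weights to edge lengths
#'
#' Communication models treat strong connections as short: the default
#' transform is the reciprocal `L = 1/w` (absent edges, `w = 0`, become
#' infinite length). The alternative `"neglog"` uses `-log(w / max(w))`,
#' i.e. the negative log of the max-normalized weight, so all lengths are
#' nonnegative; edges carrying the maximum weight get a vanishingly small
#' positive length.
#'
#' @param sc A nonnegative SC `scfc_matrix`.
#' @param transform `"inv"` (default) or `"neglog"`.
#' @return An n x n matrix of edge lengths, `Inf` where no edge, 0 diagonal.
#' @export
to_lengths <- function(sc, transform = c("inv", "neglog")) {
  transform <- match.arg(transform)
  w <- if (inherits(sc, "scfc_matrix")) sc$values else sc
  if (any(w < 0)) stop_scfc("scfc_negative_error", "weights must be >= 0")
  L <- matrix(Inf, nrow(w), ncol(w))
  pos <- w > 0
  if (transform == "inv") {
    L[pos] <- 1 / w[pos]
  } else {
    wn <- w / max(w)
    L[pos] <- -log(wn[pos])
    # equal-to-max edges get length 0; nudge to smallest positive length
    L[pos & L == 0] <- min(L[pos & L > 0], 1) * 1e-6
  }
  diag(L) <- 0
  L
}

#' Row-stochastic transition matrix of the structural random walker
#'
#' `P[i, j] = w[i, j] / strength(i)`; rows sum to one. The walker underlying
#' search information moves along structural connections with probability
#' proportional to their weight.
#'
#' @param sc A nonnegative SC `scfc_matrix` (or plain matrix).
#' @return An n x n row-stochastic matrix.
#' @export
transition_matrix <- function(sc) {
  w <- if (inherits(sc, "scfc_matrix")) sc$values else sc
  s <- rowSums(w)
  if (any(s == 0))
    stop_scfc("scfc_isolated_node_error",
              "node(s) %s have zero strength",
              paste(which(s == 0), collapse = ", "))
  w / s
}

#' Shortest paths and search information over a weighted connectome
#'
#' Computes, for every region pair, the weighted shortest-path length and
#' the search information: the number of bits `-log2(Pr)` needed to follow
#' the shortest path, where `Pr` is the probability that a random walker
#' stepping proportionally to structural weight takes exactly that path.
#' Without memory the walker's options at each node are all its neighbours;
#' with memory the edge just traversed is excluded from the denominator at
#' every step after the first. SI is symmetrized as the mean of the two
#' directions. Ties between equal-length paths are broken by the
#' lexicographically smallest node sequence, so results are deterministic.
#'
#' @param sc A nonnegative SC `scfc_matrix` (or plain matrix).
#' @param memory Logical: use the memory variant of search information?
#' @param transform Length transform passed to [to_lengths()].
#' @param return_paths If `TRUE`, also return the chosen node sequences.
#' @return List with `spl` (n x n, `Inf` for disconnected pairs), `si`
#'   (symmetrized, bits), `si_directed`, `connected` flag, and optionally
#'   `paths` (function `(s, t)` returning the 1-based node sequence).
#' @export
shortest_paths <- function(sc, memory = FALSE, transform = "inv",
                           return_paths = FALSE) {
  w <- if (inherits(sc, "scfc_matrix")) sc$values else sc
  L <- to_lengths(w, transform)
  res <- spl_si_cpp(w, L, memory, return_paths)
  if (return_paths) {
    n <- nrow(w)
    plist <- res$paths
    res$paths <- function(s, t) plist[[(s - 1) * n + t]]
  }
  res
}

#' Assemble the analytical model's predictor set
#'
#' Upper-triangle edge vectors of SPL, symmetrized SI and ED for one
#' subject's weighted SC, in the package's canonical edge ordering.
#'
#' @param sc Subject's SC `scfc_matrix` (one weight variant).
#' @param ed The Euclidean-distance `scfc_matrix`.
#' @inheritParams shortest_paths
#' @return An object of class `scfc_predictors`: list with `spl`, `si`, `ed`
#'   edge vectors and `source_weight`.
#' @export
build_predictors <- function(sc, ed, memory = FALSE, transform = "inv") {
  res <- shortest_paths(sc, memory = memory, transform = transform)
  if (!res$connected)
    stop_scfc("scfc_disconnected_error",
              "SC graph is disconnected; SPL/SI undefined (increase density)")
  structure(list(spl = upper_triangle(res$spl),
                 si = upper_triangle(res$si),
                 ed = upper_triangle(ed),
                 source_weight = if (inherits(sc, "scfc_matrix")) sc$variant
                 else NA_character_),
            class = "scfc_predictors")
}

#' Fit the analytical regression for one subject and band
#'
#' Ordinary least squares of the observed FC edges on an intercept plus the
#' SPL, SI and ED edge vectors. The fitted values are the predicted FC; the
#' reported accuracy is the Pearson correlation between observed and fitted
#' edges, which by the OLS identity equals the multiple correlation R and is
#' nonnegative.
#'
#' @param pred An `scfc_predictors` set.
#' @param ofc Observed FC `scfc_matrix` (or an edge vector).
#' @return An `scfc_fit`: list with `coefficients` (beta0..beta3), `fitted`
#'   edge vector, `pearson_r`.
#' @export
fit_fc <- function(pred, ofc) {
  y <- if (inherits(ofc, "scfc_matrix")) upper_triangle(ofc) else as.numeric(ofc)
  X <- cbind(intercept = 1, spl = pred$spl, si = pred$si, ed = pred$ed)
  if (nrow(X) != length(y))
    stop_scfc("scfc_dimension_error", "edge counts differ (%d vs %d)",
              nrow(X), length(y))
  if (nrow(X) < 5)
    stop_scfc("scfc_dimension_error", "need at least 5 edges to fit")
  if (stats::sd(y) == 0)
    stop_scfc("scfc_degenerate_error",
              "observed FC is constant; correlation undefined")
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    warning("collinear predictors; fitting with pseudo-inverse (rank ",
            qrx$rank, ")")
  beta <- qr.coef(qrx, y)
  beta[is.na(beta)] <- 0
  fitted <- qr.fitted(qrx, y)
  r <- if (stats::sd(fitted) == 0) 0 else stats::cor(y, fitted)
  structure(list(coefficients = beta, fitted = fitted, pearson_r = r),
            class = "scfc_fit")
}

#' Predict one subject's FC with the analytical model
#'
#' Builds SPL/SI/ED predictors from the subject's SC under the requested
#' edge-weight variant, fits the regression against the observed FC of the
#' requested band, and returns the predicted FC matrix together with the
#' correlation record -- the atom of all downstream statistics.
#'
#' @param coh An `scfc_cohort`.
#' @param id Subject id.
#' @param weight SC variant, one of [sc_variants()].
#' @param band FC band, one of [fc_bands()].
#' @inheritParams shortest_paths
#' @param predictors Optional precomputed `scfc_predictors` (caching hook
#'   used by the shuffling analysis).
#' @return List with `pfc` (`scfc_matrix`), `record` (one-row data.frame:
#'   subject, model, band, weight, r) and `fit`.
#' @export
predict_subject <- function(coh, id, weight, band, memory = FALSE,
                            transform = "inv", predictors = NULL) {
  ofc <- get_matrix(coh, id, "FC", band)
  if (is.null(predictors)) {
    sc <- get_matrix(coh, id, "SC", weight)
    ed <- get_matrix(coh, id, "ED")
    predictors <- build_predictors(sc, ed, memory = memory,
                                   transform = transform)
  }
  fit <- fit_fc(predictors, ofc)
  pfc_vals <- from_upper_triangle(fit$fitted, coh$parcellation$n)
  pfc <- conn_matrix(pfc_vals, "FC", band, coh$parcellation)
  rec <- data.frame(subject = id, model = "analytical", band = band,
                    weight = weight, r = fit$pearson_r,
                    stringsAsFactors = FALSE)
  list(pfc = pfc, record = rec, fit = fit)
}

#' Analytical-model correlation records for a whole cohort
#'
#' Runs [predict_subject()] for every subject over a grid of bands and
#' weights, caching the predictor set per (subject, weight). Returns the
#' stacked correlation records (one row per subject/band/weight).
#'
#' @inheritParams predict_subject
#' @param weights,bands Character vectors over which to iterate.
#' @param ids Subjects to score (default all).
#' @return data.frame with columns subject, model, band, weight, r.
#' @export
predict_cohort_analytical <- function(coh, weights = "FA", bands = fc_bands(),
                                      ids = NULL, memory = FALSE,
                                      transform = "inv") {
  if (is.null(ids)) ids <- vapply(coh$subjects, function(s) s$id, "")
  out <- list()
  for (w in weights) {
    for (id in ids) {
      sc <- get_matrix(coh, id, "SC", w)
      ed <- get_matrix(coh, id, "ED")
      pred <- build_predictors(sc, ed, memory = memory, transform = transform)
      for (b in bands) {
        out[[length(out) + 1]] <-
          predict_subject(coh, id, w, b, predictors = pred)$record
      }
    }
  }
  do.call(rbind, out)
}
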