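# Graph multi-head-attention autoencoder (GMHA-AE).
#
# Encoder: stacked multi-head graph-attention layers over the SC graph
# (self-loops always included); additive attention scores
#   e_ij = LeakyReLU(a1.(W x_i) + a2.(W x_j)) + u * log(1 + w_ij)
# softmax-normalized over each node's neighbourhood, so structural strength
# modulates attention. Head outputs pass through an exponential-linear
# nonlinearity and are concatenated in hidden layers and averaged in the
# final layer, yielding the n x d_z latent representation. Decoder: a
# symmetric pairwise MLP on [z_i * z_j || |z_i - z_j|]. Loss: mean squared
# error over upper-triangle edges against the max-normalized observed FC
# plus gamma times the squared L2 norm of all trainable parameters.
#
# Gradients are hand-derived matrix backpropagation (verified against
# numerical differentiation in the test suite); optimization is Adam.

#' GMHA-AE configuration
#'
#' Defaults follow the training protocol: 200 epochs, batch size 32,
#' learning rate 1e-3, objective regularizer gamma = 0.01, LeakyReLU slope
#' 0.2, two attention layers with 4 heads, hidden width 64, latent
#' dimension 32. `grid` optionally lists alternative
#' `(heads, hidden, latent)` combinations searched on the validation split.
#'
#' @param layers Number of attention layers.
#' @param heads Attention heads per layer.
#' @param hidden Total hidden width of the concatenated heads.
#' @param latent Latent dimension per node.
#' @param decoder_hidden Width of the decoder MLP's hidden layer.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Subjects (graphs) per gradient step.
#' @param gamma L2 regularization weight in the objective.
#' @param leaky_slope Negative slope of the attention LeakyReLU.
#' @param include_sc_row Append each node's SC row to its feature vector?
#' @param grid Optional data.frame with columns heads, hidden, latent.
#' @param seed Integer seed controlling initialization and batch order.
#' @return An object of class `scfc_gmha_config`.
#' @export
gmha_config <- function(layers = 2, heads = 4, hidden = 64, latent = 32,
                        decoder_hidden = 64, lr = 1e-3, epochs = 200,
                        batch_size = 32, gamma = 0.01, leaky_slope = 0.2,
                        include_sc_row = FALSE, grid = NULL, seed = 1) {
  stopifnot(layers >= 1, heads >= 1, hidden >= heads, latent >= 1,
            lr > 0, epochs >= 1, batch_size >= 1, gamma >= 0)
  if (hidden %% heads != 0)
    stop_scfc("scfc_config_error", "hidden must be a multiple of heads")
  structure(as.list(environment()), class = "scfc_gmha_config")
}

#' Build the node feature matrix
#'
#' Per node: mean Euclidean distance to all other nodes, sample SD of those
#' distances, minimum distance (nearest anatomical neighbour), SC node
#' strength, SC node degree, and optionally the node's full SC row.
#' Features are z-scored across nodes (constant columns become zero).
#'
#' @param ed ED `scfc_matrix`.
#' @param sc SC `scfc_matrix` over the same parcellation.
#' @param include_sc_row Append the SC row (F becomes 5 + n)?
#' @param zscore Z-score the columns across nodes (default TRUE)?
#' @return An n x F numeric matrix.
#' @export
build_node_features <- function(ed, sc, include_sc_row = FALSE,
                                zscore = TRUE) {
  dv <- if (inherits(ed, "scfc_matrix")) ed$values else ed
  wv <- if (inherits(sc, "scfc_matrix")) sc$values else sc
  n <- nrow(dv)
  if (n < 3)
    stop_scfc("scfc_dimension_error", "need >= 3 nodes for distance SD")
  offs <- lapply(seq_len(n), function(i) dv[i, -i])
  X <- cbind(ed_mean = vapply(offs, mean, 0),
             ed_sd   = vapply(offs, stats::sd, 0),
             ed_min  = vapply(offs, min, 0),
             strength = rowSums(wv),
             degree = rowSums(wv > 0))
  if (include_sc_row) X <- cbind(X, wv)
  if (zscore) {
    X <- apply(X, 2, function(col) {
      s <- stats::sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
  }
  unname(X)
}

## ---- parameter containers ----------------------------------------------

init_gmha_params <- function(F_in, config) {
  set.seed(config$seed)
  glorot <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
  }
  d_head <- config$hidden / config$heads
  layers <- vector("list", config$layers)
  fin <- F_in
  for (l in seq_len(config$layers)) {
    final <- l == config$layers
    dh <- if (final) config$latent else d_head
    layers[[l]] <- lapply(seq_len(config$heads), function(h) {
      list(W = glorot(fin, dh), a1 = glorot(dh, 1), a2 = glorot(dh, 1),
           u = matrix(0.1, 1, 1))
    })
    fin <- if (final) config$latent else d_head * config$heads
  }
  dz <- config$latent
  dec <- list(W1 = glorot(2 * dz, config$decoder_hidden),
              b1 = matrix(0, 1, config$decoder_hidden),
              W2 = glorot(config$decoder_hidden, 1),
              b2 = matrix(0, 1, 1))
  list(layers = layers, decoder = dec)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, skeleton) {
  utils::relist(v, skeleton)
}

param_sq_norm <- function(p) sum(flatten_params(p)^2)

## ---- nonlinearities -----------------------------------------------------

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
leaky <- function(x, s) ifelse(x > 0, x, s * x)
leaky_grad <- function(x, s) ifelse(x > 0, 1, s)

row_softmax_masked <- function(E, mask) {
  E[!mask] <- -Inf
  mx <- apply(E, 1, max)
  ex <- exp(E - mx)
  ex[!mask] <- 0
  ex / rowSums(ex)
}

## ---- forward / backward -------------------------------------------------

# One attention layer forward. Returns output plus the cache needed for
# backprop.
attention_layer_forward <- function(X, heads_params, mask, K, mode, slope) {
  outs <- vector("list", length(heads_params))
  caches <- vector("list", length(heads_params))
  for (h in seq_along(heads_params)) {
    pp <- heads_params[[h]]
    H <- X %*% pp$W
    f <- as.numeric(H %*% pp$a1)
    g <- as.numeric(H %*% pp$a2)
    S <- outer(f, rep(1, length(g))) + outer(rep(1, length(f)), g)
    E <- leaky(S, slope) + pp$u[1] * K
    A <- row_softmax_masked(E, mask)
    P <- A %*% H
    O <- elu(P)
    outs[[h]] <- O
    caches[[h]] <- list(H = H, S = S, A = A, P = P)
  }
  out <- if (mode == "concat") do.call(cbind, outs) else
    Reduce(`+`, outs) / length(outs)
  list(out = out, caches = caches)
}

# Backward through one attention layer. dOut is the gradient w.r.t. the
# layer output; returns dX and per-head parameter gradients.
attention_layer_backward <- function(dOut, X, heads_params, caches, mask, K,
                                     mode, slope) {
  nh <- length(heads_params)
  dX <- matrix(0, nrow(X), ncol(X))
  grads <- vector("list", nh)
  for (h in seq_len(nh)) {
    pp <- heads_params[[h]]
    ch <- caches[[h]]
    dh <- ncol(ch$H)
    dO <- if (mode == "concat") dOut[, (h - 1) * dh + seq_len(dh), drop = FALSE]
          else dOut / nh
    dP <- dO * elu_grad(ch$P)
    dA <- dP %*% t(ch$H)
    dH <- t(ch$A) %*% dP
    dE <- ch$A * (dA - rowSums(dA * ch$A))
    du <- sum(dE * K)
    dS <- dE * leaky_grad(ch$S, slope)
    df <- rowSums(dS)
    dg <- colSums(dS)
    dH <- dH + outer(df, as.numeric(pp$a1)) + outer(dg, as.numeric(pp$a2))
    da1 <- t(ch$H) %*% df
    da2 <- t(ch$H) %*% dg
    dW <- t(X) %*% dH
    dX <- dX + dH %*% t(pp$W)
    grads[[h]] <- list(W = dW, a1 = da1, a2 = da2,
                       u = matrix(du, 1, 1))
  }
  list(dX = dX, grads = grads)
}

#' Apply one multi-head attention layer
#'
#' Exposed mainly for inspection and testing: runs a single attention layer
#' forward over an SC adjacency (neighbourhood = structural neighbours plus
#' a self-loop).
#'
#' @param X n x F node feature matrix.
#' @param sc SC `scfc_matrix` or plain adjacency matrix.
#' @param heads_params List (per head) of `W`, `a1`, `a2`, `u`.
#' @param mode `"concat"` (hidden layers) or `"average"` (final layer).
#' @param leaky_slope Attention LeakyReLU slope.
#' @param return_attention If `TRUE`, also return each head's attention
#'   matrix.
#' @return The transformed feature matrix (attribute `"attention"` when
#'   requested).
#' @export
attention_layer <- function(X, sc, heads_params, mode = c("concat", "average"),
                            leaky_slope = 0.2, return_attention = FALSE) {
  mode <- match.arg(mode)
  wv <- if (inherits(sc, "scfc_matrix")) sc$values else sc
  mask <- wv > 0
  diag(mask) <- TRUE
  K <- log1p(wv)
  res <- attention_layer_forward(X, heads_params, mask, K, mode, leaky_slope)
  out <- res$out
  if (return_attention)
    attr(out, "attention") <- lapply(res$caches, function(c) c$A)
  out
}

# Pair index helpers: canonical upper-triangle ordering.
pair_indices <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(i = idx[, 1], j = idx[, 2])
}

# Full model forward for one subject graph. Returns predicted edge vector
# and caches.
gmha_forward <- function(params, X, wv, config) {
  n <- nrow(X)
  mask <- wv > 0
  diag(mask) <- TRUE
  K <- log1p(wv)
  acts <- list(X)
  caches <- vector("list", length(params$layers))
  cur <- X
  for (l in seq_along(params$layers)) {
    mode <- if (l == length(params$layers)) "average" else "concat"
    res <- attention_layer_forward(cur, params$layers[[l]], mask, K, mode,
                                   config$leaky_slope)
    caches[[l]] <- res$caches
    cur <- res$out
    acts[[l + 1]] <- cur
  }
  Z <- cur
  pr <- pair_indices(n)
  Zi <- Z[pr$i, , drop = FALSE]
  Zj <- Z[pr$j, , drop = FALSE]
  Hd <- cbind(Zi * Zj, abs(Zi - Zj))
  dec <- params$decoder
  pre1 <- sweep(Hd %*% dec$W1, 2, dec$b1[1, ], "+")
  h1 <- elu(pre1)
  yhat <- as.numeric(h1 %*% dec$W2 + dec$b2[1])
  list(yhat = yhat, Z = Z, acts = acts, caches = caches, Hd = Hd,
       pre1 = pre1, h1 = h1, pr = pr, mask = mask, K = K)
}

# Backward for one subject: returns gradients (same shape as params) of the
# per-subject reconstruction MSE (regularizer handled by the caller).
gmha_backward <- function(params, fw, dy, config) {
  dec <- params$decoder
  dW2 <- t(fw$h1) %*% dy
  db2 <- matrix(sum(dy), 1, 1)
  dh1 <- dy %*% t(dec$W2)
  dpre1 <- dh1 * elu_grad(fw$pre1)
  dW1 <- t(fw$Hd) %*% dpre1
  db1 <- matrix(colSums(dpre1), 1, ncol(dec$b1))
  dHd <- dpre1 %*% t(dec$W1)

  dz <- ncol(fw$Z)
  d_prod <- dHd[, seq_len(dz), drop = FALSE]
  d_abs <- dHd[, dz + seq_len(dz), drop = FALSE]
  Zi <- fw$Z[fw$pr$i, , drop = FALSE]
  Zj <- fw$Z[fw$pr$j, , drop = FALSE]
  sgn <- sign(Zi - Zj)
  dZi <- d_prod * Zj + d_abs * sgn
  dZj <- d_prod * Zi - d_abs * sgn
  n <- nrow(fw$Z)
  dZ <- matrix(0, n, dz)
  for (c in seq_len(dz)) {
    dZ[, c] <- tabulate_sum(fw$pr$i, dZi[, c], n) +
      tabulate_sum(fw$pr$j, dZj[, c], n)
  }

  layer_grads <- vector("list", length(params$layers))
  dcur <- dZ
  for (l in rev(seq_along(params$layers))) {
    mode <- if (l == length(params$layers)) "average" else "concat"
    bk <- attention_layer_backward(dcur, fw$acts[[l]], params$layers[[l]],
                                   fw$caches[[l]], fw$mask, fw$K, mode,
                                   config$leaky_slope)
    layer_grads[[l]] <- bk$grads
    dcur <- bk$dX
  }
  list(layers = layer_grads,
       decoder = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

tabulate_sum <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Reconstruction loss of the autoencoder
#'
#' Mean squared error over upper-triangle edges between the predicted and
#' the max-normalized observed FC, plus `gamma` times the squared L2 norm
#' of all trainable parameters.
#'
#' @param pfc_edges Predicted edge vector (or `scfc_matrix`).
#' @param ofc_edges Observed (already normalized) edge vector or
#'   `scfc_matrix`.
#' @param params Parameter set (may be `NULL` for gamma = 0).
#' @param gamma Regularization weight.
#' @return Scalar loss.
#' @export
gmha_loss <- function(pfc_edges, ofc_edges, params = NULL, gamma = 0) {
  p <- if (inherits(pfc_edges, "scfc_matrix")) upper_triangle(pfc_edges)
       else as.numeric(pfc_edges)
  o <- if (inherits(ofc_edges, "scfc_matrix")) upper_triangle(ofc_edges)
       else as.numeric(ofc_edges)
  if (length(p) != length(o))
    stop_scfc("scfc_dimension_error", "edge counts differ")
  mean((p - o)^2) + if (gamma > 0) gamma * param_sq_norm(params) else 0
}

#' Participant-level cross-validation folds
#'
#' Deterministically partitions the cohort's subjects into `k` disjoint
#' folds; within each fold's development set (the other k-1 folds) a
#' 75/25 train/validation split supports parameter training and
#' hyperparameter tuning.
#'
#' @param coh An `scfc_cohort` (or character vector of ids).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param ids Optional explicit id subset (default: healthy subjects).
#' @return An `scfc_folds` object: list of folds, each with `test`,
#'   `train`, `val`.
#' @export
make_folds <- function(coh, k = 5, seed = 1, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (is.character(coh)) coh else
      vapply(Filter(function(s) s$group == "healthy", coh$subjects),
             function(s) s$id, "")
  }
  n <- length(ids)
  if (k > n) stop_scfc("scfc_config_error", "k = %d exceeds %d subjects", k, n)
  set.seed(seed)
  shuffled <- sample(ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  folds <- lapply(seq_len(k), function(f) {
    test <- shuffled[starts[f]:stops[f]]
    dev <- setdiff(shuffled, test)
    n_val <- max(1, round(0.25 * length(dev)))
    val <- dev[seq_len(n_val)]
    train <- setdiff(dev, val)
    list(test = test, train = train, val = val)
  })
  structure(list(folds = folds, k = k, seed = seed, ids = ids),
            class = "scfc_folds")
}

# Gather per-subject (features, adjacency, target edges) for training.
gmha_subject_data <- function(coh, id, band, weight, config) {
  sc <- get_matrix(coh, id, "SC", weight)
  ed <- get_matrix(coh, id, "ED")
  ofc <- normalize_matrix(get_matrix(coh, id, "FC", band))
  list(X = build_node_features(ed, sc, include_sc_row = config$include_sc_row),
       wv = sc$values, y = upper_triangle(ofc))
}

adam_step <- function(theta, grad, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}

# Core SGD loop over one training set. Returns params and per-epoch loss.
gmha_train_set <- function(data_list, config, seed) {
  F_in <- ncol(data_list[[1]]$X)
  params <- init_gmha_params(F_in, config)
  skel <- params
  theta <- flatten_params(params)
  state <- list(t = 0, m = numeric(length(theta)), v = numeric(length(theta)))
  set.seed(seed)
  nsub <- length(data_list)
  epoch_loss <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nsub)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tot <- 0
    for (bt in batches) {
      params <- unflatten_params(theta, skel)
      gsum <- NULL
      bloss <- 0
      for (si in bt) {
        dat <- data_list[[si]]
        fw <- gmha_forward(params, dat$X, dat$wv, config)
        resid <- fw$yhat - dat$y
        bloss <- bloss + mean(resid^2)
        dy <- matrix(2 * resid / length(resid), ncol = 1)
        g <- flatten_params(gmha_backward(params, fw, dy, config))
        gsum <- if (is.null(gsum)) g else gsum + g
      }
      grad <- gsum / length(bt) + 2 * config$gamma * theta
      upd <- adam_step(theta, grad, state, config$lr)
      theta <- upd$theta
      state <- upd$state
      tot <- tot + bloss
    }
    epoch_loss[ep] <- tot / nsub + config$gamma * sum(theta^2)
    if (!is.finite(epoch_loss[ep]))
      stop_scfc("scfc_training_error",
                "non-finite loss at epoch %d; try a lower learning rate", ep)
  }
  list(params = unflatten_params(theta, skel), epoch_loss = epoch_loss)
}

gmha_eval_set <- function(params, data_list, config) {
  mean(vapply(data_list, function(dat) {
    fw <- gmha_forward(params, dat$X, dat$wv, config)
    mean((fw$yhat - dat$y)^2)
  }, 0))
}

#' Train the GMHA-AE with participant-level cross-validation
#'
#' For each fold: optional grid search over `(heads, hidden, latent)`
#' combinations using only the development data (the validation split's
#' reconstruction loss selects), then training of the fold model on the
#' full development set; the held-out subjects are scored exactly once.
#' All randomness (fold split, initialization, batch order) derives from
#' the configured seed.
#'
#' @param coh An `scfc_cohort`.
#' @param band FC band to reconstruct.
#' @param weight SC edge-weight variant.
#' @param config A [gmha_config()].
#' @param folds An [make_folds()] result (default: 5 folds over the healthy
#'   subjects with the config seed).
#' @return An `scfc_gmha_model`: per-fold parameter sets, configs, training
#'   logs, fold assignment, and the out-of-fold correlation `records`.
#' @export
train_gmha <- function(coh, band, weight, config = gmha_config(),
                       folds = NULL) {
  if (is.null(folds)) folds <- make_folds(coh, k = 5, seed = config$seed)
  all_ids <- folds$ids
  data_all <- lapply(setNames(all_ids, all_ids), function(id)
    gmha_subject_data(coh, id, band, weight, config))
  grid <- config$grid
  fold_models <- vector("list", folds$k)
  records <- list()
  for (f in seq_len(folds$k)) {
    fd <- folds$folds[[f]]
    fseed <- subseed(config$seed, 1000L + f)
    cfg_f <- config
    if (!is.null(grid) && nrow(grid) > 1) {
      val_losses <- vapply(seq_len(nrow(grid)), function(gi) {
        cfg_g <- config
        cfg_g$heads <- grid$heads[gi]
        cfg_g$hidden <- grid$hidden[gi]
        cfg_g$latent <- grid$latent[gi]
        fit <- gmha_train_set(data_all[fd$train], cfg_g, fseed)
        gmha_eval_set(fit$params, data_all[fd$val], cfg_g)
      }, 0)
      gi <- which.min(val_losses)
      cfg_f$heads <- grid$heads[gi]
      cfg_f$hidden <- grid$hidden[gi]
      cfg_f$latent <- grid$latent[gi]
    }
    fit <- gmha_train_set(data_all[c(fd$train, fd$val)], cfg_f, fseed)
    fold_models[[f]] <- list(params = fit$params, config = cfg_f,
                             epoch_loss = fit$epoch_loss, fold = fd)
    for (id in fd$test) {
      dat <- data_all[[id]]
      fw <- gmha_forward(fit$params, dat$X, dat$wv, cfg_f)
      r <- stats::cor(dat$y, fw$yhat)
      records[[length(records) + 1]] <-
        data.frame(subject = id, model = "gmha", band = band, weight = weight,
                   r = r, fold = f, stringsAsFactors = FALSE)
    }
  }
  structure(list(fold_models = fold_models, folds = folds, band = band,
                 weight = weight, config = config,
                 records = do.call(rbind, records)),
            class = "scfc_gmha_model")
}

#' Encode a subject to its latent representation
#'
#' @param model An `scfc_gmha_model` (uses the first fold model unless
#'   `fold` given) or a single fold model.
#' @param coh Cohort containing the subject.
#' @param id Subject id.
#' @param fold Fold model index.
#' @return n x d_z latent matrix.
#' @export
encode <- function(model, coh, id, fold = 1) {
  fm <- if (inherits(model, "scfc_gmha_model")) model$fold_models[[fold]]
        else model
  cfg <- fm$config
  dat <- gmha_subject_data(coh, id, model$band, model$weight, cfg)
  gmha_forward(fm$params, dat$X, dat$wv, cfg)$Z
}

#' Decode a latent representation to a predicted FC matrix
#'
#' @param model As in [encode()].
#' @param Z n x d_z latent matrix.
#' @param parc Parcellation for the output matrix.
#' @param band Band tag of the output.
#' @param fold Fold model index.
#' @return A symmetric zero-diagonal FC `scfc_matrix`.
#' @export
decode <- function(model, Z, parc, band = "alpha", fold = 1) {
  fm <- if (inherits(model, "scfc_gmha_model")) model$fold_models[[fold]]
        else model
  dec <- fm$params$decoder
  pr <- pair_indices(nrow(Z))
  Zi <- Z[pr$i, , drop = FALSE]; Zj <- Z[pr$j, , drop = FALSE]
  Hd <- cbind(Zi * Zj, abs(Zi - Zj))
  h1 <- elu(sweep(Hd %*% dec$W1, 2, dec$b1[1, ], "+"))
  yhat <- as.numeric(h1 %*% dec$W2 + dec$b2[1])
  conn_matrix(from_upper_triangle(yhat, nrow(Z)), "FC", band, parc)
}

#' Score out-of-cohort subjects with a trained model
#'
#' Predictions for subjects never seen in any fold's development data (the
#' psychosis participants, in the study design) are averaged over the five
#' fold models. Passing a subject that appears in any fold raises an error
#' unless `allow_seen = TRUE`.
#'
#' @param model An `scfc_gmha_model`.
#' @param coh Cohort containing the subjects.
#' @param ids Subject ids to score.
#' @param allow_seen Override the leakage guard.
#' @return List with `records` (data.frame subject, model, band, weight, r)
#'   and `pfc` (named list of predicted `scfc_matrix`).
#' @export
predict_external <- function(model, coh, ids, allow_seen = FALSE) {
  seen <- unique(unlist(lapply(model$fold_models, function(fm)
    c(fm$fold$train, fm$fold$val, fm$fold$test))))
  bad <- intersect(ids, seen)
  if (length(bad) > 0 && !allow_seen)
    stop_scfc("scfc_leakage_error",
              "subject(s) %s were seen during training; set allow_seen=TRUE to override",
              paste(bad, collapse = ", "))
  records <- list()
  pfcs <- list()
  for (id in ids) {
    preds <- lapply(model$fold_models, function(fm) {
      dat <- gmha_subject_data(coh, id, model$band, model$weight, fm$config)
      list(yhat = gmha_forward(fm$params, dat$X, dat$wv, fm$config)$yhat,
           y = dat$y)
    })
    yhat <- Reduce(`+`, lapply(preds, `[[`, "yhat")) / length(preds)
    y <- preds[[1]]$y
    r <- stats::cor(y, yhat)
    records[[length(records) + 1]] <-
      data.frame(subject = id, model = "gmha", band = model$band,
                 weight = model$weight, r = r, stringsAsFactors = FALSE)
    pfcs[[id]] <- conn_matrix(from_upper_triangle(yhat, coh$parcellation$n),
                              "FC", model$band, coh$parcellation)
  }
  list(records = do.call(rbind, records), pfc = pfcs)
}

#' Export latent coordinates and prediction errors
#'
#' Flat table of per-node latent coordinates for each subject (suitable for
#' any external embedding tool) plus the per-subject prediction error
#' `1 - r`.
#'
#' @param model An `scfc_gmha_model`.
#' @param coh Cohort.
#' @param ids Subjects (default: all fold subjects).
#' @param fold Fold model used for encoding.
#' @return List with `latent` (data.frame: subject, node, z1..z_dz) and
#'   `errors` (data.frame: subject, error).
#' @export
export_latent <- function(model, coh, ids = NULL, fold = 1) {
  if (is.null(ids)) ids <- model$folds$ids
  fm <- model$fold_models[[fold]]
  rows <- list()
  errs <- list()
  for (id in ids) {
    dat <- gmha_subject_data(coh, id, model$band, model$weight, fm$config)
    fw <- gmha_forward(fm$params, dat$X, dat$wv, fm$config)
    df <- as.data.frame(fw$Z)
    names(df) <- paste0("z", seq_len(ncol(fw$Z)))
    df <- cbind(subject = id, node = coh$parcellation$labels, df)
    rows[[id]] <- df
    errs[[id]] <- data.frame(subject = id,
                             error = 1 - stats::cor(dat$y, fw$yhat),
                             stringsAsFactors = FALSE)
  }
  list(latent = do.call(rbind, rows), errors = do.call(rbind, errs))
}
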