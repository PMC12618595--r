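# Independent brute-force oracles used to verify the compiled graph
# algorithms and the exact small-sample tests.

# Enumerate every simple path between all node pairs of a small weighted
# graph; return the shortest-path-length matrix, the lexicographically
# smallest minimal path per ordered pair, and search information (both
# memory variants) computed as explicit probability products.
enum_paths_oracle <- function(W) {
  n <- nrow(W)
  L <- matrix(Inf, n, n)
  pos <- W > 0
  L[pos] <- 1 / W[pos]
  diag(L) <- 0
  strength <- rowSums(W)

  best_len <- matrix(Inf, n, n)
  best_path <- vector("list", n * n)
  for (s in seq_len(n)) {
    dfs <- function(path, len) {
      u <- path[length(path)]
      t <- u
      if (length(path) > 1) {
        key <- (s - 1) * n + t
        if (len < best_len[s, t] - 1e-12 ||
            (abs(len - best_len[s, t]) <= 1e-12 &&
             lex_less(path, best_path[[key]]))) {
          best_len[s, t] <<- len
          best_path[[key]] <<- path
        }
      }
      for (v in seq_len(n)) {
        if (W[u, v] > 0 && !(v %in% path)) dfs(c(path, v), len + L[u, v])
      }
    }
    dfs(s, 0)
  }
  diag(best_len) <- 0

  si_dir <- function(memory) {
    out <- matrix(NA_real_, n, n)
    diag(out) <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t) next
      p <- best_path[[(s - 1) * n + t]]
      if (is.null(p)) next
      pr <- 1
      for (m in seq_len(length(p) - 1)) {
        denom <- strength[p[m]]
        if (memory && m > 1) denom <- denom - W[p[m], p[m - 1]]
        pr <- pr * W[p[m], p[m + 1]] / denom
      }
      out[s, t] <- -log2(pr)
    }
    out
  }
  sym <- function(M) { S <- (M + t(M)) / 2; diag(S) <- 0; S }
  list(spl = best_len, paths = best_path,
       si_nomem = sym(si_dir(FALSE)), si_mem = sym(si_dir(TRUE)),
       si_nomem_dir = si_dir(FALSE), si_mem_dir = si_dir(TRUE))
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Random connected weighted graph on n nodes (retry until connected).
random_connected_graph <- function(n, p = 0.5, wmin = 0.2, wmax = 2) {
  repeat {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on <- runif(length(ut)) < p
    W[ut[on]] <- runif(sum(on), wmin, wmax)
    W <- W + t(W)
    if (all(rowSums(W) > 0) && max(components_r(W)) == 1) return(W)
  }
}

components_r <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    q <- s; comp[s] <- cur
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      nb <- which(adj[u, ] > 0 & comp == 0L)
      comp[nb] <- cur; q <- c(q, nb)
    }
  }
  comp
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments,
# mirroring the doubled-tail convention of the exact distribution.
enum_mannwhitney_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idxs <- combn(length(pool), na)
  u_of <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(idxs, 2, u_of)
  u_obs <- u_of(seq_len(na))
  pl <- mean(us <= u_obs + 1e-12)
  pu <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(pl, pu))
}

# All permutations of 1..n (for rank-statistic enumeration oracles).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}

# Exact permutation p for the difference of group means by enumeration.
enum_permutation_p <- function(a, b, sided = "two") {
  pool <- c(a, b)
  na <- length(a)
  idxs <- combn(length(pool), na)
  st <- apply(idxs, 2, function(idx) mean(pool[idx]) - mean(pool[-idx]))
  obs <- mean(a) - mean(b)
  eps <- 1e-12 * (1 + abs(obs))
  if (sided == "one") mean(st >= obs - eps) else
    mean(abs(st) >= abs(obs) - eps)
}
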