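# Independent oracles, deliberately naive: brute-force enumeration and
# definition-level implementations against which the package code is checked.

# random symmetric nonnegative matrix with zero diagonal
rand_sym_matrix <- function(n, density = 1, seed = NULL, wmin = 0.5,
                            wmax = 5) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- runif(nrow(ut), wmin, wmax)
  w[runif(nrow(ut)) > density] <- 0
  W[ut] <- w
  W[ut[, c(2, 1)]] <- w
  W
}

# betweenness by exhaustive simple-path enumeration on the 1/w length graph,
# fractional credit across co-minimal paths; feasible for n <= 8
bf_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- list()
    rec <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- list(nodes = visited, len = len)
        return(invisible())
      }
      for (u in seq_len(n)) {
        if (W[v, u] > 0 && !(u %in% visited))
          rec(u, c(visited, u), len + L[v, u])
      }
    }
    rec(s, s, 0)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    mn <- min(lens)
    sel <- which(lens <= mn + tol * max(1, mn))
    for (idx in sel) {
      inter <- setdiff(paths[[idx]]$nodes, c(s, t))
      bc[inter] <- bc[inter] + 1 / length(sel)
    }
  }
  bc
}

# clustering coefficient by the direct triple loop over ordered (j, h)
bf_clustering <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  mx <- max(W)
  if (mx == 0) return(out)
  Wh <- W / mx
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h &&
          W[i, j] > 0 && W[i, h] > 0 && W[j, h] > 0)
        s <- s + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# proportional-threshold oracle: exhaustive sort of upper-triangle entries
bf_threshold <- function(W, S) {
  n <- nrow(W)
  k <- floor(S * n * (n - 1) / 2)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2], w = W[ut])
  df <- df[df$w > 0, ]
  df <- df[order(-df$w, df$i, df$j), ]
  keep <- head(df, k)
  out <- matrix(0, n, n)
  out[cbind(keep$i, keep$j)] <- keep$w
  out[cbind(keep$j, keep$i)] <- keep$w
  out
}

# BH adjusted values straight from the step-up definition (double loop)
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# group-coefficient t by explicit normal equations on the full design
bf_ancova_t <- function(y, g, covs = NULL) {
  X <- cbind(1, g, covs)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  list(t = as.numeric(beta[2] / se), df = df,
       d = as.numeric(beta[2] / sqrt(s2)))
}

# exhaustive permutation p over all label assignments (small n only)
bf_exhaustive_perm_p <- function(y, g, covs = NULL) {
  n <- length(y)
  idx_mdd <- utils::combn(n, sum(g == "MDD"))
  t_obs <- bf_ancova_t(y, as.integer(g == "MDD"), covs)$t
  tvals <- apply(idx_mdd, 2, function(ix) {
    gi <- integer(n)
    gi[ix] <- 1L
    bf_ancova_t(y, gi, covs)$t
  })
  mean(abs(tvals) >= abs(t_obs) - 1e-12)
}

# reference nodal metrics from networkx (independent published toolbox
# implementation of the same definitions; python is part of the image)
nx_reference <- function(W) {
  mf <- tempfile(fileext = ".tsv")
  utils::write.table(W, mf, sep = "\t", row.names = FALSE, col.names = FALSE)
  sf <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import numpy as np, networkx as nx",
    "W = np.loadtxt(sys.argv[1])",
    "G = nx.from_numpy_array(W)",
    "for u, v, d in G.edges(data=True): d['dist'] = 1.0 / d['weight']",
    "bt = nx.betweenness_centrality(G, weight='dist', normalized=False)",
    "cl = nx.clustering(G, weight='weight')",
    "n = W.shape[0]",
    "print(json.dumps({'betweenness': [bt[i] for i in range(n)],",
    "                  'clustering': [cl[i] for i in range(n)]}))"), sf)
  out <- system2("python", c(sf, mf), stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(out[length(out)])
}
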