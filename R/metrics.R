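#' Proportional sparsity thresholding
#'
#' Retains the `k = floor(S * N * (N - 1) / 2)` strongest upper-triangle
#' edges of a weighted matrix and zeroes the rest, keeping the surviving
#' weights (no binarization). Matching edge counts across subjects is what
#' makes nodal features comparable between individuals with different raw
#' network densities. Ties at the cutoff weight are broken deterministically
#' by ascending (row, column) index of the upper-triangle entry.
#'
#' @param W validated symmetric weight matrix.
#' @param S sparsity fraction in (0, 1].
#' @return thresholded symmetric matrix.  If the matrix has fewer than `k`
#'   nonzero edges, all nonzero edges are retained and a warning is issued.
#' @export
threshold_proportional <- function(W, S) {
  if (!is.numeric(S) || length(S) != 1 || S <= 0 || S > 1)
    stop("S must be a single value in (0, 1]")
  n <- nrow(W)
  k <- floor(S * n * (n - 1) / 2)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  nz <- which(w > 0)
  if (length(nz) < k) {
    warning(sprintf(
      "matrix density below requested sparsity: %d nonzero edges < k = %d; retaining all",
      length(nz), k))
    keep <- nz
  } else {
    # order by descending weight, ties by ascending (row, col)
    ord <- nz[order(-w[nz], ut[nz, 1], ut[nz, 2])]
    keep <- ord[seq_len(k)]
  }
  out <- matrix(0, n, n)
  ik <- ut[keep, , drop = FALSE]
  out[ik] <- w[keep]
  out[ik[, c(2, 1), drop = FALSE]] <- w[keep]
  out
}

#' Node strength
#'
#' Sum of the weights of all links connected to each node; high values mark
#' network hubs with strong direct influence on the rest of the network.
#'
#' @param W symmetric weight matrix.
#' @return numeric vector of length N.
#' @export
node_strength <- function(W) rowSums(W)

#' Weighted betweenness centrality
#'
#' Fractional count of shortest paths between all other node pairs that pass
#' through each node, on the length graph `l_ij = 1 / w_ij` (a stronger
#' connection is a shorter path). Unnormalized; each unordered pair is
#' counted once; disconnected pairs contribute zero. Backed by the Brandes
#' algorithm (igraph); the edge-to-length transform is isolated here so an
#' alternative (e.g. `-log`) could be substituted.
#'
#' @param W symmetric weight matrix with at least one positive edge.
#' @return numeric vector of length N.
#' @export
betweenness_w <- function(W) {
  if (all(W == 0)) stop("betweenness undefined on an all-zero matrix")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                      normalized = FALSE)
}

#' Weighted clustering coefficient
#'
#' Geometric-mean triangle intensity: with weights normalized by the matrix
#' maximum, `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`,
#' where `k_i` counts nonzero neighbors; `C_i = 0` when `k_i < 2`. On binary
#' graphs this reduces to the classic triangle fraction
#' `2 T_i / (k_i (k_i - 1))`. Values lie in [0, 1] and quantify how strongly
#' a node's neighbors interconnect (its embedding in a cluster).
#'
#' @param W symmetric weight matrix.
#' @return numeric vector of length N, in \[0, 1\].
#' @export
clustering_coef_w <- function(W) {
  mx <- max(W)
  if (mx == 0) return(rep(0, nrow(W)))
  Wh <- (W / mx)^(1 / 3)
  cyc <- diag(Wh %*% Wh %*% Wh)     # 2 * sum over ordered (j, h) triangles
  k <- rowSums(W > 0)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, cyc / denom, 0)
  unname(out)
}

#' The default sparsity grid
#'
#' 21 thresholds from 10% to 30% of the strongest connections in steps of
#' 1%, the range over which nodal features are summarized by their area
#' under the curve.
#'
#' @param from,to,by grid bounds and step.
#' @return strictly increasing numeric vector in (0, 1].
#' @export
sparsity_grid <- function(from = 0.10, to = 0.30, by = 0.01) {
  g <- seq(from, to, by = by)
  validate_grid(g)
  g
}

validate_grid <- function(grid) {
  if (any(grid <= 0) || any(grid > 1)) stop("sparsity values must be in (0, 1]")
  if (any(diff(grid) <= 0)) stop("sparsity grid must be strictly increasing")
  invisible(grid)
}

#' Nodal metric curves across the sparsity grid
#'
#' For each threshold `S` in the grid, applies [threshold_proportional()]
#' and computes the requested nodal metrics on the thresholded matrix.
#'
#' @param W symmetric weight matrix.
#' @param grid sparsity grid (see [sparsity_grid()]).
#' @param metrics subset of `c("strength", "betweenness", "clustering")`.
#' @return named list of `N x length(grid)` matrices, one per metric.
#' @export
metric_curves <- function(W, grid = sparsity_grid(),
                          metrics = c("strength", "betweenness", "clustering")) {
  validate_grid(grid)
  metrics <- match.arg(metrics, several.ok = TRUE)
  fns <- list(strength = node_strength, betweenness = betweenness_w,
              clustering = clustering_coef_w)
  out <- lapply(metrics, function(m) matrix(NA_real_, nrow(W), length(grid)))
  names(out) <- metrics
  for (j in seq_along(grid)) {
    Wt <- threshold_proportional(W, grid[j])
    for (m in metrics) out[[m]][, j] <- fns[[m]](Wt)
  }
  out
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of each region's metric curve over the sparsity
#' grid, giving a summary feature independent of any single threshold
#' choice. For the default 21-point grid the integration width is 0.20.
#'
#' @param curve `N x length(grid)` matrix of metric values.
#' @param grid sparsity grid of length >= 2.
#' @return numeric vector of length N.
#' @export
auc_over_thresholds <- function(curve, grid) {
  validate_grid(grid)
  if (length(grid) < 2) stop("grid must have at least 2 points")
  if (ncol(curve) != length(grid)) stop("curve columns must match grid length")
  h <- diff(grid)
  mid <- (curve[, -1, drop = FALSE] + curve[, -ncol(curve), drop = FALSE]) / 2
  as.numeric(mid %*% h)
}

#' AUC-summarized nodal features for every subject
#'
#' Runs [metric_curves()] and [auc_over_thresholds()] for each subject of a
#' cohort, producing the long feature table used by the inference stages.
#'
#' @param cohort a `limb_cohort`.
#' @param grid sparsity grid.
#' @param metrics metrics to compute (betweenness is the expensive one).
#' @return data.frame with columns `subject_id`, `region_index`, `region`,
#'   `metric`, `auc`.
#' @export
compute_nodal_features <- function(cohort, grid = sparsity_grid(),
                                   metrics = c("strength", "betweenness",
                                               "clustering")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rt <- cohort$region_table
  res <- lapply(seq_along(cohort$matrices), function(i) {
    curves <- metric_curves(cohort$matrices[[i]], grid, metrics)
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(subject_id = cohort$subjects$subject_id[i],
                 region_index = rt$region_index, region = rt$name,
                 metric = m, auc = auc_over_thresholds(curves[[m]], grid),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Subjects-by-regions matrix of one metric's AUC features
#' @param features output of [compute_nodal_features()].
#' @param metric one metric name.
#' @param cohort the cohort (defines subject and region order).
#' @return numeric matrix, subjects in rows, regions in columns.
#' @export
feature_matrix <- function(features, metric, cohort) {
  f <- features[features$metric == metric, ]
  n_s <- nrow(cohort$subjects); n_r <- nrow(cohort$region_table)
  m <- matrix(NA_real_, n_s, n_r,
              dimnames = list(cohort$subjects$subject_id,
                              cohort$region_table$name))
  m[cbind(match(f$subject_id, cohort$subjects$subject_id),
          f$region_index + 1L)] <- f$auc
  m
}
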