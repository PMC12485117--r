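#' Functional connectivity matrix and graph
#'
#' Pairwise Pearson correlation between node traces (regions or voxels),
#' optionally thresholded to the top fraction of correlations as edges.
#' Region-level networks conventionally keep all edges of the weighted
#' matrix; voxel-level networks keep the top 30% correlations.
#'
#' @param traces nodes x frames matrix (frames typically concatenated over
#'   stimulation windows, or a resting segment).
#' @param edge_rule `"all"` or `"top_fraction"`.
#' @param q fraction of node pairs kept as edges under `"top_fraction"`
#'   (count is `ceiling(q * n_pairs)`; ties at the cutoff broken by node-id
#'   order).
#' @param node_meta optional data.frame (one row per node) with columns such
#'   as `region`, `olfactory`, `x`, `y`, `z`.
#' @param state `"stimulation"` or `"resting"` tag.
#' @return An object of class `fc_matrix` with elements `corr` (symmetric,
#'   unit diagonal; zero-variance nodes give NA off-diagonals and are
#'   excluded from edge ranking), `edges` (data.frame `from`, `to`,
#'   `weight`), `graph` (weighted undirected igraph), `node_meta`, `state`.
#' @export
build_fc <- function(traces, edge_rule = c("all", "top_fraction"), q = 0.30,
                     node_meta = NULL, state = "stimulation") {
  edge_rule <- match.arg(edge_rule)
  stopifnot(ncol(traces) >= 2)
  n <- nrow(traces)
  M <- suppressWarnings(cor(t(traces)))
  diag(M) <- 1
  ut <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[ut]
  valid <- is.finite(w)
  if (edge_rule == "all") {
    keep <- which(valid)
  } else {
    n_pairs <- sum(valid)
    k <- ceiling(q * n_pairs)
    ord <- order(-w, ut[, 1], ut[, 2], na.last = TRUE)
    ord <- ord[valid[ord]]
    keep <- ord[seq_len(min(k, length(ord)))]
  }
  edges <- data.frame(from = ut[keep, 1], to = ut[keep, 2], weight = w[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  structure(list(corr = M, edges = edges, graph = g,
                 node_meta = node_meta, state = state),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("Functional connectivity (", x$state, "): ", nrow(x$corr), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# Graph restricted to positive-weight edges (community detection operates on
# positive couplings; negative correlations are not valid modularity weights).
positive_graph <- function(fc) {
  e <- fc$edges[fc$edges$weight > 0, , drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = seq_len(nrow(fc$corr))))
}

#' Community detection on a functional connectivity network
#'
#' Runs seeded Louvain and greedy modularity maximization on the
#' positive-weight graph (isolated nodes become singleton communities) and
#' reports both partitions together with their adjusted-Rand agreement.
#'
#' @param fc an `fc_matrix` (or an igraph graph).
#' @param method `"both"` (default), `"louvain"`, or `"greedy"`.
#' @param seed integer seed for the Louvain heuristic.
#' @return For a single method, a list with `assignment` (community id per
#'   node), `method`, `modularity`. For `"both"`, a list `louvain`,
#'   `greedy`, `agreement` (adjusted Rand index).
#' @export
detect_communities <- function(fc, method = c("both", "louvain", "greedy"),
                               seed = 1L) {
  method <- match.arg(method)
  g <- if (inherits(fc, "fc_matrix")) positive_graph(fc) else fc
  if (igraph::vcount(g) == 0) stop("empty graph")
  run <- function(m) {
    comm <- if (m == "louvain") {
      with_seed(seed, igraph::cluster_louvain(g, resolution = 1))
    } else {
      igraph::cluster_fast_greedy(igraph::simplify(g))
    }
    list(assignment = igraph::membership(comm), method = m,
         modularity = igraph::modularity(comm))
  }
  if (method != "both") return(run(method))
  lv <- run("louvain"); gr <- run("greedy")
  list(louvain = lv, greedy = gr,
       agreement = adjusted_rand_index(lv$assignment, gr$assignment))
}

# Community holding the most olfactory nodes.
olfactory_community <- function(assignment, olfactory) {
  stopifnot(length(assignment) == length(olfactory))
  if (!any(olfactory)) stop("no olfactory nodes")
  counts <- tapply(olfactory, assignment, sum)
  as.integer(names(counts)[which.max(counts)])
}

#' Community ratio: edge-weight share of the olfactory community
#'
#' Share of total positive edge weight carried by edges with both endpoints
#' inside the community containing most olfactory nodes.
#'
#' @param fc an `fc_matrix`.
#' @param assignment community id per node.
#' @param olfactory logical flag per node; the target community is the one
#'   holding the most olfactory nodes (or pass `target` directly).
#' @param target optional explicit community id.
#' @return proportion in `[0, 1]`.
#' @export
community_ratio <- function(fc, assignment, olfactory = NULL, target = NULL) {
  e <- fc$edges[fc$edges$weight > 0, , drop = FALSE]
  if (is.null(target)) target <- olfactory_community(assignment, olfactory)
  total <- sum(e$weight)
  if (total == 0) return(0)
  inside <- assignment[e$from] == target & assignment[e$to] == target
  sum(e$weight[inside]) / total
}

#' Weighted node degrees of a connectivity network
#'
#' Degree of a node is the sum of the (signed) weights of its incident
#' edges; the distribution is exposed for two-sample comparisons across
#' signals and states.
#'
#' @param fc an `fc_matrix`.
#' @return list with `degree` (per node), `average_degree`, and
#'   `distribution` (the degree sample).
#' @export
node_degrees <- function(fc) {
  n <- nrow(fc$corr)
  deg <- numeric(n)
  e <- fc$edges
  for (i in seq_len(nrow(e))) {
    deg[e$from[i]] <- deg[e$from[i]] + e$weight[i]
    deg[e$to[i]] <- deg[e$to[i]] + e$weight[i]
  }
  list(degree = deg, average_degree = mean(deg), distribution = deg)
}

#' Deflation ratio of a correlation matrix
#'
#' `(M - mean(M)) / mean(M)` elementwise, where the mean is taken over the
#' off-diagonal entries (the unit diagonal is non-informative). Invariant to
#' positive rescaling of `M`.
#'
#' @param M symmetric correlation matrix (or `fc_matrix`).
#' @return matrix of the same shape.
#' @export
deflation_ratio <- function(M) {
  if (inherits(M, "fc_matrix")) M <- M$corr
  m <- mean(M[row(M) != col(M)])
  if (!is.finite(m) || m == 0) stop("undefined: off-diagonal mean is zero")
  (M - m) / m
}

#' Dual-channel difference matrix
#'
#' Difference between the deflation ratios of the neurochemical and the
#' calcium connectivity matrices,
#' `Delta = (M_N - mean(M_N))/mean(M_N) - (M_C - mean(M_C))/mean(M_C)`.
#' Positive entries mark voxel pairs whose relative coupling is stronger in
#' the neurochemical channel than in the calcium channel.
#'
#' @param M_N neurochemical-channel correlation matrix (or `fc_matrix`).
#' @param M_C calcium-channel correlation matrix (or `fc_matrix`), same node
#'   set and ordering.
#' @param clusters optional cluster label per node, conventionally the
#'   Louvain communities of the calcium-channel network.
#' @return An object of class `diff_matrix`: list with `delta` and
#'   `clusters`.
#' @export
difference_matrix <- function(M_N, M_C, clusters = NULL) {
  a <- if (inherits(M_N, "fc_matrix")) M_N$corr else M_N
  b <- if (inherits(M_C, "fc_matrix")) M_C$corr else M_C
  if (!all(dim(a) == dim(b))) stop("alignment error: node sets differ")
  structure(list(delta = deflation_ratio(a) - deflation_ratio(b),
                 clusters = clusters),
            class = "diff_matrix")
}

#' Complementation metric Delta_w+ - Delta_b+
#'
#' Mean of the positive difference-matrix entries with both endpoints in the
#' same cluster, minus the mean of the positive entries spanning clusters.
#' A class with no positive entries contributes 0. Small values indicate
#' that the neurochemical channel's extra coupling lies between the
#' calcium-defined clusters ("complementation"); large values indicate it
#' merely emphasizes the existing within-cluster structure.
#'
#' @param delta a `diff_matrix` (with clusters) or a plain matrix.
#' @param clusters cluster label per node (needed if `delta` is a matrix).
#' @return scalar `Delta_w+ - Delta_b+`.
#' @export
complementation_metric <- function(delta, clusters = NULL) {
  if (inherits(delta, "diff_matrix")) {
    clusters <- clusters %||% delta$clusters
    delta <- delta$delta
  }
  if (is.null(clusters)) stop("cluster labels required")
  if (length(unique(clusters)) < 2) stop("undefined for a single cluster")
  off <- row(delta) != col(delta)
  same <- outer(clusters, clusters, "==")
  pos_mean <- function(x) if (any(x > 0)) mean(x[x > 0]) else 0
  pos_mean(delta[off & same]) - pos_mean(delta[off & !same])
}

#' Local and global clustering coefficient
#'
#' On the unweighted (thresholded) graph: `C_v = 2 E(v) / (k_v (k_v - 1))`
#' with `E(v)` the number of edges among the neighbors of `v`; nodes of
#' degree < 2 have `C_v = 0`. The global coefficient is the mean over all
#' nodes.
#'
#' @param fc an `fc_matrix` (its edges are used as an unweighted simple
#'   graph) or an adjacency matrix.
#' @return list with `local` (per node) and `global`.
#' @export
clustering_coefficient <- function(fc) {
  if (inherits(fc, "fc_matrix")) {
    n <- nrow(fc$corr)
    A <- matrix(0, n, n)
    A[cbind(fc$edges$from, fc$edges$to)] <- 1
    A <- pmax(A, t(A))
  } else {
    A <- (fc != 0) * 1
    diag(A) <- 0
    A <- pmax(A, t(A))
  }
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A)           # 2 * E(v) counted twice = 2E(v)
  denom <- k * (k - 1)
  local <- ifelse(denom > 0, tri / denom, 0)
  list(local = local, global = mean(local))
}

#' 1-D Wasserstein-1 distance between two samples
#'
#' Computed as the integral of the absolute difference of the two empirical
#' CDFs (equivalently the quantile-function formula).
#'
#' @param a,b non-empty numeric samples.
#' @return non-negative distance; 0 iff the empirical distributions match.
#' @export
wasserstein_distance <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  grid <- sort(c(a, b))
  if (length(grid) < 2) return(0)
  x <- grid[-length(grid)]
  dx <- diff(grid)
  Fa <- vapply(x, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(x, function(v) mean(b <= v), numeric(1))
  sum(abs(Fa - Fb) * dx)
}

#' Energy distance between two samples
#'
#' `sqrt(2 E|X-Y| - E|X-X'| - E|Y-Y'|)` over all sample pairs.
#'
#' @param a,b non-empty numeric samples.
#' @return non-negative distance; 0 iff the empirical distributions match.
#' @export
energy_distance <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  A <- mean(abs(outer(a, b, "-")))
  B <- mean(abs(outer(a, a, "-")))
  C <- mean(abs(outer(b, b, "-")))
  sqrt(max(2 * A - B - C, 0))
}

#' Distance between two degree-centrality distributions
#'
#' @param dist_a,dist_b degree-centrality samples (e.g. from
#'   [node_degrees()]).
#' @param metric `"wasserstein"` or `"energy"`.
#' @return non-negative scalar distance.
#' @export
centrality_distance <- function(dist_a, dist_b,
                                metric = c("wasserstein", "energy")) {
  metric <- match.arg(metric)
  if (metric == "wasserstein") wasserstein_distance(dist_a, dist_b)
  else energy_distance(dist_a, dist_b)
}

#' Ensemble functional connectivity and weighted coverage
#'
#' Functional connectivity over the union of odor-tuned voxel ensembles,
#' hierarchically ordered for display (average linkage on `1 - r`), plus,
#' per odor: the top-fraction strongest edges among that odor's ensemble and
#' the weighted coverage (mean over those edges of Euclidean voxel distance
#' times correlation).
#'
#' @param trials a `trial_tensor` (trial windows are concatenated into one
#'   trace per voxel).
#' @param tuned_sets named list per odor of tuned voxel indices (from
#'   [odor_tuning()] masks).
#' @param coords voxels x 3 coordinate matrix for the full voxel set.
#' @param top_edge_fraction fraction of strongest edges mapped (default top
#'   10%).
#' @return list with `fc` (fc_matrix over the union, in hierarchical display
#'   order), `order` (voxel indices in display order), `per_odor` (edges and
#'   `weighted_coverage` per odor).
#' @export
ensemble_fc <- function(trials, tuned_sets, coords, top_edge_fraction = 0.10) {
  stopifnot(inherits(trials, "trial_tensor"))
  union_vox <- sort(unique(unlist(tuned_sets)))
  if (length(union_vox) < 2) stop("need at least 2 tuned voxels")
  d <- dim(trials$values)
  traces <- function(vox) {
    x <- trials$values[, vox, , drop = FALSE]
    t(apply(x, 2, function(m) as.vector(t(m))))
  }
  tr_union <- matrix(aperm(trials$values[, union_vox, , drop = FALSE], c(2, 1, 3)),
                     nrow = length(union_vox))
  fc <- build_fc(tr_union, edge_rule = "all")
  hc <- stats::hclust(stats::as.dist(1 - fc$corr), method = "average")
  per_odor <- lapply(tuned_sets, function(vox) {
    vox <- sort(unique(vox))
    if (length(vox) < 2) return(list(edges = NULL, weighted_coverage = NA_real_))
    pos <- match(vox, union_vox)
    sub <- fc$corr[pos, pos, drop = FALSE]
    ut <- which(upper.tri(sub), arr.ind = TRUE)
    w <- sub[ut]
    k <- max(1, ceiling(top_edge_fraction * length(w)))
    ord <- order(-w, ut[, 1], ut[, 2])[seq_len(k)]
    i <- vox[ut[ord, 1]]; j <- vox[ut[ord, 2]]
    dist_ij <- sqrt(rowSums((coords[i, , drop = FALSE] -
                             coords[j, , drop = FALSE])^2))
    edges <- data.frame(from = i, to = j, weight = w[ord],
                        distance = dist_ij)
    list(edges = edges,
         weighted_coverage = mean(dist_ij * w[ord]))
  })
  list(fc = fc, order = union_vox[hc$order], per_odor = per_odor)
}
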