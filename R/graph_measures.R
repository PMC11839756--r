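#' Weighted graph measures for structural covariance networks
#'
#' All measures follow the standard weighted-network conventions for
#' correlation-based brain graphs (Rubinov & Sporns definitions): edge
#' lengths are reciprocal weights `l_ij = 1 / w_ij`, triangles use the
#' Onnela geometric mean of max-normalized weights, and betweenness is
#' normalized by `(N - 1)(N - 2)`.
#'
#' @name graph-measures
#' @keywords internal
NULL

#' Exact measure names, global and nodal
#'
#' These strings are the row labels used in the result tables.
#' @return Character vector of measure names.
#' @export
global_measure_names <- function() {
  c("Average degree", "Average strength", "Radius", "Diameter",
    "Eccentricity", "Characteristic path length", "Global efficiency",
    "Clustering", "Transitivity", "Modularity", "Assortativity",
    "Small-worldness")
}

#' @rdname global_measure_names
#' @export
nodal_measure_names <- function() {
  c("Betweenness centrality", "Closeness centrality", "Clustering nodes",
    "Degree", "Eccentricity", "Global efficiency nodes",
    "Local efficiency nodes", "Participation", "Path length", "Strength",
    "Triangles", "Within module degree z-score")
}

.as_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shortest weighted path lengths
#'
#' Dijkstra shortest paths on edge lengths `1 / w_ij`; unreachable pairs
#' are `Inf`, the diagonal 0.
#'
#' @param net A `group_network` (or bare weight matrix).
#' @return Symmetric distance matrix.
#' @export
shortest_paths_matrix <- function(net) {
  w <- if (inherits(net, "group_network")) net$weights else as.matrix(net)
  .dist_from_w(w)
}

.dist_from_w <- function(w) {
  n <- nrow(w)
  if (all(w == 0)) {
    d <- matrix(Inf, n, n, dimnames = dimnames(w))
    diag(d) <- 0
    return(d)
  }
  g <- .as_igraph(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

# Onnela triangle intensity per node: t_i = diag(What^3) / 2 with
# What = (w / max(w))^(1/3).
.triangles <- function(w) {
  mx <- max(w)
  if (mx == 0) return(rep(0, nrow(w)))
  cw <- (w / mx)^(1 / 3)
  diag(cw %*% cw %*% cw) / 2
}

#' Reciprocal-of-path-length closeness centrality
#'
#' The package's closeness convention: a node's closeness centrality is the
#' reciprocal of its nodal path length (the mean shortest weighted distance
#' to the other nodes), so `closeness * path length = 1` wherever the path
#' length is finite.
#'
#' @param path_length Nodal path length(s), > 0.
#' @return Closeness value(s).
#' @export
#' @examples
#' closeness_centrality(4.64)
closeness_centrality <- function(path_length) {
  ifelse(is.finite(path_length) & path_length > 0, 1 / path_length,
         NA_real_)
}

#' Modularity of a partition
#'
#' Weighted Newman modularity
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * [c_i == c_j]` with
#' `m = sum(w)/2`.
#'
#' @param w Weight matrix.
#' @param membership Integer community labels, one per node.
#' @return Scalar Q (0 for an empty network).
#' @export
modularity_q <- function(w, membership) {
  w <- as.matrix(w)
  two_m <- sum(w)
  if (two_m == 0) return(0)
  s <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(s, s) / two_m) * same) / two_m
}

#' Louvain community detection with restarts
#'
#' Weighted-modularity optimization (Louvain), best partition of
#' `n_restarts` seeded runs. The returned partition is the single source of
#' community labels for modularity, participation and within-module degree
#' z-score on that network. Deterministic given `seed`.
#'
#' @param net A `group_network` or weight matrix.
#' @param seed Integer RNG seed.
#' @param n_restarts Number of restarts (default 10).
#' @return A `module_partition`: list with `membership` (named integer
#'   vector), `q` (modularity), `seed`.
#' @export
detect_modules <- function(net, seed = 1L, n_restarts = 10L) {
  w <- if (inherits(net, "group_network")) net$weights else as.matrix(net)
  n <- nrow(w)
  nodes <- if (!is.null(rownames(w))) rownames(w) else paste0("V", 1:n)
  if (all(w == 0)) {
    return(structure(list(membership = stats::setNames(rep(1L, n), nodes),
                          q = 0, seed = seed),
                     class = "module_partition"))
  }
  g <- .as_igraph(w)
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    mem <- as.integer(igraph::membership(cl))
    q <- modularity_q(w, mem)
    if (q > best_q) {
      best_q <- q
      best <- mem
    }
  }
  structure(list(membership = stats::setNames(best, nodes), q = best_q,
                 seed = seed),
            class = "module_partition")
}

# Participation coefficient and within-module degree z-score given a
# membership vector.
.participation <- function(w, membership) {
  s <- rowSums(w)
  mods <- sort(unique(membership))
  sm2 <- rep(0, nrow(w))
  for (m in mods) {
    sm <- rowSums(w[, membership == m, drop = FALSE])
    sm2 <- sm2 + (sm / pmax(s, .Machine$double.eps))^2
  }
  p <- 1 - sm2
  p[s == 0] <- 0
  p
}

.within_module_z <- function(w, membership) {
  z <- rep(0, nrow(w))
  for (m in sort(unique(membership))) {
    idx <- which(membership == m)
    sw <- rowSums(w[idx, idx, drop = FALSE])
    sdw <- stats::sd(sw)
    if (length(idx) > 1 && is.finite(sdw) && sdw > 0) {
      z[idx] <- (sw - mean(sw)) / sdw
    }
  }
  z
}

# Weighted assortativity: correlation of endpoint strengths over edges,
# each edge contributing both orientations with weight w_ij.
.assortativity_weighted <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) return(NA_real_)
  s <- rowSums(w)
  x <- c(s[idx[, 1]], s[idx[, 2]])
  y <- c(s[idx[, 2]], s[idx[, 1]])
  wt <- c(w[idx], w[idx])
  wt <- wt / sum(wt)
  mx <- sum(wt * x)
  my <- sum(wt * y)
  vx <- sum(wt * (x - mx)^2)
  vy <- sum(wt * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(wt * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Degree-preserving randomized reference networks
#'
#' Each realization rewires the binary topology by Maslov-Sneppen
#' double-edge swaps (10 x |E| attempted swaps), preserving every node's
#' degree exactly, then reassigns the original multiset of edge weights
#' uniformly at random to the rewired edges. For topologies that cannot be
#' rewired (e.g. complete graphs) the realizations keep the topology and
#' only reshuffle weights, with a warning.
#'
#' @param net A `group_network` or weight matrix.
#' @param n_rand Number of realizations.
#' @param seed Integer RNG seed.
#' @return List of weight matrices.
#' @export
randomized_reference <- function(net, n_rand = 100L, seed = 1L) {
  w <- if (inherits(net, "group_network")) net$weights else as.matrix(net)
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ne <- nrow(idx)
  if (ne < 2) stop("randomized_reference needs at least 2 edges")
  if (ne == n * (n - 1) / 2) {
    warning("complete topology cannot be rewired; reshuffling weights only")
  }
  weights <- w[idx]
  g <- .as_igraph((w > 0) * 1)
  set.seed(seed)
  lapply(seq_len(n_rand), function(r) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
    el <- igraph::as_edgelist(gr, names = FALSE)
    wr <- matrix(0, n, n, dimnames = dimnames(w))
    wperm <- sample(weights)
    wr[cbind(el[, 1], el[, 2])] <- wperm
    wr[cbind(el[, 2], el[, 1])] <- wperm
    wr
  })
}

# Clustering-and-path-length summary used for small-worldness references.
.cl_summary <- function(w) {
  t <- .triangles(w)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  C <- ifelse(denom > 0, 2 * t / denom, 0)
  d <- .dist_from_w(w)
  diag(d) <- NA
  L_i <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  c(C = mean(C), L = mean(L_i, na.rm = TRUE))
}

#' Small-worldness index
#'
#' `sigma = (C / <C_rand>) / (L / <L_rand>)` where C is the mean nodal
#' clustering coefficient, L the characteristic path length, and the
#' averages are taken over a [randomized_reference()] ensemble.
#'
#' @param net A `group_network` or weight matrix.
#' @param n_rand Ensemble size (default 100 for observed networks; a
#'   smaller ensemble is typically used inside permutation replications).
#' @param seed Integer RNG seed for the ensemble.
#' @return Scalar sigma (`NA` when undefined).
#' @export
small_worldness <- function(net, n_rand = 100L, seed = 1L) {
  w <- if (inherits(net, "group_network")) net$weights else as.matrix(net)
  if (sum(w[upper.tri(w)] > 0) < 2) return(NA_real_)
  obs <- .cl_summary(w)
  refs <- vapply(randomized_reference(w, n_rand = n_rand, seed = seed),
                 .cl_summary, numeric(2))
  c_rand <- mean(refs["C", ])
  l_rand <- mean(refs["L", ], na.rm = TRUE)
  if (!is.finite(c_rand) || c_rand == 0 || !is.finite(l_rand) ||
      l_rand == 0 || !is.finite(obs["L"]) || obs["L"] == 0) {
    return(NA_real_)
  }
  unname((obs["C"] / c_rand) / (obs["L"] / l_rand))
}

#' Nodal graph measures
#'
#' Computes, per node: betweenness centrality (fraction of shortest paths
#' through the node, normalized by `(N-1)(N-2)`), closeness centrality
#' (reciprocal nodal path length), Onnela clustering coefficient, degree,
#' eccentricity, nodal global efficiency (mean reciprocal distance to the
#' other nodes), local efficiency (global efficiency of the
#' neighbor-induced subgraph), participation coefficient, path length (mean
#' finite distance), strength, triangle intensity, and within-module degree
#' z-score. Isolated nodes get `NA` path length and eccentricity with a
#' warning.
#'
#' @param net A `group_network`.
#' @param dist Optional precomputed [shortest_paths_matrix()].
#' @param part Optional precomputed [detect_modules()] partition.
#' @param modules_seed,modules_restarts Passed to [detect_modules()] when
#'   `part` is missing.
#' @return Numeric matrix, nodes x measures (columns named as in
#'   [nodal_measure_names()]).
#' @export
nodal_measures <- function(net, dist = NULL, part = NULL,
                           modules_seed = 1L, modules_restarts = 10L) {
  w <- if (inherits(net, "group_network")) net$weights else as.matrix(net)
  if (is.null(dist)) dist <- .dist_from_w(w)
  if (is.null(part)) {
    part <- detect_modules(w, seed = modules_seed,
                           n_restarts = modules_restarts)
  }
  n <- nrow(w)
  k <- rowSums(w > 0)
  s <- rowSums(w)
  t <- .triangles(w)
  denom <- k * (k - 1)
  C <- ifelse(denom > 0, 2 * t / denom, 0)
  d <- dist
  diag(d) <- NA
  L <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  ecc <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else max(f)
  })
  if (anyNA(L)) warning("isolated node(s): path length/eccentricity NA")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  ge <- rowSums(inv, na.rm = TRUE) / (n - 1)
  le <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    dsub <- .dist_from_w(w[nb, nb, drop = FALSE])
    isub <- 1 / dsub
    diag(isub) <- 0
    isub[!is.finite(isub)] <- 0
    sum(isub) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  btw <- if (all(w == 0)) rep(0, n) else {
    g <- .as_igraph(w)
    igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                        directed = FALSE, normalized = FALSE) /
      ((n - 1) * (n - 2))
  }
  out <- cbind(
    `Betweenness centrality` = as.numeric(btw),
    `Closeness centrality` = closeness_centrality(L),
    `Clustering nodes` = C,
    `Degree` = k,
    `Eccentricity` = ecc,
    `Global efficiency nodes` = ge,
    `Local efficiency nodes` = le,
    `Participation` = .participation(w, part$membership),
    `Path length` = L,
    `Strength` = s,
    `Triangles` = t,
    `Within module degree z-score` = .within_module_z(w, part$membership))
  rownames(out) <- rownames(w)
  out[, nodal_measure_names(), drop = FALSE]
}

#' Global graph measures
#'
#' Computes average degree, average strength, radius (min nodal
#' eccentricity), diameter (max), eccentricity (mean of nodal
#' eccentricities), characteristic path length (mean nodal path length),
#' global efficiency (mean reciprocal distance over ordered pairs),
#' clustering (mean nodal clustering), transitivity (ratio of summed
#' triangle intensity to summed connected triples), modularity (Q of the
#' Louvain partition), weighted assortativity, and the small-worldness
#' index. Unreachable pairs are excluded from path-length and eccentricity
#' means and contribute zero to efficiency.
#'
#' @inheritParams nodal_measures
#' @param sw_n_rand,sw_seed Small-worldness reference ensemble size and
#'   seed; `sw_n_rand = 0` skips the index (`NA`).
#' @return Named numeric vector (names as in [global_measure_names()]).
#' @export
global_measures <- function(net, dist = NULL, part = NULL,
                            sw_n_rand = 100L, sw_seed = 1L,
                            modules_seed = 1L, modules_restarts = 10L) {
  w <- if (inherits(net, "group_network")) net$weights else as.matrix(net)
  if (is.null(dist)) dist <- .dist_from_w(w)
  if (is.null(part)) {
    part <- detect_modules(w, seed = modules_seed,
                           n_restarts = modules_restarts)
  }
  n <- nrow(w)
  k <- rowSums(w > 0)
  s <- rowSums(w)
  t <- .triangles(w)
  denom <- k * (k - 1)
  C <- ifelse(denom > 0, 2 * t / denom, 0)
  d <- dist
  diag(d) <- NA
  L <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  ecc <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) == 0) NA_real_ else max(f)
  })
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  geff <- sum(inv, na.rm = TRUE) / (n * (n - 1))
  trans <- if (sum(denom) > 0) sum(2 * t) / sum(denom) else 0
  sw <- if (sw_n_rand > 0 && sum(w[upper.tri(w)] > 0) >= 2) {
    small_worldness(w, n_rand = sw_n_rand, seed = sw_seed)
  } else {
    NA_real_
  }
  c(`Average degree` = mean(k),
    `Average strength` = mean(s),
    `Radius` = if (all(is.na(ecc))) NA_real_ else min(ecc, na.rm = TRUE),
    `Diameter` = if (all(is.na(ecc))) NA_real_ else max(ecc, na.rm = TRUE),
    `Eccentricity` = mean(ecc, na.rm = TRUE),
    `Characteristic path length` = mean(L, na.rm = TRUE),
    `Global efficiency` = geff,
    `Clustering` = mean(C),
    `Transitivity` = trans,
    `Modularity` = part$q,
    `Assortativity` = .assortativity_weighted(w),
    `Small-worldness` = sw)
}

#' All measures for one network
#'
#' Convenience wrapper computing distances and the community partition
#' once, then both [global_measures()] and [nodal_measures()] from them.
#'
#' @inheritParams global_measures
#' @return List of class `measure_set` with elements `global` (named
#'   vector) and `nodal` (nodes x measures matrix).
#' @export
graph_measures <- function(net, sw_n_rand = 100L, sw_seed = 1L,
                           modules_seed = 1L, modules_restarts = 10L) {
  w <- if (inherits(net, "group_network")) net$weights else as.matrix(net)
  dist <- .dist_from_w(w)
  part <- detect_modules(w, seed = modules_seed,
                         n_restarts = modules_restarts)
  structure(
    list(global = global_measures(net, dist, part, sw_n_rand = sw_n_rand,
                                  sw_seed = sw_seed),
         nodal = nodal_measures(net, dist, part),
         partition = part),
    class = "measure_set")
}

#' Write measure tables
#'
#' @param measures A `measure_set`.
#' @param global_path,nodal_path Output TSV paths (either `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_measures <- function(measures, global_path = NULL, nodal_path = NULL) {
  stopifnot(inherits(measures, "measure_set"))
  written <- character()
  if (!is.null(global_path)) {
    utils::write.table(
      data.frame(measure = names(measures$global),
                 value = unname(measures$global)),
      global_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, global_path)
  }
  if (!is.null(nodal_path)) {
    m <- measures$nodal
    long <- data.frame(node = rep(rownames(m), times = ncol(m)),
                       measure = rep(colnames(m), each = nrow(m)),
                       value = as.vector(m))
    utils::write.table(long, nodal_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, nodal_path)
  }
  invisible(written)
}
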