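# Independent oracles, deliberately written with different algorithms than
# the package (Floyd-Warshall vs Dijkstra, exhaustive path enumeration vs
# Brandes, brute-force triples vs matrix powers, exhaustive partition
# search vs Louvain).

# Floyd-Warshall all-pairs shortest paths on lengths 1/w.
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- 1 / w
  d[w == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# All simple paths between s and t (DFS), as list of vertex sequences.
.all_simple_paths <- function(w, s, t) {
  n <- nrow(w)
  out <- list()
  walk <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1]] <<- list(path = path, len = len)
      return()
    }
    for (u in seq_len(n)) {
      if (w[v, u] > 0 && !(u %in% path)) {
        walk(c(path, u), len + 1 / w[v, u])
      }
    }
  }
  walk(s, 0)
  out
}

# Betweenness by exhaustive shortest-path enumeration, normalized by
# (n-1)(n-2).
oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- .all_simple_paths(w, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      dmin <- min(lens)
      short <- paths[lens <= dmin * (1 + tol)]
      sigma <- length(short)
      for (p in short) {
        inner <- setdiff(p$path, c(s, t))
        b[inner] <- b[inner] + 1 / sigma
      }
    }
  }
  b / ((n - 1) * (n - 2))
}

# Onnela triangle intensity by brute-force triple enumeration.
oracle_triangles <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(numeric(n))
  wh <- w / mx
  t <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
        }
      }
    }
    t[i] <- acc / 2
  }
  t
}

# All set partitions of 1..n (restricted growth strings).
.all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(mx + 1)) grow(c(prefix, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# Maximum modularity by exhaustive partition search (small n only).
oracle_best_modularity <- function(w) {
  parts <- .all_partitions(nrow(w))
  qs <- vapply(parts, function(m) modularity_q(w, m), numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# Partial correlation of columns i, j given the others, via precision
# matrix inversion.
oracle_partial_cor <- function(X, i, j) {
  P <- solve(stats::cov(X))
  -P[i, j] / sqrt(P[i, i] * P[j, j])
}

# Random connected-ish weighted graph for oracle sweeps.
random_weighted_graph <- function(n, density = NULL) {
  if (is.null(density)) density <- stats::runif(1, 0.3, 0.9)
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < density]
  w[on] <- stats::runif(length(on), 0.05, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

# Small two-group cohort drawn from one distribution (true null).
null_cohort <- function(n_per_group, p = 22, seed, lambda_frac = 0.6) {
  rois <- paste0("roi", seq_len(p))
  mk <- function(g, s) {
    simulation_config(
      n = n_per_group, group = g,
      mu = stats::setNames(rep(1000, p), rois),
      sigma = stats::setNames(rep(100, p), rois),
      lambda = matrix(lambda_frac * 100, p, 1), seed = s)
  }
  simulate_cohort(list(mk("A", seed), mk("B", seed + 1L)))
}
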