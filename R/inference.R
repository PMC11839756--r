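# Internal lazily-evaluated measure computation on a weight matrix.
# Computes only what the requested measure subset needs, so permutation
# replications that track e.g. only average strength stay cheap.
.measures_from_w <- function(w, global = character(), nodal = character(),
                             sw_n_rand = 0L, sw_seed = 1L,
                             modules_seed = 1L, modules_restarts = 10L) {
  n <- nrow(w)
  k <- s <- t <- C <- d <- L <- ecc <- part <- NULL
  need_dist <- any(c("Radius", "Diameter", "Eccentricity",
                     "Characteristic path length",
                     "Global efficiency") %in% global) ||
    any(c("Betweenness centrality", "Closeness centrality", "Eccentricity",
          "Global efficiency nodes", "Local efficiency nodes",
          "Path length") %in% nodal)
  need_part <- "Modularity" %in% global ||
    any(c("Participation", "Within module degree z-score") %in% nodal)
  need_tri <- any(c("Clustering", "Transitivity") %in% global) ||
    any(c("Clustering nodes", "Triangles") %in% nodal)
  k <- rowSums(w > 0)
  s <- rowSums(w)
  if (need_tri) {
    t <- .triangles(w)
    denom <- k * (k - 1)
    C <- ifelse(denom > 0, 2 * t / denom, 0)
  }
  if (need_dist) {
    d <- .dist_from_w(w)
    diag(d) <- NA
    L <- apply(d, 1, function(r) {
      f <- r[is.finite(r)]
      if (length(f) == 0) NA_real_ else mean(f)
    })
    ecc <- apply(d, 1, function(r) {
      f <- r[is.finite(r)]
      if (length(f) == 0) NA_real_ else max(f)
    })
  }
  if (need_part) {
    part <- detect_modules(w, seed = modules_seed,
                           n_restarts = modules_restarts)
  }
  gvals <- numeric(0)
  if (length(global) > 0) {
    gv <- function(name) {
      switch(name,
        "Average degree" = mean(k),
        "Average strength" = mean(s),
        "Radius" = if (all(is.na(ecc))) NA_real_ else
          min(ecc, na.rm = TRUE),
        "Diameter" = if (all(is.na(ecc))) NA_real_ else
          max(ecc, na.rm = TRUE),
        "Eccentricity" = mean(ecc, na.rm = TRUE),
        "Characteristic path length" = mean(L, na.rm = TRUE),
        "Global efficiency" = {
          inv <- 1 / d
          inv[!is.finite(inv)] <- 0
          sum(inv, na.rm = TRUE) / (n * (n - 1))
        },
        "Clustering" = mean(C),
        "Transitivity" = {
          dn <- sum(k * (k - 1))
          if (dn > 0) sum(2 * t) / dn else 0
        },
        "Modularity" = part$q,
        "Assortativity" = .assortativity_weighted(w),
        "Small-worldness" = if (sw_n_rand > 0 &&
                                sum(w[upper.tri(w)] > 0) >= 2) {
          small_worldness(w, n_rand = sw_n_rand, seed = sw_seed)
        } else NA_real_,
        stop("unknown global measure: ", name))
    }
    gvals <- vapply(global, gv, numeric(1))
  }
  nvals <- numeric(0)
  if (length(nodal) > 0) {
    nodes <- if (!is.null(rownames(w))) rownames(w) else paste0("V", 1:n)
    nv <- function(name) {
      switch(name,
        "Betweenness centrality" = if (all(w == 0)) rep(0, n) else {
          g <- .as_igraph(w)
          as.numeric(igraph::betweenness(
            g, weights = 1 / igraph::E(g)$weight, directed = FALSE,
            normalized = FALSE)) / ((n - 1) * (n - 2))
        },
        "Closeness centrality" = closeness_centrality(L),
        "Clustering nodes" = C,
        "Degree" = k,
        "Eccentricity" = ecc,
        "Global efficiency nodes" = {
          inv <- 1 / d
          inv[!is.finite(inv)] <- 0
          rowSums(inv, na.rm = TRUE) / (n - 1)
        },
        "Local efficiency nodes" = vapply(seq_len(n), function(i) {
          nb <- which(w[i, ] > 0)
          if (length(nb) < 2) return(0)
          isub <- 1 / .dist_from_w(w[nb, nb, drop = FALSE])
          diag(isub) <- 0
          isub[!is.finite(isub)] <- 0
          sum(isub) / (length(nb) * (length(nb) - 1))
        }, numeric(1)),
        "Participation" = .participation(w, part$membership),
        "Path length" = L,
        "Strength" = s,
        "Triangles" = .triangles(w),
        "Within module degree z-score" =
          .within_module_z(w, part$membership),
        stop("unknown nodal measure: ", name))
    }
    nm <- lapply(nodal, nv)
    nvals <- unlist(nm)
    names(nvals) <- as.vector(outer(nodes, nodal, paste, sep = "||"))
  }
  c(gvals, nvals)
}

#' Benjamini-Hochberg step-up FDR decisions
#'
#' Sorts the p-values ascending, finds the largest k with
#' `p_(k) <= (k/m) * q`, and rejects hypotheses 1..k (step-up rule; ties
#' rejected together). Flags are returned in input order; `NA` p-values get
#' `NA` flags and do not count toward m.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical vector of rejection flags.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) return(logical(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  ord <- order(pv)
  passed <- which(pv[ord] <= (seq_len(m) / m) * q)
  flags <- rep(FALSE, m)
  if (length(passed) > 0) {
    kmax <- max(passed)
    flags[ord[seq_len(kmax)]] <- TRUE
    # step-up: any p tied with the threshold p-value is rejected too
    flags[pv <= pv[ord[kmax]]] <- TRUE
  }
  out[ok] <- flags
  out
}

#' Label-permutation group comparison of network measures
#'
#' Computes every requested global and nodal measure on the two observed
#' group networks, then builds a null distribution of between-group
#' differences by repeatedly permuting the group labels over the pooled
#' subjects (preserving group sizes), rebuilding both networks and
#' recomputing the measures. Volumes should already be covariate-adjusted:
#' residuals are permuted, the adjustment is not refit per replication
#' (covariate-volume relations are label-independent under the null).
#'
#' The two-tailed p-value is the fraction of null differences at least as
#' large in absolute value as the observed one (`tail = "one"` gives the
#' literal one-sided exceedance rule; `small_sample = TRUE` uses
#' `(k + 1) / (R + 1)`). The 95% interval is the 2.5th/97.5th percentile of
#' the null difference distribution. FDR is controlled per family: all
#' global measures as one family and all (node, measure) nodal tests as one
#' pooled family by default (`family = "per-measure"` corrects each nodal
#' measure across nodes separately).
#'
#' @param adjusted A `cohort_table` of adjusted volumes with exactly two
#'   group labels.
#' @param R Number of permutation replications (default 1000; fewer than
#'   100 draws a warning).
#' @param seed Integer seed; the whole run is reproducible given it.
#' @param reference Label of the reference group ("group 1"; differences
#'   are reference minus the other group). Default `"HC"` when present,
#'   otherwise the first sorted label.
#' @param measures_global,measures_nodal Character vectors selecting
#'   measures (defaults: all of [global_measure_names()] /
#'   [nodal_measure_names()]); use `character(0)` to skip a family.
#' @param sw_n_rand_obs,sw_n_rand Small-worldness reference ensemble sizes
#'   for the observed networks (default 100) and within replications
#'   (default 20).
#' @param modules_restarts Louvain restarts per network (default 10).
#' @param q FDR level (default 0.05).
#' @param family `"pooled"` (default) or `"per-measure"` nodal FDR family.
#' @param tail `"two"` (default) or `"one"`.
#' @param small_sample Use the `(k + 1) / (R + 1)` p-value correction.
#' @param nodes Node columns (default: the table's volume columns).
#' @return A `permutation_result`: list with data frames `global` and
#'   `nodal` (columns: measure (+ node), value_ref, value_other,
#'   difference, ci_low, ci_high, p, fdr_significant, comparison, n_null)
#'   and metadata (`groups`, `R`, `seed`, `config`).
#' @export
permutation_test <- function(adjusted, R = 1000L, seed = 1L,
                             reference = NULL,
                             measures_global = global_measure_names(),
                             measures_nodal = nodal_measure_names(),
                             sw_n_rand_obs = 100L, sw_n_rand = 20L,
                             modules_restarts = 10L, q = 0.05,
                             family = c("pooled", "per-measure"),
                             tail = c("two", "one"),
                             small_sample = FALSE, nodes = NULL) {
  stopifnot(inherits(adjusted, "cohort_table"))
  family <- match.arg(family)
  tail <- match.arg(tail)
  grp <- as.character(adjusted$group)
  labs <- sort(unique(grp))
  if (length(labs) != 2) stop("exactly two group labels required")
  if (is.null(reference)) reference <- if ("HC" %in% labs) "HC" else labs[1]
  if (!reference %in% labs) stop("reference label not present: ", reference)
  other <- setdiff(labs, reference)
  if (min(table(grp)) < 4) stop("each group needs at least 4 subjects")
  if (R < 100) warning("R < 100: permutation p-values will be coarse")
  if (is.null(nodes)) {
    nodes <- volume_cols(adjusted)
    canon <- network_nodes()
    if (setequal(nodes, canon)) nodes <- canon
  }
  Y <- as.matrix(as.data.frame(adjusted)[, nodes, drop = FALSE])
  n <- nrow(Y)

  mfun <- function(idx_ref, idx_oth, sw_n, seed_offset) {
    w1 <- .weights_from_matrix(Y[idx_ref, , drop = FALSE])$weights
    w2 <- .weights_from_matrix(Y[idx_oth, , drop = FALSE])$weights
    m1 <- .measures_from_w(w1, measures_global, measures_nodal,
                           sw_n_rand = sw_n, sw_seed = seed_offset,
                           modules_seed = seed_offset,
                           modules_restarts = modules_restarts)
    m2 <- .measures_from_w(w2, measures_global, measures_nodal,
                           sw_n_rand = sw_n, sw_seed = seed_offset + 1L,
                           modules_seed = seed_offset + 1L,
                           modules_restarts = modules_restarts)
    list(m1 = m1, m2 = m2)
  }

  set.seed(seed)
  perms <- lapply(seq_len(R), function(r) sample.int(n))

  obs <- mfun(which(grp == reference), which(grp == other),
              sw_n_rand_obs, seed)
  mnames <- names(obs$m1)
  obs_diff <- obs$m1 - obs$m2

  null <- matrix(NA_real_, nrow = R, ncol = length(mnames),
                 dimnames = list(NULL, mnames))
  for (r in seq_len(R)) {
    lab_r <- grp[perms[[r]]]
    mr <- mfun(which(lab_r == reference), which(lab_r == other),
               sw_n_rand, seed + 2L * r)
    null[r, ] <- mr$m1 - mr$m2
  }

  n_null <- colSums(!is.na(null))
  dropped <- sum(is.na(null))
  if (dropped > 0) {
    message("permutation_test: ", dropped,
            " degenerate replication value(s) excluded from null")
  }
  pval <- vapply(seq_along(mnames), function(j) {
    nl <- null[!is.na(null[, j]), j]
    if (length(nl) == 0 || is.na(obs_diff[j])) return(NA_real_)
    k <- if (tail == "two") sum(abs(nl) >= abs(obs_diff[j])) else
      sum(nl > obs_diff[j])
    if (small_sample) (k + 1) / (length(nl) + 1) else k / length(nl)
  }, numeric(1))
  ci <- t(apply(null, 2, function(x) {
    if (all(is.na(x))) c(NA_real_, NA_real_) else
      stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }))

  comparison <- ifelse(is.na(obs_diff) | obs_diff == 0,
                       paste(other, "=", reference),
                       ifelse(obs_diff > 0, paste(other, "<", reference),
                              paste(other, ">", reference)))

  is_global <- mnames %in% measures_global & !grepl("\\|\\|", mnames)
  res <- data.frame(name = mnames,
                    value_ref = unname(obs$m1),
                    value_other = unname(obs$m2),
                    difference = unname(obs_diff),
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    p = pval, comparison = comparison,
                    n_null = unname(n_null), row.names = NULL)
  gl <- res[is_global, , drop = FALSE]
  names(gl)[1] <- "measure"
  gl$fdr_significant <- bh_fdr(gl$p, q)
  nd <- res[!is_global, , drop = FALSE]
  if (nrow(nd) > 0) {
    parts <- strsplit(nd$name, "||", fixed = TRUE)
    nd$node <- vapply(parts, `[`, character(1), 1)
    nd$measure <- vapply(parts, `[`, character(1), 2)
    nd$name <- NULL
    nd <- nd[, c("node", "measure", setdiff(names(nd),
                                            c("node", "measure")))]
    nd$fdr_significant <- if (family == "pooled") bh_fdr(nd$p, q) else
      stats::ave(nd$p, nd$measure, FUN = function(p) bh_fdr(p, q)) > 0
    rownames(nd) <- NULL
  }
  rownames(gl) <- NULL
  structure(list(global = gl, nodal = nd),
            class = "permutation_result",
            groups = c(reference = reference, other = other),
            R = R, seed = seed,
            config = list(measures_global = measures_global,
                          measures_nodal = measures_nodal,
                          sw_n_rand_obs = sw_n_rand_obs,
                          sw_n_rand = sw_n_rand,
                          modules_restarts = modules_restarts, q = q,
                          family = family, tail = tail,
                          small_sample = small_sample))
}

#' @export
print.permutation_result <- function(x, ...) {
  g <- attr(x, "groups")
  cat("permutation_result: ", g["other"], " vs ", g["reference"],
      " (reference), R = ", attr(x, "R"), ", seed = ", attr(x, "seed"),
      "\n", sep = "")
  print(x$global[, c("measure", "value_other", "value_ref", "difference",
                     "p", "fdr_significant")], digits = 3)
  if (!is.null(x$nodal) && nrow(x$nodal) > 0) {
    sig <- sum(x$nodal$fdr_significant, na.rm = TRUE)
    cat("nodal tests: ", nrow(x$nodal), " (", sig, " FDR-significant)\n",
        sep = "")
  }
  invisible(x)
}

#' Result tables in the published layout
#'
#' Formats a [permutation_test()] result as the familiar comparison tables:
#' one row per global measure (and per node/measure pair for the nodal
#' table) with the two group values, the null-distribution 95% CI bounds,
#' the difference (reference minus other group), the permutation p-value
#' and the direction label. The nodal table is restricted to
#' FDR-significant rows unless `all_nodal = TRUE`.
#'
#' @param result A `permutation_result`.
#' @param all_nodal Emit all nodal rows, not only FDR-significant ones.
#' @param dir Optional output directory; when given, writes
#'   `global_measures.tsv` and `nodal_measures.tsv` (deterministic column
#'   order and formatting).
#' @return List with data frames `global` and `nodal`.
#' @export
report_tables <- function(result, all_nodal = FALSE, dir = NULL) {
  stopifnot(inherits(result, "permutation_result"))
  g <- attr(result, "groups")
  gl <- result$global
  global <- data.frame(
    `Global graph measure` = gl$measure,
    other = gl$value_other, ref = gl$value_ref,
    `CI lower` = gl$ci_low, `CI upper` = gl$ci_high,
    Difference = gl$difference, `p value` = gl$p,
    Comparison = gl$comparison, check.names = FALSE)
  names(global)[2:3] <- c(g["other"], g["reference"])
  nodal <- NULL
  nd <- result$nodal
  if (!is.null(nd) && nrow(nd) > 0) {
    keep <- if (all_nodal) rep(TRUE, nrow(nd)) else
      !is.na(nd$fdr_significant) & nd$fdr_significant
    nd <- nd[keep, , drop = FALSE]
    nodal <- data.frame(
      `Brain region` = nd$node, `Local graph measure` = nd$measure,
      other = nd$value_other, ref = nd$value_ref,
      `CI lower` = nd$ci_low, `CI upper` = nd$ci_high,
      Difference = nd$difference, `p value` = nd$p,
      Comparison = nd$comparison, check.names = FALSE)
    names(nodal)[3:4] <- c(g["other"], g["reference"])
    rownames(nodal) <- NULL
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(global, file.path(dir, "global_measures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(nodal)) {
      utils::write.table(nodal, file.path(dir, "nodal_measures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(global = global, nodal = nodal)
}
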