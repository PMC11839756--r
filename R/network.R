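#' Pearson correlation of two sequences
#'
#' Thin, validated wrapper around the product-moment correlation used for
#' edge weights.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant sequence: correlation undefined")
  }
  stats::cor(x, y)
}

# Correlation -> nonnegative weight matrix; constant columns give zero rows.
.weights_from_matrix <- function(Y) {
  sds <- apply(Y, 2, stats::sd)
  w <- suppressWarnings(stats::cor(Y))
  w[!is.finite(w)] <- 0
  w[w < 0] <- 0
  w[w > 1] <- 1
  diag(w) <- 0
  w[sds == 0, ] <- 0
  w[, sds == 0] <- 0
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  list(weights = w, degenerate = colnames(Y)[sds == 0])
}

#' Build a group structural covariance network
#'
#' For one group, edges are the Pearson correlations of covariate-adjusted
#' volumes across the group's subjects, with negative correlations set to
#' zero. Because the volumes are residuals on age, sex and ICV, these edges
#' equal the partial correlations given those covariates. The result is a
#' symmetric, undirected, nonnegative weighted adjacency matrix with zero
#' diagonal. Constant (degenerate) columns yield zero-weight edges with a
#' warning rather than an error.
#'
#' @param adjusted A `cohort_table` of adjusted volumes.
#' @param group Group label to select.
#' @param nodes Node columns to use; default the table's volume columns
#'   (canonically ordered when they are the 22 network nodes).
#' @return A `group_network`: list with `nodes`, `weights` (matrix),
#'   `group`, `n_subjects`.
#' @export
build_group_network <- function(adjusted, group, nodes = NULL) {
  stopifnot(inherits(adjusted, "cohort_table"))
  if (!group %in% adjusted$group) stop("group label not present: ", group)
  if (is.null(nodes)) {
    nodes <- volume_cols(adjusted)
    canon <- network_nodes()
    if (setequal(nodes, canon)) nodes <- canon
  }
  rows <- adjusted$group == group
  if (sum(rows) < 4) stop("need at least 4 subjects in group ", group)
  Y <- as.matrix(as.data.frame(adjusted)[rows, nodes, drop = FALSE])
  res <- .weights_from_matrix(Y)
  if (length(res$degenerate) > 0) {
    warning("degenerate (constant) column(s), edges zeroed: ",
            paste(res$degenerate, collapse = ", "))
  }
  group_network(res$weights, nodes = nodes, group = group,
                n_subjects = sum(rows))
}

#' Construct a group network from a weight matrix
#'
#' @param weights Symmetric nonnegative matrix with zero diagonal, entries
#'   in `[0, 1]`.
#' @param nodes Node labels (default from `weights` dimnames or `V1..Vn`).
#' @param group Group label.
#' @param n_subjects Number of subjects behind the matrix (`NA` for
#'   constructed networks).
#' @return A `group_network`.
#' @export
group_network <- function(weights, nodes = NULL, group = "network",
                          n_subjects = NA_integer_) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (is.null(nodes)) {
    nodes <- if (!is.null(colnames(weights))) colnames(weights) else
      paste0("V", seq_len(ncol(weights)))
  }
  if (any(weights < 0) || any(weights > 1 + 1e-12)) {
    stop("weights must lie in [0, 1]")
  }
  if (any(abs(weights - t(weights)) > 0)) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights, group = group,
                 n_subjects = n_subjects),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  pos <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("group_network '", x$group, "': ", length(x$nodes), " nodes, ",
      pos, " positive edges, n = ", x$n_subjects, "\n", sep = "")
  invisible(x)
}

#' Export a group network
#'
#' Writes the dense weight matrix as a TSV (node labels as header row and
#' first column, 17 significant digits so a round-trip read is bit-exact)
#' and the positive edges as an edge-list TSV (`node_i`, `node_j`,
#' `weight`), each unordered pair once, sorted lexicographically.
#'
#' @param net A `group_network`.
#' @param matrix_path,edges_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, matrix_path = NULL, edges_path = NULL) {
  stopifnot(inherits(net, "group_network"))
  written <- character()
  if (!is.null(matrix_path)) {
    w <- net$weights
    lines <- c(paste(c("node", net$nodes), collapse = "\t"),
               vapply(seq_along(net$nodes), function(i) {
                 paste(c(net$nodes[i], sprintf("%.17g", w[i, ])),
                       collapse = "\t")
               }, character(1)))
    writeLines(lines, matrix_path, useBytes = TRUE)
    written <- c(written, matrix_path)
  }
  if (!is.null(edges_path)) {
    idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
    edges <- data.frame(node_i = net$nodes[idx[, 1]],
                        node_j = net$nodes[idx[, 2]],
                        weight = net$weights[idx])
    swap <- edges$node_j < edges$node_i
    tmp <- edges$node_i[swap]
    edges$node_i[swap] <- edges$node_j[swap]
    edges$node_j[swap] <- tmp
    edges <- edges[order(edges$node_i, edges$node_j), , drop = FALSE]
    lines <- c("node_i\tnode_j\tweight",
               if (nrow(edges) > 0) {
                 paste(edges$node_i, edges$node_j,
                       sprintf("%.17g", edges$weight), sep = "\t")
               })
    writeLines(lines, edges_path, useBytes = TRUE)
    written <- c(written, edges_path)
  }
  invisible(written)
}

#' Read a dense network matrix written by [export_network()]
#'
#' @param path Matrix TSV path.
#' @param group Group label to attach.
#' @return A `group_network`.
#' @export
read_network <- function(path, group = "network") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1)
  w <- as.matrix(tab)
  storage.mode(w) <- "double"
  group_network(w, nodes = rownames(w), group = group)
}
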