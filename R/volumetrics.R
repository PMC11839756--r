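#' ANCOVA volumetric group comparison
#'
#' For each ROI, fits `volume ~ group + covariates` by ordinary least
#' squares and tests the group coefficient (a t-test, equivalent to the
#' 1-df F-test with two groups). Adjusted group means are the model
#' predictions at the grand covariate means. FDR is controlled across the
#' ROI family with [bh_fdr()].
#'
#' @param cohort A `cohort_table` with exactly two group labels.
#' @param rois ROI columns to compare (default: all volume columns).
#' @param covariates Covariate columns (default `c("age", "sex", "icv")`).
#' @param reference Reference group level (default `"HC"` when present,
#'   else first sorted label); the group coefficient is the other group's
#'   mean shift relative to it, in mm^3.
#' @param q FDR level.
#' @return Data frame of class `ancova_result`: one row per ROI with raw
#'   mean/SD per group, adjusted means, group coefficient, SE, t, p and
#'   FDR flag. Covariates used are recorded in the `covariates` attribute.
#' @export
ancova_compare <- function(cohort, rois = NULL,
                           covariates = c("age", "sex", "icv"),
                           reference = NULL, q = 0.05) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(rois)) rois <- volume_cols(cohort)
  labs <- sort(unique(as.character(cohort$group)))
  if (length(labs) != 2) stop("exactly two group labels required")
  if (is.null(reference)) reference <- if ("HC" %in% labs) "HC" else labs[1]
  other <- setdiff(labs, reference)
  if (min(table(cohort$group)) < length(covariates) + 2) {
    stop("need at least ", length(covariates) + 2, " subjects per group")
  }
  tab <- as.data.frame(cohort)
  tab$group <- factor(tab$group, levels = c(reference, other))
  X <- stats::model.matrix(
    stats::reformulate(c("group", covariates)), data = tab)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient ANCOVA design")
  out <- lapply(rois, function(roi) {
    fit <- stats::lm.fit(X, tab[[roi]])
    dfres <- nrow(X) - ncol(X)
    sigma2 <- sum(fit$residuals^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(X)))
    j <- which(colnames(X) == paste0("group", other))
    est <- fit$coefficients[j]
    se <- sqrt(sigma2 * XtXinv[j, j])
    tstat <- est / se
    p <- 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE)
    cm <- colMeans(X)
    x_ref <- cm; x_ref[j] <- 0
    x_oth <- cm; x_oth[j] <- 1
    data.frame(
      roi = roi,
      mean_ref = mean(tab[[roi]][tab$group == reference]),
      sd_ref = stats::sd(tab[[roi]][tab$group == reference]),
      mean_other = mean(tab[[roi]][tab$group == other]),
      sd_other = stats::sd(tab[[roi]][tab$group == other]),
      adj_mean_ref = sum(x_ref * fit$coefficients),
      adj_mean_other = sum(x_oth * fit$coefficients),
      group_coef = unname(est), se = unname(se), t = unname(tstat),
      p = unname(p))
  })
  res <- do.call(rbind, out)
  res$fdr_significant <- bh_fdr(res$p, q)
  rownames(res) <- NULL
  structure(res, class = c("ancova_result", "data.frame"),
            covariates = covariates,
            groups = c(reference = reference, other = other), q = q)
}

#' Write an ANCOVA table
#'
#' TSV mirroring the published volumetric-table layout: ROI, mean +/- SD
#' per group, p-value and FDR flag.
#'
#' @param result An `ancova_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_ancova_table <- function(result, path) {
  stopifnot(inherits(result, "ancova_result"))
  g <- attr(result, "groups")
  fmt <- function(m, s) sprintf("%.0f ± %.0f", m, s)
  out <- data.frame(
    Data = result$roi,
    other = fmt(result$mean_other, result$sd_other),
    ref = fmt(result$mean_ref, result$sd_ref),
    `p value` = signif(result$p, 3),
    `FDR significant` = result$fdr_significant, check.names = FALSE)
  names(out)[2:3] <- c(g["other"], g["reference"])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Spearman association between a volume and an external variable
#'
#' Rank correlation with midrank ties; exact p-value for n <= 9 without
#' ties, t approximation otherwise (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors (at least 5 complete pairs).
#' @return List with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_assoc(1:5, c(1, 3, 2, 5, 4))
spearman_assoc <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: rho undefined")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- stats::cor.test(x, y, method = "spearman",
                        exact = (n <= 9 && !ties))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Spearman associations for a set of ROIs
#'
#' @param cohort A `cohort_table`.
#' @param variable Column name of the external variable (e.g. `"age"`).
#' @param rois ROI columns (default: all volume columns).
#' @param group Optional group label to subset first.
#' @param q FDR level for the across-ROI family.
#' @return Data frame: roi, rho, p, fdr_significant.
#' @export
spearman_table <- function(cohort, variable, rois = NULL, group = NULL,
                           q = 0.05) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!variable %in% names(cohort)) {
    stop("variable not in cohort: ", variable)
  }
  if (is.null(rois)) rois <- volume_cols(cohort)
  tab <- as.data.frame(cohort)
  if (!is.null(group)) tab <- tab[tab$group == group, , drop = FALSE]
  res <- do.call(rbind, lapply(rois, function(roi) {
    a <- spearman_assoc(tab[[roi]], tab[[variable]])
    data.frame(roi = roi, rho = a$rho, p = a$p, n = a$n)
  }))
  res$fdr_significant <- bh_fdr(res$p, q)
  rownames(res) <- NULL
  res
}
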