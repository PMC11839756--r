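#' Fit the covariate-adjustment model
#'
#' Fits, for every volume column, an ordinary least-squares regression of
#' volume on the covariates (by default age, sex and intracranial volume),
#' pooled over both groups. Per-ROI R^2 is reported as a message. Pooled
#' fitting is the default so that group differences are not regressed out
#' asymmetrically and permutation inference on the residuals stays
#' exchangeable; `per_group = TRUE` fits each group separately for
#' sensitivity checks.
#'
#' @param cohort A `cohort_table`.
#' @param covariates Covariate column names (default `c("age", "sex",
#'   "icv")`).
#' @param per_group Fit separate coefficients per group (default `FALSE`).
#' @return An `adjustment_model`: list with `coefficients` (one
#'   `(1 + n_cov) x n_roi` matrix, or one per group), `covariates`,
#'   `per_group`, `rois`, `n_fit`.
#' @export
fit_adjustment <- function(cohort, covariates = c("age", "sex", "icv"),
                           per_group = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  missing <- setdiff(covariates, names(cohort))
  if (length(missing) > 0) {
    stop("covariate(s) not in cohort: ", paste(missing, collapse = ", "))
  }
  rois <- volume_cols(cohort)
  if (nrow(cohort) < length(covariates) + 2) {
    stop("need at least ", length(covariates) + 2, " subjects")
  }
  fit_one <- function(tab) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(tab)[, covariates, drop = FALSE]))
    if (anyNA(X)) {
      bad <- tab$subject_id[apply(is.na(X), 1, any)]
      stop("missing covariate for subject(s): ", paste(bad, collapse = ", "))
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      # identify which covariate is redundant (constant or collinear)
      drop <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
      stop("rank-deficient design; offending covariate(s): ",
           paste(colnames(X)[drop], collapse = ", "))
    }
    Y <- as.matrix(as.data.frame(tab)[, rois, drop = FALSE])
    B <- qr.coef(qx, Y)
    fitted <- X %*% B
    r2 <- 1 - colSums((Y - fitted)^2) /
      pmax(colSums(scale(Y, scale = FALSE)^2), .Machine$double.eps)
    message("fit_adjustment: n = ", nrow(tab), ", median R^2 = ",
            signif(stats::median(r2), 3))
    B
  }
  coefs <- if (per_group) {
    lapply(split(as.data.frame(cohort), cohort$group), fit_one)
  } else {
    fit_one(cohort)
  }
  structure(list(coefficients = coefs, covariates = covariates,
                 per_group = per_group, rois = rois, n_fit = nrow(cohort)),
            class = "adjustment_model")
}

#' Remove covariate effects from volumes
#'
#' Replaces every volume column by its regression residual (observed minus
#' fitted value under the model). On the fitting sample, residual means per
#' ROI are zero and residuals are uncorrelated with each covariate (OLS
#' identities). Residuals are not re-centered per group and the grand mean
#' is not added back: correlations, the downstream consumer, are
#' location-invariant.
#'
#' @param cohort A `cohort_table`.
#' @param model An `adjustment_model` covering all volume columns of
#'   `cohort`.
#' @return A `cohort_table` of adjusted volumes (identifier, group and
#'   covariate columns preserved).
#' @export
residualize <- function(cohort, model) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(model, "adjustment_model"))
  rois <- volume_cols(cohort)
  missing <- setdiff(rois, model$rois)
  if (length(missing) > 0) {
    stop("model does not cover ROI(s): ", paste(missing, collapse = ", "))
  }
  tab <- as.data.frame(cohort)
  X <- cbind(1, as.matrix(tab[, model$covariates, drop = FALSE]))
  if (anyNA(X)) {
    bad <- tab$subject_id[apply(is.na(X), 1, any)]
    stop("missing covariate for subject(s): ", paste(bad, collapse = ", "))
  }
  resid_for <- function(rows, B) {
    as.matrix(tab[rows, rois, drop = FALSE]) -
      X[rows, , drop = FALSE] %*% B[, rois, drop = FALSE]
  }
  if (model$per_group) {
    for (g in names(model$coefficients)) {
      rows <- which(tab$group == g)
      if (length(rows) > 0) {
        tab[rows, rois] <- resid_for(rows, model$coefficients[[g]])
      }
    }
  } else {
    tab[, rois] <- resid_for(seq_len(nrow(tab)), model$coefficients)
  }
  cohort_table(tab, volume_cols = rois, adjusted = TRUE)
}

#' Write adjustment coefficients
#'
#' @param model An `adjustment_model` (pooled fit).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_adjustment_model <- function(model, path) {
  stopifnot(inherits(model, "adjustment_model"))
  B <- if (model$per_group) {
    do.call(rbind, lapply(names(model$coefficients), function(g) {
      data.frame(group = g, roi = model$rois,
                 t(model$coefficients[[g]]), check.names = FALSE)
    }))
  } else {
    data.frame(roi = model$rois, t(model$coefficients), check.names = FALSE)
  }
  utils::write.table(B, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
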