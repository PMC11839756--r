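#' Construct a cohort table
#'
#' A cohort table holds one row per subject: a subject identifier, a group
#' label, the covariates (age in years, sex coded 0/1, intracranial volume
#' in mm^3) and one volume column per ROI or network node (mm^3). Sex given
#' as a two-level text column is coded deterministically 0/1 by sorted label
#' order, and the coding is recorded in the `sex_levels` attribute.
#'
#' @param tab Data frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `icv` plus numeric volume columns.
#' @param volume_cols Character vector naming the volume columns; default:
#'   every numeric column other than the covariates.
#' @param adjusted Set `TRUE` for covariate-adjusted tables (residuals):
#'   volumes may then be negative.
#' @param allow_negative Permit negative volumes without marking the table
#'   adjusted (used by the Gaussian simulator, whose tails can cross
#'   zero).
#' @return The validated table, class `cohort_table`, with attributes
#'   `volume_cols` and `sex_levels`.
#' @export
cohort_table <- function(tab, volume_cols = NULL, adjusted = FALSE,
                         allow_negative = adjusted) {
  required <- c("subject_id", "group", "age", "sex", "icv")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id) > 0) {
    stop("duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  }
  sex_levels <- NULL
  if (!is.numeric(tab$sex)) {
    lev <- sort(unique(as.character(tab$sex)))
    if (length(lev) > 2) stop("sex must have at most two levels")
    sex_levels <- stats::setNames(seq_along(lev) - 1L, lev)
    tab$sex <- as.numeric(sex_levels[as.character(tab$sex)])
  }
  for (cv in c("age", "sex", "icv")) {
    if (!is.numeric(tab[[cv]]) || any(!is.finite(tab[[cv]]))) {
      stop("covariate '", cv, "' must be finite numeric")
    }
  }
  if (is.null(volume_cols)) {
    cand <- setdiff(names(tab), required)
    volume_cols <- cand[vapply(tab[cand], is.numeric, logical(1))]
  }
  if (length(volume_cols) == 0) stop("no volume columns found")
  for (vc in volume_cols) {
    v <- tab[[vc]]
    if (!is.numeric(v)) stop("volume column '", vc, "' is not numeric")
    if (any(!is.finite(v))) stop("non-finite volume in column '", vc, "'")
    if (!allow_negative && any(v < 0)) {
      stop("negative volume in column '", vc, "'")
    }
  }
  structure(tab, class = c("cohort_table", "data.frame"),
            volume_cols = volume_cols, sex_levels = sex_levels,
            adjusted = adjusted)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x), "subjects,",
      length(attr(x, "volume_cols")), "volume columns\n")
  print(table(group = x$group))
  invisible(x)
}

#' Volume columns of a cohort table
#' @param cohort A `cohort_table`.
#' @return Character vector of volume column names.
#' @export
volume_cols <- function(cohort) {
  vc <- attr(cohort, "volume_cols")
  if (is.null(vc)) stop("not a cohort_table (no volume_cols attribute)")
  vc
}

#' Read a subject-level volume table
#'
#' Reads a TSV (or CSV, by file extension) with a header and one row per
#' subject, validates it and reports group sizes. Columns can be renamed to
#' the canonical schema through `schema`.
#'
#' @param path File path.
#' @param schema Named character vector mapping canonical names
#'   (`subject_id`, `group`, `age`, `sex`, `icv`) to the column names used
#'   in the file; defaults to the canonical names themselves.
#' @param volume_cols Optional explicit volume column selection (file
#'   names, after renaming).
#' @param adjusted Set `TRUE` when reading a covariate-adjusted (residual)
#'   table, whose volumes may be negative.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, schema = NULL, volume_cols = NULL,
                        adjusted = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(tab)) {
        stop("schema column '", src, "' (for '", canon, "') not in file")
      }
      names(tab)[names(tab) == src] <- canon
    }
  }
  missing <- setdiff(c("subject_id", "group", "age", "sex", "icv"), names(tab))
  if (length(missing) > 0) {
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- cohort_table(tab, volume_cols = volume_cols, adjusted = adjusted)
  n <- table(out$group)
  message("read_cohort: ", nrow(out), " subjects (",
          paste(names(n), n, sep = " = ", collapse = ", "), ")")
  extras <- setdiff(names(out),
                    c("subject_id", "group", "age", "sex", "icv",
                      volume_cols(out)))
  if (length(extras) > 0) {
    message("read_cohort: extra column(s) retained: ",
            paste(extras, collapse = ", "))
  }
  out
}

#' Read a per-subject segmentation volume file
#'
#' Parses the simple "label value" per-line listing produced by
#' segmentation pipelines (whitespace- or comma-delimited). Labels are
#' normalized with [normalize_parcel()].
#'
#' @param path File path.
#' @return Named numeric vector of volumes (mm^3).
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("Left-LGN 223.0", "Left-MGN 109.0"), f)
#' read_freesurfer_volumes(f)
read_freesurfer_volumes <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("no volumes found in ", path)
  labels <- character(length(lines))
  values <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    if (length(parts) < 2) stop("unparseable line ", i, " in ", path)
    val <- suppressWarnings(as.numeric(parts[length(parts)]))
    if (is.na(val)) stop("unparseable line ", i, " in ", path)
    labels[i] <- normalize_parcel(paste(parts[-length(parts)], collapse = " "))
    values[i] <- val
  }
  if (anyDuplicated(labels) > 0) {
    stop("duplicated label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  stats::setNames(values, labels)
}

#' Tukey fence outlier flags for one ROI
#'
#' Flags values below `Q1 - 1.5 IQR` as `low` and above `Q3 + 1.5 IQR` as
#' `high`. Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), the convention recorded in the QC report.
#'
#' @param values Numeric vector of per-subject volumes (at least 4 finite
#'   values; quartiles are unstable below that).
#' @return Character vector (`"none"`, `"low"`, `"high"`) with attribute
#'   `fences = c(lower, upper)` and `quartiles = c(q1, q3)`.
#' @export
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))
iqr_outliers <- function(values) {
  if (sum(is.finite(values)) < 4) {
    stop("iqr_outliers needs at least 4 finite values")
  }
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  flag <- rep("none", length(values))
  flag[values < fences[1]] <- "low"
  flag[values > fences[2]] <- "high"
  structure(flag, fences = fences, quartiles = c(q1 = q[1], q3 = q[2]))
}

#' Whole-thalamus vs summed-nuclei consistency check
#'
#' Compares the whole-thalamus volume from the primary segmentation with the
#' sum of the atlas-based nucleus volumes; a large relative difference marks
#' a suspect segmentation.
#'
#' @param whole_thalamus Whole-thalamus volume(s), mm^3, > 0.
#' @param nuclei_sum Summed nucleus volume(s), mm^3, > 0.
#' @param tolerance Relative-difference threshold (default 0.10).
#' @return Data frame with columns `ratio` (|whole - sum| / whole) and
#'   `flagged`.
#' @export
thalamus_consistency <- function(whole_thalamus, nuclei_sum,
                                 tolerance = 0.10) {
  if (any(!is.finite(whole_thalamus)) || any(whole_thalamus <= 0) ||
      any(!is.finite(nuclei_sum)) || any(nuclei_sum <= 0)) {
    stop("volumes must be finite and positive")
  }
  ratio <- abs(whole_thalamus - nuclei_sum) / whole_thalamus
  data.frame(ratio = ratio, flagged = ratio > tolerance)
}

#' Statistical QC report for a cohort
#'
#' Applies [iqr_outliers()] to every ROI across subjects and, where a
#' whole-thalamus column is available, [thalamus_consistency()] per subject
#' and hemisphere. The cohort itself is never modified; exclusion is a
#' separate step ([apply_qc_exclusions()]).
#'
#' @param cohort A `cohort_table`.
#' @param rois ROI columns to screen; default all volume columns.
#' @param whole_thalamus Optional named list, e.g.
#'   `list(left = "left whole thalamus")`, giving whole-thalamus columns;
#'   nucleus sums are taken over the thalamic node columns of that
#'   hemisphere.
#' @param tolerance Consistency tolerance passed to
#'   [thalamus_consistency()].
#' @return List of class `qc_report`: `outliers` (data frame subject, roi,
#'   flag, value, fence_low, fence_high — flagged rows only), `consistency`
#'   (data frame or NULL), `summary` (named counts), `quartile_method`.
#' @export
qc_report <- function(cohort, rois = NULL, whole_thalamus = NULL,
                      tolerance = 0.10) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(rois)) rois <- volume_cols(cohort)
  rows <- list()
  for (roi in rois) {
    fl <- iqr_outliers(cohort[[roi]])
    hit <- which(fl != "none")
    if (length(hit) > 0) {
      fences <- attr(fl, "fences")
      rows[[roi]] <- data.frame(
        subject_id = cohort$subject_id[hit], roi = roi, flag = fl[hit],
        value = cohort[[roi]][hit],
        fence_low = fences[1], fence_high = fences[2], row.names = NULL)
    }
  }
  outliers <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(subject_id = character(), roi = character(),
               flag = character(), value = numeric(),
               fence_low = numeric(), fence_high = numeric())
  rownames(outliers) <- NULL
  outliers <- outliers[order(outliers$subject_id, outliers$roi), ,
                       drop = FALSE]
  consistency <- NULL
  if (!is.null(whole_thalamus)) {
    thal_groups <- c("ventral", "anteroventral", "medial", "lateral",
                     "pulvinar", "geniculate")
    cons <- list()
    for (h in names(whole_thalamus)) {
      nuclei <- intersect(paste(h, thal_groups), names(cohort))
      if (length(nuclei) == 0) stop("no thalamic node columns for ", h)
      tc <- thalamus_consistency(cohort[[whole_thalamus[[h]]]],
                                 rowSums(as.matrix(cohort[, nuclei])),
                                 tolerance)
      cons[[h]] <- data.frame(subject_id = cohort$subject_id,
                              hemisphere = h, tc, row.names = NULL)
    }
    consistency <- do.call(rbind, cons)
    rownames(consistency) <- NULL
  }
  res <- list(
    outliers = outliers,
    consistency = consistency,
    summary = c(n_subjects = nrow(cohort), n_rois = length(rois),
                n_outlier_flags = nrow(outliers),
                n_consistency_flags =
                  if (is.null(consistency)) 0L else sum(consistency$flagged)),
    quartile_method = "linear interpolation (type 7)",
    tolerance = tolerance)
  class(res) <- "qc_report"
  res
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report (quartiles:", x$quartile_method, ")\n")
  print(x$summary)
  invisible(x)
}

#' Apply QC exclusions
#'
#' Filtering is opt-in and separate from reporting: by default
#' (`max_outlier_rois = Inf`, `drop_inconsistent = FALSE`) nothing is
#' dropped. Returns a fresh table plus the dropped subject list; the input
#' is untouched.
#'
#' @param cohort A `cohort_table`.
#' @param report A `qc_report` on the same cohort.
#' @param max_outlier_rois Drop subjects flagged as outlier in more than
#'   this many ROIs.
#' @param drop_inconsistent Drop subjects failing the thalamus consistency
#'   check.
#' @return List with `cohort` (filtered `cohort_table`) and `dropped`
#'   (character vector of subject ids).
#' @export
apply_qc_exclusions <- function(cohort, report, max_outlier_rois = Inf,
                                drop_inconsistent = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(report, "qc_report"))
  drop <- character()
  if (is.finite(max_outlier_rois) && nrow(report$outliers) > 0) {
    cnt <- table(report$outliers$subject_id)
    drop <- c(drop, names(cnt)[cnt > max_outlier_rois])
  }
  if (drop_inconsistent && !is.null(report$consistency)) {
    drop <- c(drop, unique(
      report$consistency$subject_id[report$consistency$flagged]))
  }
  drop <- sort(unique(drop))
  keep <- !(cohort$subject_id %in% drop)
  if (length(drop) > 0) {
    message("apply_qc_exclusions: dropping ", length(drop), " subject(s): ",
            paste(drop, collapse = ", "))
  }
  filtered <- cohort_table(as.data.frame(cohort)[keep, , drop = FALSE],
                           volume_cols = volume_cols(cohort),
                           adjusted = isTRUE(attr(cohort, "adjusted")))
  list(cohort = filtered, dropped = drop)
}

#' Write a QC report
#'
#' Writes the outlier table as TSV (with a header comment recording the
#' quartile convention) and the summary as JSON.
#'
#' @param report A `qc_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "qc_outliers.tsv")
  con <- file(tsv, "w", encoding = "UTF-8")
  writeLines(paste0("# quartile method: ", report$quartile_method), con)
  utils::write.table(report$outliers, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  paths <- tsv
  if (!is.null(report$consistency)) {
    p <- file.path(dir, "qc_consistency.tsv")
    utils::write.table(report$consistency, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  js <- file.path(dir, "qc_summary.json")
  writeLines(paste0(
    "{", paste0('"', names(report$summary), '": ', report$summary,
                collapse = ", "),
    ', "quartile_method": "', report$quartile_method, '"}'), js)
  invisible(c(paths, js))
}
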