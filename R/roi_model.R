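#' Canonical 22-node cortical-thalamic network
#'
#' The network analysed by this package has 22 nodes: six thalamic nuclear
#' groups per hemisphere (ventral, anteroventral, medial, lateral, pulvinar,
#' geniculate) and five cortical lobes per hemisphere (frontal, parietal,
#' temporal, occipital, cingulate). Node order is fixed: thalamic groups
#' (left hemisphere then right), then lobes (left then right).
#'
#' @return Character vector of the 22 canonical node labels, in canonical
#'   order.
#' @export
#' @examples
#' network_nodes()
network_nodes <- function() {
  thal <- c("ventral", "anteroventral", "medial", "lateral", "pulvinar",
            "geniculate")
  lobe <- c("frontal", "parietal", "temporal", "occipital", "cingulate")
  c(paste("left", thal), paste("right", thal),
    paste("left", lobe), paste("right", lobe))
}

#' Normalize a parcel or node name
#'
#' Parcel names coming out of segmentation pipelines differ in case and
#' separator conventions (`Left-LGN`, `left_lgn`, `Left LGN`). Matching is
#' therefore case-insensitive with space, underscore and hyphen treated as
#' equivalent, and the filler words "nucleus"/"nuclei" dropped.
#'
#' @param x Character vector of names.
#' @return Normalized names: lower case, single-space separated.
#' @export
#' @examples
#' normalize_parcel(c("Left-LGN", "ventral lateral posterior nucleus"))
normalize_parcel <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[-_/]+", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  x <- gsub("\\b(nucleus|nuclei)\\b", "", x)
  gsub("\\s+", " ", trimws(x))
}

#' Construct an ROI mapping
#'
#' An ROI mapping is a many-to-one map from fine parcels (thalamic nuclei or
#' Desikan-Killiany cortical regions, hemisphere included in the name) to
#' network node labels. Parcels are normalized with [normalize_parcel()];
#' each parcel may map to exactly one node.
#'
#' @param parcel Character vector of parcel names (with hemisphere prefix).
#' @param node Character vector of target node labels, same length.
#' @return A `data.frame` of class `roi_mapping` with columns `parcel`,
#'   `node`.
#' @export
roi_mapping <- function(parcel, node) {
  stopifnot(length(parcel) == length(node), length(parcel) > 0)
  parcel <- normalize_parcel(parcel)
  node <- normalize_parcel(node)
  dup <- duplicated(parcel)
  if (any(dup)) {
    bad <- unique(parcel[dup])
    stop("parcel(s) mapped more than once: ", paste(bad, collapse = ", "))
  }
  out <- data.frame(parcel = parcel, node = node, stringsAsFactors = FALSE)
  class(out) <- c("roi_mapping", "data.frame")
  out
}

#' Read / write a mapping file
#'
#' Mapping files are two-column TSVs with a header line
#' (`parcel_name<TAB>node_label`), the format the default mappings are
#' shipped in, so users can extend or replace them.
#'
#' @param path Path to a mapping TSV.
#' @return [read_roi_mapping()]: an `roi_mapping`.
#' @export
read_roi_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("mapping file must have two columns: ", path)
  roi_mapping(tab[[1]], tab[[2]])
}

#' @rdname read_roi_mapping
#' @param mapping An `roi_mapping`.
#' @export
write_roi_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "roi_mapping"))
  out <- data.frame(parcel_name = mapping$parcel, node_label = mapping$node)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "thalnet")
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}

#' Default thalamic nuclei grouping
#'
#' Maps the fine thalamic nuclei of the probabilistic atlas to the six
#' nuclear groups used as network nodes in each hemisphere: anteroventral;
#' lateral (lateral dorsal, lateral posterior); medial (central medial,
#' paracentral, parvocellular and medial mediodorsal, parafascicular,
#' centromedian, central lateral, reuniens, paratenial); pulvinar (anterior,
#' inferior, lateral, medial pulvinar); ventral (ventral anterior,
#' ventromedial, ventral lateral anterior, ventral lateral posterior,
#' ventral posterolateral); and geniculate (lateral and medial geniculate,
#' merged into one node per hemisphere). Common abbreviations (LGN, MGN) are
#' included as synonyms. Atlas labels not listed here (for example a
#' whole-thalamus label) are not part of any group and pass through
#' aggregation untouched.
#'
#' @return An `roi_mapping` with 12 distinct target nodes (6 groups x 2
#'   hemispheres).
#' @export
#' @examples
#' m <- default_thalamic_mapping()
#' map_parcel(m, "ventral lateral posterior nucleus", "left")
default_thalamic_mapping <- function() {
  read_roi_mapping(.extdata("thalamic_nuclei_mapping.tsv"))
}

#' Default cortical lobe grouping
#'
#' Maps the 34 Desikan-Killiany cortical regions per hemisphere to the five
#' anatomical lobes (frontal, parietal, temporal, occipital, cingulate). The
#' insula belongs to none of the five lobes; by default it is left unmapped
#' (and so passes through aggregation untouched, with a note), but it can be
#' merged into the frontal or temporal lobe.
#'
#' @param insula One of `"exclude"` (default), `"frontal"`, `"temporal"`.
#' @return An `roi_mapping` with 10 distinct target nodes.
#' @export
default_lobe_mapping <- function(insula = c("exclude", "frontal", "temporal")) {
  insula <- match.arg(insula)
  m <- read_roi_mapping(.extdata("dk_lobe_mapping.tsv"))
  if (insula != "exclude") {
    extra <- roi_mapping(c("left insula", "right insula"),
                         paste(c("left", "right"), insula))
    m <- roi_mapping(c(m$parcel, extra$parcel), c(m$node, extra$node))
  }
  m
}

#' Look up the node a parcel belongs to
#'
#' @param mapping An `roi_mapping`.
#' @param parcel Parcel name, with or without hemisphere prefix.
#' @param hemisphere Optional `"left"`/`"right"`, prepended when `parcel`
#'   does not already carry a hemisphere.
#' @return The node label, or `NA_character_` if unmapped.
#' @export
map_parcel <- function(mapping, parcel, hemisphere = NULL) {
  stopifnot(inherits(mapping, "roi_mapping"))
  key <- normalize_parcel(parcel)
  if (!is.null(hemisphere) && !grepl("^(left|right) ", key)) {
    key <- paste(normalize_parcel(hemisphere), key)
  }
  i <- match(key, mapping$parcel)
  if (is.na(i)) NA_character_ else mapping$node[i]
}

#' Aggregate fine parcel volumes to network nodes
#'
#' Each node's volume is the sum of the volumes of its member parcels.
#' Non-volume columns (identifiers, covariates) and columns that do not
#' match any mapping entry are passed through untouched; unmatched volume
#' columns are reported with a message. Output node columns follow the
#' canonical node order of [network_nodes()] where applicable.
#'
#' @param tab Data frame, one row per subject, with one column per parcel
#'   (column names are matched after [normalize_parcel()]).
#' @param mapping An `roi_mapping`.
#' @param require_complete If `TRUE` (default) every parcel listed in the
#'   mapping must be present as a column; missing parcels are an error.
#' @return Data frame with parcel columns replaced by aggregated node
#'   columns.
#' @export
aggregate_parcels <- function(tab, mapping, require_complete = TRUE) {
  stopifnot(is.data.frame(tab), inherits(mapping, "roi_mapping"))
  norm <- normalize_parcel(names(tab))
  hit <- norm %in% mapping$parcel
  if (require_complete) {
    missing <- setdiff(mapping$parcel, norm)
    if (length(missing) > 0) {
      stop("parcel(s) required by mapping missing from table: ",
           paste(missing, collapse = ", "))
    }
  }
  if (!any(hit)) stop("no mapped parcel columns found in table")
  vols <- as.matrix(tab[, hit, drop = FALSE])
  if (!is.numeric(vols)) stop("mapped parcel columns must be numeric")
  if (anyNA(vols) || any(!is.finite(vols))) {
    bad <- which(!is.finite(vols), arr.ind = TRUE)
    stop("non-finite volume for parcel '", norm[hit][bad[1, 2]],
         "' in row ", bad[1, 1])
  }
  if (any(vols < 0)) {
    bad <- which(vols < 0, arr.ind = TRUE)
    stop("negative volume for parcel '", norm[hit][bad[1, 2]],
         "' in row ", bad[1, 1])
  }
  node_of <- mapping$node[match(norm[hit], mapping$parcel)]
  targets <- unique(mapping$node)
  canon <- network_nodes()
  targets <- c(intersect(canon, targets), sort(setdiff(targets, canon)))
  agg <- sapply(targets, function(nd) {
    cols <- which(node_of == nd)
    if (length(cols) == 0) return(rep(0, nrow(vols)))
    rowSums(vols[, cols, drop = FALSE])
  })
  if (nrow(tab) == 1) agg <- matrix(agg, nrow = 1, dimnames = list(NULL, targets))
  extras <- names(tab)[!hit]
  numeric_extras <- extras[vapply(tab[extras], is.numeric, logical(1))]
  unmatched <- setdiff(normalize_parcel(numeric_extras),
                       c("age", "sex", "icv"))
  if (length(unmatched) > 0) {
    message("unmapped column(s) passed through: ",
            paste(unmatched, collapse = ", "))
  }
  out <- cbind(tab[, !hit, drop = FALSE], as.data.frame(agg, optional = TRUE))
  names(out) <- c(extras, targets)
  rownames(out) <- NULL
  out
}

#' Assert that a mapping partitions its parcels
#'
#' @param mapping An `roi_mapping`.
#' @return `TRUE` invisibly; errors if any parcel maps to two nodes.
#' @export
assert_partition <- function(mapping) {
  stopifnot(inherits(mapping, "roi_mapping"))
  if (anyDuplicated(mapping$parcel) > 0) {
    stop("mapping is not a partition")
  }
  invisible(TRUE)
}
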