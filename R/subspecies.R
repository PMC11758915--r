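#' Filter subspecies marker-gene hits
#'
#' Keeps alignments of MAG genes against subspecies-specific marker genes that
#' reach both inclusive thresholds: >= 90\% alignment identity and >= 50\%
#' coverage.
#'
#' @param hits data.frame with at least \code{mag_id}, \code{marker_id},
#'   \code{pident}, \code{qcovs}.
#' @param min_identity,min_coverage inclusive thresholds (\%).
#' @return the retained hits.
#' @export
filter_marker_hits <- function(hits, min_identity = 90, min_coverage = 50) {
  stop_if_not_cols(hits, c("mag_id", "marker_id", "pident", "qcovs"),
                   "marker hit table")
  out <- hits[hits$pident >= min_identity & hits$qcovs >= min_coverage, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the marker copy-number matrix
#'
#' Cell (MAG, marker) = number of the MAG's genes hitting that marker after
#' filtering; absent combinations are zero-filled so every roster MAG has a
#' row and every roster marker a column.
#'
#' @param hits filtered hits from [filter_marker_hits()].
#' @param mag_roster character vector of MAG ids.
#' @param markers data.frame with \code{marker_id} and \code{subspecies}
#'   (\code{"BLinfantis"} / \code{"BLlongum"}).
#' @return integer matrix MAGs x markers with a \code{"subspecies"} attribute
#'   (named vector marker -> subspecies).
#' @export
build_marker_matrix <- function(hits, mag_roster, markers) {
  stop_if_not_cols(markers, c("marker_id", "subspecies"), "marker roster")
  unknown <- setdiff(hits$marker_id, markers$marker_id)
  if (length(unknown))
    stop("unknown marker id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- table(factor(hits$mag_id, levels = mag_roster),
             factor(hits$marker_id, levels = markers$marker_id))
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  attr(m, "subspecies") <- setNames(markers$subspecies, markers$marker_id)
  m
}

#' Assign B. longum MAGs to subspecies from marker copy numbers
#'
#' Hierarchically clusters MAGs on their marker copy-number vectors (euclidean
#' distance, Ward.D2 linkage), cuts the tree at k = 2, and labels each cluster
#' by the subspecies whose marker set has the larger mean total copy number
#' among the cluster's members. An exact tie between the two candidate labels,
#' or both clusters resolving to the same label, raises an error rather than
#' guessing.
#'
#' @param marker_matrix matrix from [build_marker_matrix()] (or any MAGs x
#'   markers matrix plus a \code{marker_subspecies} vector).
#' @param marker_subspecies named vector marker -> subspecies; defaults to the
#'   matrix's \code{"subspecies"} attribute.
#' @return data.frame, one row per MAG: \code{mag_id}, \code{label},
#'   \code{infantis_total}, \code{longum_total}, \code{cluster}.
#' @export
assign_subspecies <- function(marker_matrix, marker_subspecies = NULL) {
  if (nrow(marker_matrix) < 2L) stop("need >= 2 MAGs", call. = FALSE)
  marker_subspecies <- marker_subspecies %||% attr(marker_matrix, "subspecies")
  if (is.null(marker_subspecies))
    stop("marker -> subspecies mapping required", call. = FALSE)
  marker_subspecies <- marker_subspecies[colnames(marker_matrix)]
  hc <- stats::hclust(stats::dist(marker_matrix), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  inf_total <- rowSums(marker_matrix[, marker_subspecies == "BLinfantis",
                                     drop = FALSE])
  lon_total <- rowSums(marker_matrix[, marker_subspecies == "BLlongum",
                                     drop = FALSE])
  lab <- character(2)
  for (g in 1:2) {
    mi <- mean(inf_total[cl == g]); ml <- mean(lon_total[cl == g])
    if (isTRUE(all.equal(mi, ml)))
      stop("cluster ", g, ": marker totals tied between subspecies; ",
           "cannot label", call. = FALSE)
    lab[g] <- if (mi > ml) "BLinfantis" else "BLlongum"
  }
  if (lab[1] == lab[2])
    stop("both clusters resolve to the same subspecies label (", lab[1],
         "); marker matrix does not separate the subspecies", call. = FALSE)
  data.frame(mag_id = rownames(marker_matrix), label = lab[cl],
             infantis_total = unname(inf_total), longum_total = unname(lon_total),
             cluster = unname(cl), stringsAsFactors = FALSE)
}
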