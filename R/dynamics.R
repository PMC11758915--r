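#' Call per-sample taxon presence
#'
#' A taxon is present in a sample when its relative abundance is strictly
#' greater than the presence threshold (default 0.01\% of the total
#' community).
#'
#' @param cohort cohort table (see [simulate_cohort()] / [read_cohort_table()]).
#' @param threshold presence threshold in \% (strict inequality).
#' @return long data.frame: \code{sample_id}, \code{pair_id}, \code{role},
#'   \code{timepoint}, \code{taxon}, \code{abundance}, \code{present}.
#' @export
call_presence <- function(cohort, threshold = 0.01) {
  taxa <- cohort_taxa(cohort)
  ab <- as.matrix(cohort[, taxa, drop = FALSE])
  if (any(ab < 0)) stop("negative abundance in cohort table", call. = FALSE)
  out <- data.frame(
    sample_id = rep(cohort$sample_id, times = length(taxa)),
    pair_id = rep(cohort$pair_id, times = length(taxa)),
    role = rep(cohort$role, times = length(taxa)),
    timepoint = rep(cohort$timepoint, times = length(taxa)),
    taxon = rep(taxa, each = nrow(cohort)),
    abundance = as.vector(ab),
    stringsAsFactors = FALSE)
  out$present <- out$abundance > threshold
  out
}

#' Prevalence and abundance-when-present summary for one stratum
#'
#' Prevalence is the fraction of stratum samples where the taxon exceeds the
#' presence threshold; mean and SD are computed over the present samples only
#' ("abundance when detected") and reported as \code{NA} when the taxon is
#' never present.
#'
#' @param cohort cohort table.
#' @param taxon taxon column name.
#' @param role \code{"mother"} or \code{"infant"} (optional filter).
#' @param timepoint \code{"prenatal"}, \code{"1m"} or \code{"6m"} (optional).
#' @param threshold presence threshold in \%.
#' @return one-row data.frame: \code{taxon}, \code{n}, \code{prevalence}
#'   (\%), \code{mean_when_present}, \code{sd_when_present}.
#' @export
summarize_prevalence_abundance <- function(cohort, taxon, role = NULL,
                                           timepoint = NULL,
                                           threshold = 0.01) {
  if (!taxon %in% cohort_taxa(cohort))
    stop("unknown taxon: ", taxon, call. = FALSE)
  sub <- cohort
  if (!is.null(role)) sub <- sub[sub$role == role, , drop = FALSE]
  if (!is.null(timepoint))
    sub <- sub[sub$timepoint == timepoint, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no samples in stratum", call. = FALSE)
  ab <- sub[[taxon]]
  present <- ab > threshold
  data.frame(
    taxon = taxon, n = length(ab), prevalence = 100 * mean(present),
    mean_when_present = if (any(present)) mean(ab[present]) else NA_real_,
    sd_when_present = if (any(present)) stats::sd(ab[present]) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Derive arrival-order proxies for a taxon
#'
#' Early arrival of a (sub)species cannot be observed directly in
#' cross-sectional stool samples; three proxies are derived per pair:
#' \describe{
#'   \item{maternal_dominance}{the focal taxon is the strictly most abundant
#'     bifidobacterial taxon in the reference sample (the mother's prenatal
#'     sample for 1m infants; for 6m infants the mother's sample, falling back
#'     to the infant's own 1m sample) \emph{and} its abundance there exceeds
#'     0.1\%.}
#'   \item{strain_sharing}{a maternal strain of the taxon was detected in the
#'     infant (read from the pair metadata).}
#'   \item{either}{the logical OR of the two.}
#' }
#' Pairs without a usable reference sample get \code{NA} (missing, not FALSE).
#'
#' @param cohort cohort table.
#' @param metadata pair metadata with \code{shared_<taxon>_<timepoint>}
#'   columns.
#' @param taxon focal taxon.
#' @param timepoint infant timepoint, \code{"1m"} or \code{"6m"}.
#' @param dominance_threshold abundance floor (\%) for the dominance proxy.
#' @return data.frame per pair: \code{pair_id}, \code{taxon},
#'   \code{timepoint}, \code{maternal_dominance}, \code{strain_sharing},
#'   \code{either}.
#' @export
derive_arrival_proxies <- function(cohort, metadata, taxon,
                                   timepoint = "1m",
                                   dominance_threshold = 0.1) {
  taxa <- cohort_taxa(cohort)
  if (length(taxa) == 0L)
    stop("no bifidobacterial taxa in cohort table", call. = FALSE)
  if (!taxon %in% taxa) stop("unknown taxon: ", taxon, call. = FALSE)
  share_col <- paste0("shared_", taxon, "_", timepoint)
  stop_if_not_cols(metadata, c("pair_id", share_col), "pair metadata")

  infants <- cohort[cohort$role == "infant" & cohort$timepoint == timepoint, ]
  out <- lapply(infants$pair_id, function(p) {
    ref <- cohort[cohort$pair_id == p & cohort$role == "mother", ]
    if (nrow(ref) == 0L && timepoint == "6m")
      ref <- cohort[cohort$pair_id == p & cohort$role == "infant" &
                      cohort$timepoint == "1m", ]
    dom <- NA
    if (nrow(ref) >= 1L) {
      ab <- as.numeric(ref[1, taxa])
      names(ab) <- taxa
      dom <- ab[[taxon]] > dominance_threshold &&
        ab[[taxon]] > max(ab[setdiff(taxa, taxon)])
    }
    sharing <- metadata[[share_col]][match(p, metadata$pair_id)]
    data.frame(pair_id = p, taxon = taxon, timepoint = timepoint,
               maternal_dominance = dom, strain_sharing = sharing,
               either = dom | sharing, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Priority-effect strength from infant abundances and an arrival proxy
#'
#' The strength of priority effects for a taxon is
#' \deqn{P' = \ln(\bar B_{late} / \bar B_{early})}
#' where \eqn{\bar B_{early}} is the taxon's mean infant abundance among pairs
#' whose arrival proxy is TRUE (early arrival) and \eqn{\bar B_{late}} the
#' mean among the remaining pairs. Negative values indicate an early-arrival
#' advantage. Group difference is tested with an unpaired Wilcoxon rank-sum
#' test when both groups have >= 3 members.
#'
#' @param abundance numeric vector of infant abundances (\%).
#' @param early_arrival logical vector (same length); NA entries are dropped.
#' @param taxon,criterion labels carried into the result.
#' @return list of class \code{"priority_effect"}: \code{taxon},
#'   \code{criterion}, \code{mean_early}, \code{mean_late}, \code{n_early},
#'   \code{n_late}, \code{pprime}, \code{p}, \code{reason} (when undefined).
#' @export
priority_effect_strength <- function(abundance, early_arrival,
                                     taxon = NA_character_,
                                     criterion = "either") {
  stopifnot(length(abundance) == length(early_arrival))
  keep <- !is.na(early_arrival) & !is.na(abundance)
  abundance <- abundance[keep]
  early_arrival <- early_arrival[keep]
  early <- abundance[early_arrival]
  late <- abundance[!early_arrival]
  res <- list(taxon = taxon, criterion = criterion,
              mean_early = if (length(early)) mean(early) else NA_real_,
              mean_late = if (length(late)) mean(late) else NA_real_,
              n_early = length(early), n_late = length(late),
              pprime = NA_real_, p = NA_real_, reason = NA_character_)
  class(res) <- "priority_effect"
  if (length(early) == 0L || length(late) == 0L) {
    res$reason <- "empty group"
    return(res)
  }
  res$pprime <- log(res$mean_late / res$mean_early)  # +/-Inf if a mean is 0
  if (!is.finite(res$pprime)) res$reason <- "zero group mean"
  if (length(early) >= 3L && length(late) >= 3L)
    res$p <- suppressWarnings(
      stats::wilcox.test(early, late, exact = FALSE)$p.value)
  res
}

#' @export
print.priority_effect <- function(x, ...) {
  cat(sprintf(
    "Priority effect [%s, criterion = %s]\n  P' = %.4f (mean early %.3f, n = %d; mean late %.3f, n = %d)\n",
    x$taxon, x$criterion, x$pprime, x$mean_early, x$n_early, x$mean_late,
    x$n_late))
  if (!is.na(x$p)) cat(sprintf("  Wilcoxon rank-sum p = %.4g\n", x$p))
  if (!is.na(x$reason)) cat("  note:", x$reason, "\n")
  invisible(x)
}

#' Priority-effect analysis across criteria and timepoints
#'
#' Computes [priority_effect_strength()] for every combination of arrival
#' criterion (maternal dominance, strain sharing, either) and infant
#' timepoint, applying Benjamini-Hochberg FDR across all group tests.
#'
#' @param cohort cohort table.
#' @param metadata pair metadata.
#' @param taxon focal taxon.
#' @param timepoints infant timepoints to analyze.
#' @param dominance_threshold abundance floor (\%) of the dominance proxy.
#' @return data.frame: one row per criterion x timepoint with group means,
#'   sizes, \code{pprime}, \code{p} and \code{q}.
#' @export
priority_effect_analysis <- function(cohort, metadata, taxon = "BLlongum",
                                     timepoints = c("1m", "6m"),
                                     dominance_threshold = 0.1) {
  criteria <- c("maternal_dominance", "strain_sharing", "either")
  out <- list()
  for (tp in timepoints) {
    proxies <- derive_arrival_proxies(cohort, metadata, taxon, tp,
                                      dominance_threshold)
    infants <- cohort[cohort$role == "infant" & cohort$timepoint == tp, ]
    ab <- infants[[taxon]][match(proxies$pair_id, infants$pair_id)]
    for (cr in criteria) {
      e <- priority_effect_strength(ab, proxies[[cr]], taxon, cr)
      out[[length(out) + 1L]] <- data.frame(
        taxon = taxon, timepoint = tp, criterion = cr,
        mean_early = e$mean_early, mean_late = e$mean_late,
        n_early = e$n_early, n_late = e$n_late, pprime = e$pprime, p = e$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
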