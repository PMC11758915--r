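#' Cluster glycoside hydrolase sequences into variants
#'
#' Groups protein sequences of one GH family into variants by agglomerative
#' hierarchical clustering (Ward linkage on percent dissimilarity,
#' \code{100 - identity}). The tree is cut at the smallest number of clusters
#' such that every multi-member cluster has mean pairwise identity at or above
#' \code{identity_threshold}. Singleton sequences and variants carried by
#' fewer than \code{min_prevalence} of the MAG roster are excluded from the
#' returned variant set and reported separately.
#'
#' @param identity square numeric matrix of pairwise percent identities
#'   (symmetric, diagonal 100, values in [0, 100]), with sequence ids as
#'   dimnames.
#' @param seq_mags named character vector mapping every sequence id to its MAG.
#' @param n_mags size of the MAG roster used for prevalence (defaults to the
#'   number of distinct MAGs in \code{seq_mags}).
#' @param identity_threshold minimum mean within-cluster identity (\%).
#' @param min_prevalence minimum fraction of MAGs carrying >= 1 member.
#' @param family family label attached to variant names (e.g. \code{"GH2"}).
#' @return list with \code{variants} (data.frame: \code{family},
#'   \code{variant}, \code{n_members}, \code{mean_identity},
#'   \code{prevalence}), \code{members} (named list of sequence ids per kept
#'   variant), \code{dropped} (data.frame of excluded clusters with a
#'   \code{reason}), and \code{assignment} (integer cluster id per sequence,
#'   before exclusion).
#' @export
cluster_gh_variants <- function(identity, seq_mags, n_mags = NULL,
                                identity_threshold = 60,
                                min_prevalence = 0.05,
                                family = "GH") {
  validate_identity_matrix(identity)
  ids <- rownames(identity)
  if (!all(ids %in% names(seq_mags)))
    stop("every sequence id needs a MAG in `seq_mags`", call. = FALSE)
  n_mags <- n_mags %||% length(unique(seq_mags))
  n <- nrow(identity)
  assignment <- variant_cut(identity, identity_threshold)

  keep <- list(); members <- list(); dropped <- list()
  v <- 0L
  for (cl in sort(unique(assignment))) {
    idx <- which(assignment == cl)
    mean_id <- if (length(idx) > 1)
      mean(identity[idx, idx][upper.tri(identity[idx, idx])]) else 100
    prev <- length(unique(seq_mags[ids[idx]])) / n_mags
    rec <- data.frame(family = family, n_members = length(idx),
                      mean_identity = mean_id, prevalence = prev,
                      stringsAsFactors = FALSE)
    if (length(idx) == 1L) {
      rec$reason <- "singleton"
      dropped[[length(dropped) + 1L]] <- rec
    } else if (prev < min_prevalence) {
      rec$reason <- "low_prevalence"
      dropped[[length(dropped) + 1L]] <- rec
    } else {
      v <- v + 1L
      rec$variant <- sprintf("%s_v%d", family, v)
      keep[[v]] <- rec[c("family", "variant", "n_members", "mean_identity",
                         "prevalence")]
      members[[rec$variant]] <- ids[idx]
    }
  }
  list(
    variants = if (length(keep)) do.call(rbind, keep) else
      data.frame(family = character(), variant = character(),
                 n_members = integer(), mean_identity = numeric(),
                 prevalence = numeric()),
    members = members,
    dropped = if (length(dropped)) do.call(rbind, dropped) else
      data.frame(family = character(), n_members = integer(),
                 mean_identity = numeric(), prevalence = numeric(),
                 reason = character()),
    assignment = setNames(assignment, ids))
}

# Smallest-k Ward.D2 cut whose multi-member clusters all reach the mean
# within-cluster identity threshold. k = n (all singletons) always qualifies.
variant_cut <- function(identity, identity_threshold) {
  n <- nrow(identity)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(100 - identity), method = "ward.D2")
  for (k in seq_len(n)) {
    assignment <- stats::cutree(hc, k = k)
    ok <- TRUE
    for (cl in unique(assignment)) {
      idx <- which(assignment == cl)
      if (length(idx) < 2L) next
      sub <- identity[idx, idx]
      if (mean(sub[upper.tri(sub)]) < identity_threshold) { ok <- FALSE; break }
    }
    if (ok) return(assignment)
  }
  stats::cutree(hc, k = n)
}

validate_identity_matrix <- function(identity) {
  if (!is.matrix(identity) || nrow(identity) != ncol(identity))
    stop("identity matrix must be square", call. = FALSE)
  if (is.null(rownames(identity)))
    stop("identity matrix needs sequence ids as dimnames", call. = FALSE)
  if (any(identity < 0 | identity > 100))
    stop("identities must lie in [0, 100]", call. = FALSE)
  if (max(abs(identity - t(identity))) > 1e-8)
    stop("identity matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(identity) - 100) > 1e-8))
    stop("identity matrix diagonal must equal 100", call. = FALSE)
  invisible(identity)
}

#' Filter transporter alignment hits and keep the best hit per query
#'
#' Applies the alignment-quality thresholds (bitscore >= 50, e-value <= 0.001,
#' percent identity >= 60, all inclusive) and then, per query sequence, retains
#' only the surviving hit with the highest percent identity (ties broken by
#' first occurrence).
#'
#' @param hits data.frame with at least \code{qseqid}, \code{sseqid},
#'   \code{pident}, \code{evalue}, \code{bitscore}.
#' @param min_bitscore,max_evalue,min_identity filter thresholds.
#' @return the retained best hits, one row per surviving query.
#' @export
filter_transporter_hits <- function(hits, min_bitscore = 50,
                                    max_evalue = 0.001, min_identity = 60) {
  stop_if_not_cols(hits, c("qseqid", "sseqid", "pident", "evalue", "bitscore"),
                   "alignment hit table")
  if (nrow(hits) == 0L) return(hits)
  surv <- hits[hits$bitscore >= min_bitscore & hits$evalue <= max_evalue &
                 hits$pident >= min_identity, , drop = FALSE]
  if (nrow(surv) == 0L) return(surv)
  best <- unlist(lapply(split(seq_len(nrow(surv)), surv$qseqid),
                        function(i) i[which.max(surv$pident[i])]),
                 use.names = FALSE)
  out <- surv[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the per-MAG HMG-utilization profile matrix
#'
#' Copy numbers per MAG: for GH variants the number of member sequences
#' belonging to the MAG, for transporters the number of retained best hits of
#' the MAG's genes against that transporter gene. MAGs with no sequence or hit
#' get explicit all-zero rows.
#'
#' @param variants result of [cluster_gh_variants()] (or a list of such
#'   results, one per family).
#' @param transporter_hits retained hits from [filter_transporter_hits()],
#'   with \code{qseqid} of the form \code{<MAG>_g...} or accompanied by a
#'   \code{mag_id} column; the transporter column is \code{sseqid}.
#' @param mag_roster character vector of all MAG ids.
#' @param seq_mags named vector mapping GH sequence ids to MAGs.
#' @return integer matrix MAGs x (variants + transporter genes).
#' @export
build_profile_matrix <- function(variants, transporter_hits, mag_roster,
                                 seq_mags) {
  if (!is.null(variants$variants)) variants <- list(variants)
  cols <- character(0)
  counts <- list()
  for (res in variants) {
    for (v in names(res$members)) {
      mags <- seq_mags[res$members[[v]]]
      if (any(!mags %in% mag_roster))
        stop("sequence mapped to unknown MAG: ",
             paste(setdiff(mags, mag_roster), collapse = ", "), call. = FALSE)
      counts[[v]] <- table(factor(mags, levels = mag_roster))
      cols <- c(cols, v)
    }
  }
  if (!is.null(transporter_hits) && nrow(transporter_hits) > 0) {
    mag_id <- transporter_hits$mag_id %||%
      sub("_g[^_]*$", "", transporter_hits$qseqid)
    if (any(!mag_id %in% mag_roster))
      stop("hit mapped to unknown MAG: ",
           paste(unique(setdiff(mag_id, mag_roster)), collapse = ", "),
           call. = FALSE)
    for (tr in unique(transporter_hits$sseqid)) {
      counts[[tr]] <- table(factor(mag_id[transporter_hits$sseqid == tr],
                                   levels = mag_roster))
      cols <- c(cols, tr)
    }
  }
  m <- matrix(0L, length(mag_roster), length(cols),
              dimnames = list(mag_roster, cols))
  for (cn in cols) m[, cn] <- as.integer(counts[[cn]])
  m
}

#' Cluster MAGs by HMG-utilization profile
#'
#' Standardizes each gene column to zero mean and unit variance (zero-variance
#' columns are dropped with a warning), computes euclidean distances, applies
#' Ward.D2 agglomerative clustering, and cuts the tree at \code{k}. When
#' \code{k} is not given it is chosen as the number of clusters maximizing the
#' mean silhouette width over k in 2..min(8, n - 1).
#'
#' @param counts numeric matrix, MAGs x genes (raw copy numbers).
#' @param k optional number of clusters.
#' @return list with \code{assignment} (named integer vector), \code{k},
#'   \code{silhouette} (data.frame k/mean width, when k was selected),
#'   \code{dropped_columns}, and the \code{hclust} tree.
#' @export
cluster_profiles <- function(counts, k = NULL) {
  if (nrow(counts) < 2L) stop("need >= 2 MAGs", call. = FALSE)
  vars <- apply(counts, 2, stats::var)
  drop <- colnames(counts)[vars == 0]
  if (length(drop) == ncol(counts))
    stop("all gene columns are constant", call. = FALSE)
  if (length(drop))
    warning("dropping zero-variance column(s): ", paste(drop, collapse = ", "),
            call. = FALSE)
  x <- scale(counts[, vars > 0, drop = FALSE])
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- NULL
  if (is.null(k)) {
    ks <- 2:min(8L, nrow(counts) - 1L)
    widths <- vapply(ks, function(kk) {
      mean(cluster::silhouette(stats::cutree(hc, k = kk), d)[, "sil_width"])
    }, numeric(1))
    sil <- data.frame(k = ks, mean_silhouette = widths)
    k <- ks[which.max(widths)]
  } else if (k > nrow(counts)) {
    stop("k exceeds the number of MAGs", call. = FALSE)
  }
  assignment <- stats::cutree(hc, k = k)
  list(assignment = assignment, k = as.integer(k), silhouette = sil,
       dropped_columns = drop, tree = hc)
}

#' Test per-gene enrichment across HMG-profile clusters
#'
#' For every gene: a Kruskal-Wallis test of \code{log2(count + 1)} across
#' clusters; unpaired pairwise Wilcoxon rank-sum post-hoc tests; and, per
#' cluster, a cluster-of-interest versus remaining-clusters Wilcoxon test with
#' a log2 fold change \code{log2((mean_in + 0.5) / (mean_rest + 0.5))}.
#' Benjamini-Hochberg FDR is applied across all gene x comparison tests
#' (separately for the pairwise and the cluster-vs-rest families). A gene is
#' called \code{enriched} in a cluster when q < 0.05 and log2FC >= 2, and
#' \code{depleted} when q < 0.05 and log2FC <= -2 (a 4-fold change in copy
#' number either way).
#'
#' @param counts numeric matrix, MAGs x genes.
#' @param assignment cluster id per MAG (named vector or in \code{counts}
#'   row order).
#' @param alpha FDR level for verdicts.
#' @return list with \code{records} (data.frame: gene, cluster, kw_stat, kw_p,
#'   mean_in, mean_rest, log2fc, p, q, verdict) and \code{pairwise}
#'   (data.frame: gene, group1, group2, p, q).
#' @export
test_gene_enrichment <- function(counts, assignment, alpha = 0.05) {
  if (!is.null(names(assignment)) && !is.null(rownames(counts)))
    assignment <- assignment[rownames(counts)]
  cl <- factor(assignment)
  if (nlevels(cl) < 2L) stop("need >= 2 clusters", call. = FALSE)
  small <- names(which(table(cl) < 3L))
  if (length(small))
    warning("cluster(s) with < 3 MAGs skipped in post-hoc verdicts: ",
            paste(small, collapse = ", "), call. = FALSE)

  recs <- list(); pw <- list()
  combos <- utils::combn(levels(cl), 2, simplify = FALSE)
  for (g in colnames(counts)) {
    y <- counts[, g]
    ly <- log2(y + 1)
    kw <- tryCatch(stats::kruskal.test(ly, cl),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    for (lev in levels(cl)) {
      inn <- y[cl == lev]; out <- y[cl != lev]
      l2fc <- log2((mean(inn) + 0.5) / (mean(out) + 0.5))
      p <- if (lev %in% small || length(out) < 3L) NA_real_ else
        suppressWarnings(stats::wilcox.test(log2(inn + 1), log2(out + 1),
                                            exact = FALSE)$p.value)
      recs[[length(recs) + 1L]] <- data.frame(
        gene = g, cluster = lev,
        kw_stat = unname(kw$statistic), kw_p = kw$p.value,
        mean_in = mean(inn), mean_rest = mean(out), log2fc = l2fc, p = p,
        stringsAsFactors = FALSE)
    }
    for (cb in combos) {
      a <- y[cl == cb[1]]; b <- y[cl == cb[2]]
      p <- if (length(a) < 3L || length(b) < 3L) NA_real_ else
        suppressWarnings(stats::wilcox.test(log2(a + 1), log2(b + 1),
                                            exact = FALSE)$p.value)
      pw[[length(pw) + 1L]] <- data.frame(gene = g, group1 = cb[1],
                                          group2 = cb[2], p = p,
                                          stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  pairwise <- do.call(rbind, pw)
  records$q <- stats::p.adjust(records$p, method = "BH")
  pairwise$q <- stats::p.adjust(pairwise$p, method = "BH")
  records$verdict <- ifelse(
    !is.na(records$q) & records$q < alpha & records$log2fc >= 2, "enriched",
    ifelse(!is.na(records$q) & records$q < alpha & records$log2fc <= -2,
           "depleted", "none"))
  list(records = records, pairwise = pairwise)
}
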