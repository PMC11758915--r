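#' Simulate a mother-infant cohort with planted ground truth
#'
#' Draws a longitudinal relative-abundance table (mother prenatal, infant at
#' one and six months) plus per-pair metadata (feeding type/frequency,
#' strain-sharing booleans) under the generative model described in
#' [simulation_config()]. Every random draw is governed by \code{config$seed},
#' so identical configurations reproduce byte-identical outputs.
#'
#' @param config a [simulation_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{cohort}{data.frame, one row per sample: \code{sample_id},
#'       \code{pair_id}, \code{role} (mother/infant), \code{timepoint}
#'       (prenatal/1m/6m), one column per taxon (relative abundance, \% of the
#'       total community) and the \code{other_bacteria} closure remainder.}
#'     \item{metadata}{data.frame, one row per pair: \code{pair_id},
#'       \code{feeding_type}, \code{feeding_frequency_per_day},
#'       \code{solid_food}, and \code{shared_<taxon>_<timepoint>} logicals.}
#'     \item{truth}{list with the realized per-pair transmission events and
#'       additive effect components (percentage points) for every taxon.}
#'   }
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  taxa <- config$taxa
  n <- config$n_pairs
  with_seed(config$seed, {
    pair_ids <- sprintf("P%03d", seq_len(n))
    feeding <- sample(names(config$feeding_probs), n, replace = TRUE,
                      prob = config$feeding_probs)
    freq <- stats::rpois(n, config$feeding_frequency_mean)
    solid <- stats::runif(n) < 0.9

    draw_sample <- function(tp, mother_ab, shared, feeding_type) {
      base <- config$baselines[[tp]][taxa]
      carried <- stats::runif(length(taxa)) < config$carriage_prob[[tp]][taxa]
      noise <- if (config$noise_sd > 0)
        stats::rnorm(length(taxa), 0, config$noise_sd) else numeric(length(taxa))
      if (is.null(mother_ab)) {            # maternal sample
        ab <- ifelse(carried & base > 0, exp(log(pmax(base, 1e-12)) + noise), 0)
        ab[base == 0] <- 0
        eff_feed <- eff_share <- setNames(numeric(length(taxa)), taxa)
      } else {                             # infant sample
        carried <- carried | shared        # a transmitted strain is present
        eff_feed <- config$feeding_effects[[feeding_type]][taxa]
        eff_share <- config$sharing_bonus * as.numeric(shared)
        ab <- ifelse(carried & base > 0,
                     exp(log(pmax(base, 1e-12)) +
                           config$maternal_effect * mother_ab + noise) +
                       eff_feed + eff_share,
                     0)
        ab[base == 0] <- 0
      }
      ab <- pmax(ab, 0)
      total <- sum(ab)
      if (total > 100) ab <- ab * 100 / total
      list(ab = setNames(ab, taxa), carried = carried,
           eff_feed = setNames(as.numeric(eff_feed), taxa),
           eff_share = setNames(as.numeric(eff_share), taxa))
    }

    rows <- vector("list", 3L * n)
    meta <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      mother <- draw_sample("mother", NULL, NULL, NULL)
      shared1 <- mother$carried &
        stats::runif(length(taxa)) < config$transmission_prob[taxa]
      shared6 <- shared1 & stats::runif(length(taxa)) < config$persistence_prob
      inf1 <- draw_sample("1m", mother$ab, shared1, feeding[i])
      inf6 <- draw_sample("6m", mother$ab, shared6, feeding[i])

      mk <- function(role, tp, s) {
        cbind(data.frame(sample_id = paste0(pair_ids[i], "_", role, "_", tp),
                         pair_id = pair_ids[i], role = role, timepoint = tp,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(s$ab), check.names = FALSE),
              data.frame(other_bacteria = max(0, 100 - sum(s$ab))))
      }
      rows[[3 * i - 2]] <- mk("mother", "prenatal", mother)
      rows[[3 * i - 1]] <- mk("infant", "1m", inf1)
      rows[[3 * i]] <- mk("infant", "6m", inf6)

      m <- data.frame(pair_id = pair_ids[i], feeding_type = feeding[i],
                      feeding_frequency_per_day = freq[i],
                      solid_food = solid[i], stringsAsFactors = FALSE)
      for (t in taxa) {
        m[[paste0("shared_", t, "_1m")]] <- shared1[[t]]
        m[[paste0("shared_", t, "_6m")]] <- shared6[[t]]
      }
      meta[[i]] <- m
      truth[[i]] <- list(pair_id = pair_ids[i], feeding_type = feeding[i],
                         shared_1m = shared1, shared_6m = shared6,
                         effects_1m = list(feeding = inf1$eff_feed,
                                           sharing = inf1$eff_share),
                         effects_6m = list(feeding = inf6$eff_feed,
                                           sharing = inf6$eff_share))
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    list(cohort = cohort, metadata = metadata,
         truth = list(pairs = truth, config = config))
  })
}

#' Simulate MAG gene repertoires from the HMG archetypes
#'
#' Draws per-MAG copy-number vectors around one of the configured archetype
#' means (normal noise with SD \code{config$noise_sd}, rounded to the nearest
#' integer, negative draws clipped to zero) and returns the planted archetype
#' labels as ground truth.
#'
#' @param config a [simulation_config()] object (uses \code{archetype_defs},
#'   \code{archetype_probs}, \code{noise_sd}, \code{seed}).
#' @param n_mags number of MAGs to draw (>= 3).
#' @return list with \code{counts} (integer matrix, MAGs x gene families) and
#'   \code{labels} (named character vector of archetype assignments).
#' @export
simulate_mag_repertoires <- function(config, n_mags = 63) {
  validate_simulation_config(config)
  if (n_mags < 3) stop("n_mags must be >= 3", call. = FALSE)
  arch <- config$archetype_defs
  if (length(arch) < 2) stop("need at least two archetypes", call. = FALSE)
  genes <- names(arch[[1]])
  with_seed(config$seed, {
    probs <- config$archetype_probs[names(arch)]
    labels <- sample(names(arch), n_mags, replace = TRUE,
                     prob = probs / sum(probs))
    counts <- t(vapply(labels, function(a) {
      mu <- arch[[a]][genes]
      as.integer(round(pmax(mu + stats::rnorm(length(mu), 0, config$noise_sd),
                            0)))
    }, integer(length(genes))))
    dimnames(counts) <- list(sprintf("MAG%03d", seq_len(n_mags)), genes)
    names(labels) <- rownames(counts)
    list(counts = counts, labels = labels)
  })
}

#' Simulate tabular protein alignment hits and a pairwise identity matrix
#'
#' Fixture generator for the alignment-based filters: emits one BLAST
#' outfmt-6-style record (plus query coverage) per intended status, and a
#' block-structured symmetric percent-identity matrix for variant clustering.
#'
#' @param config a [simulation_config()] object (supplies the seed).
#' @param truth list describing the intended outputs:
#'   \describe{
#'     \item{statuses}{character vector, one hit per element, each one of
#'       \code{"pass"}, \code{"fail_bitscore"}, \code{"fail_evalue"},
#'       \code{"fail_identity"}; failing hits violate exactly that filter and
#'       satisfy the others.}
#'     \item{blocks}{list with \code{sizes} (integer vector),
#'       \code{within} (per-block pairwise identity \%) and \code{between}
#'       (identity across blocks); optional.}
#'   }
#' @return list with \code{hits} (data.frame in outfmt-6 column order plus
#'   \code{qcovs}, rows aligned with \code{truth$statuses}) and
#'   \code{identity} (symmetric matrix, unit diagonal at 100), plus
#'   \code{seq_mags} (round-robin sequence-to-MAG assignment for the identity
#'   matrix sequences).
#' @export
simulate_alignment_hits <- function(config, truth) {
  validate_simulation_config(config)
  statuses <- truth$statuses %||% character(0)
  ok <- c("pass", "fail_bitscore", "fail_evalue", "fail_identity")
  if (!all(statuses %in% ok))
    stop("statuses must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  with_seed(config$seed, {
    n <- length(statuses)
    hits <- NULL
    if (n > 0) {
      pident <- stats::runif(n, 60, 100)
      evalue <- 10^stats::runif(n, -50, -4)
      bitscore <- stats::runif(n, 50, 500)
      pident[statuses == "fail_identity"] <- stats::runif(
        sum(statuses == "fail_identity"), 20, 59.9)
      evalue[statuses == "fail_evalue"] <- 10^stats::runif(
        sum(statuses == "fail_evalue"), -2.9, 1)
      bitscore[statuses == "fail_bitscore"] <- stats::runif(
        sum(statuses == "fail_bitscore"), 5, 49.9)
      len <- as.integer(round(stats::runif(n, 100, 900)))
      hits <- data.frame(
        qseqid = sprintf("MAG%03d_g%04d", sample.int(20, n, replace = TRUE),
                         seq_len(n)),
        sseqid = sprintf("ref_%03d", sample.int(50, n, replace = TRUE)),
        pident = round(pident, 1), length = len,
        mismatch = as.integer(round(len * (100 - pident) / 100)),
        gapopen = as.integer(stats::rpois(n, 1)),
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = signif(evalue, 3), bitscore = round(bitscore, 1),
        qcovs = round(stats::runif(n, 60, 100), 1),
        stringsAsFactors = FALSE)
    }
    identity <- NULL
    seq_mags <- NULL
    if (!is.null(truth$blocks)) {
      b <- truth$blocks
      stopifnot(length(b$sizes) == length(b$within))
      total <- sum(b$sizes)
      identity <- matrix(b$between, total, total)
      at <- 0
      for (j in seq_along(b$sizes)) {
        idx <- at + seq_len(b$sizes[j])
        identity[idx, idx] <- b$within[j]
        at <- at + b$sizes[j]
      }
      diag(identity) <- 100
      ids <- sprintf("seq%03d", seq_len(total))
      dimnames(identity) <- list(ids, ids)
      n_mags <- truth$n_mags %||% max(10L, ceiling(total / 2))
      seq_mags <- setNames(
        sprintf("MAG%03d", rep_len(seq_len(n_mags), total)), ids)
    }
    list(hits = hits, identity = identity, seq_mags = seq_mags)
  })
}

#' Simulate subspecies marker-gene hits
#'
#' Emits a marker-hit table (MAG gene vs. subspecies-specific marker, percent
#' identity and coverage) for a set of MAGs with known subspecies, such that
#' own-subspecies markers yield high-identity/high-coverage hits and a sprinkle
#' of cross-subspecies hits falls below the filter. Marker rosters default to
#' 119 BLinfantis and 128 BLlongum marker genes.
#'
#' @param labels named character vector MAG -> subspecies
#'   (\code{"BLinfantis"} or \code{"BLlongum"}; archetype labels such as
#'   \code{"BLlongum-HMGsimple"} are mapped by prefix).
#' @param seed integer RNG seed.
#' @param n_markers named integer vector: marker roster sizes.
#' @param marker_frac fraction of own-subspecies markers hit per MAG.
#' @return list with \code{hits} (data.frame: \code{gene_id}, \code{mag_id},
#'   \code{marker_id}, \code{pident}, \code{qcovs}) and \code{markers}
#'   (data.frame: \code{marker_id}, \code{subspecies}).
#' @export
simulate_marker_hits <- function(labels, seed = 1L,
                                 n_markers = c(BLinfantis = 119,
                                               BLlongum = 128),
                                 marker_frac = 0.9) {
  subsp <- ifelse(startsWith(labels, "BLinfantis"), "BLinfantis", "BLlongum")
  markers <- data.frame(
    marker_id = c(sprintf("BLinf_m%03d", seq_len(n_markers[["BLinfantis"]])),
                  sprintf("BLlon_m%03d", seq_len(n_markers[["BLlongum"]]))),
    subspecies = rep(c("BLinfantis", "BLlongum"), n_markers),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    out <- list()
    for (i in seq_along(labels)) {
      mag <- names(labels)[i]
      own <- markers$marker_id[markers$subspecies == subsp[i]]
      other <- markers$marker_id[markers$subspecies != subsp[i]]
      own_hit <- own[stats::runif(length(own)) < marker_frac]
      cross_hit <- other[stats::runif(length(other)) < 0.1]
      k <- length(own_hit); m <- length(cross_hit)
      out[[i]] <- data.frame(
        gene_id = sprintf("%s_g%04d", mag, seq_len(k + m)),
        mag_id = mag,
        marker_id = c(own_hit, cross_hit),
        pident = round(c(stats::runif(k, 92, 100), stats::runif(m, 70, 88)), 1),
        qcovs = round(c(stats::runif(k, 60, 100), stats::runif(m, 55, 100)), 1),
        stringsAsFactors = FALSE)
    }
    list(hits = do.call(rbind, out), markers = markers)
  })
}
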