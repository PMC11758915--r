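# All tables are TSV with a header row; percentages on the 0-100 scale.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore")

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rownames_as),
                as.data.frame(df, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort relative-abundance table
#'
#' Samples x taxa TSV with bookkeeping columns \code{sample_id},
#' \code{pair_id}, \code{role}, \code{timepoint} and one numeric column per
#' taxon (percent of total community). On load every abundance is checked to
#' be a nonnegative number and each sample's total to be <= 100 (within
#' rounding tolerance); violations are reported with row and column.
#'
#' @param path file path.
#' @param cohort cohort data.frame (for the writer).
#' @return the validated data.frame (reader); the path, invisibly (writer).
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c("sample_id", "pair_id", "role", "timepoint"),
                   basename(path))
  if (anyDuplicated(df[c("pair_id", "role", "timepoint")]))
    stop("duplicate (pair_id, role, timepoint) keys in ", basename(path),
         call. = FALSE)
  taxa <- cohort_taxa(df)
  for (t in c(taxa, intersect("other_bacteria", names(df)))) {
    v <- suppressWarnings(as.numeric(df[[t]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad))
      stop(sprintf("invalid abundance at row %d, column '%s' in %s",
                   bad[1], t, basename(path)), call. = FALSE)
    df[[t]] <- v
  }
  tot <- rowSums(df[, taxa, drop = FALSE])
  if (any(tot > 100 + 1e-6))
    stop("per-sample abundance total exceeds 100% at row ",
         which(tot > 100 + 1e-6)[1], call. = FALSE)
  df
}

#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(cohort, path) write_tsv(cohort, path)

#' Read / write a pair metadata table
#'
#' One row per mother-infant pair: \code{pair_id}, \code{feeding_type},
#' \code{feeding_frequency_per_day}, \code{solid_food} and logical
#' \code{shared_<taxon>_<timepoint>} columns.
#'
#' @param path file path.
#' @param metadata metadata data.frame (for the writer).
#' @export
read_pair_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c("pair_id", "feeding_type",
                         "feeding_frequency_per_day"), basename(path))
  if (anyDuplicated(df$pair_id))
    stop("duplicate pair_id in ", basename(path), call. = FALSE)
  for (cn in grep("^shared_|^solid_food$", names(df), value = TRUE))
    df[[cn]] <- as.logical(df[[cn]])
  df
}

#' @rdname read_pair_metadata
#' @export
write_pair_metadata <- function(metadata, path) write_tsv(metadata, path)

#' Read / write an alignment-hit table (BLAST outfmt 6 + query coverage)
#'
#' Header-rowed TSV in the standard 12-column tabular layout (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) plus an appended \code{qcovs} column. A file missing any of the
#' 13 columns is rejected with the missing names listed.
#'
#' @param path file path.
#' @param hits hit data.frame (for the writer).
#' @export
read_alignment_hits <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not_cols(df, c(OUTFMT6_COLS, "qcovs"), basename(path))
  for (cn in c("pident", "evalue", "bitscore", "qcovs")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && nrow(df) > 0)
      stop("non-numeric value in column '", cn, "' of ", basename(path),
           call. = FALSE)
    df[[cn]] <- v
  }
  df
}

#' @rdname read_alignment_hits
#' @export
write_alignment_hits <- function(hits, path) write_tsv(hits, path)

#' Read / write a square pairwise identity matrix
#'
#' TSV with sequence ids as both the header row and the first column;
#' validated to be symmetric with a diagonal of 100 and values in [0, 100].
#'
#' @param path file path.
#' @param identity identity matrix (for the writer).
#' @export
read_identity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m)))
    stop("identity matrix rows and columns disagree in ", basename(path),
         call. = FALSE)
  storage.mode(m) <- "double"
  validate_identity_matrix(m)
  m
}

#' @rdname read_identity_matrix
#' @export
write_identity_matrix <- function(identity, path)
  write_tsv(identity, path, rownames_as = "seq_id")

#' Read / write a gene copy-number matrix (MAGs x genes)
#'
#' TSV with MAG ids in the first column (\code{mag_id}) and one nonnegative
#' integer column per gene family / variant / transporter.
#'
#' @param path file path.
#' @param counts count matrix (for the writer).
#' @export
read_gene_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not_cols(df, "mag_id", basename(path))
  m <- as.matrix(df[, setdiff(names(df), "mag_id"), drop = FALSE])
  rownames(m) <- df$mag_id
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m)))
    stop("gene counts must be nonnegative integers in ", basename(path),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene columns in ", basename(path), call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_gene_counts
#' @export
write_gene_counts <- function(counts, path)
  write_tsv(counts, path, rownames_as = "mag_id")

#' Read a pipeline run configuration
#'
#' YAML file with the run seed, output directory, cohort/MAG sizes, stage
#' toggles and analysis thresholds. Missing fields fall back to package
#' defaults; thresholds are range-checked.
#'
#' @param path YAML file path.
#' @return a validated named list (class \code{"run_config"}).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config a plain named list of overrides.
#' @export
as_run_config <- function(config = list()) {
  defaults <- list(
    seed = 1L, out_dir = "bifidodyn_run", n_pairs = 24L, n_mags = 63L,
    stages = c("simulate", "profile", "type", "dynamics", "select"),
    taxon = "BLlongum",
    presence_threshold = 0.01, dominance_threshold = 0.1,
    identity_threshold = 60, min_prevalence = 0.05,
    min_bitscore = 50, max_evalue = 0.001, min_hit_identity = 60,
    marker_min_identity = 90, marker_min_coverage = 50,
    log2fc_threshold = 2, fdr_alpha = 0.05, collinearity_threshold = 0.70)
  config <- utils::modifyList(defaults, config)
  with(config, {
    stopifnot(presence_threshold >= 0, presence_threshold < 100,
              dominance_threshold >= 0, dominance_threshold < 100,
              identity_threshold > 0, identity_threshold <= 100,
              min_prevalence >= 0, min_prevalence <= 1,
              min_bitscore > 0, max_evalue > 0,
              marker_min_identity > 0, marker_min_identity <= 100,
              marker_min_coverage > 0, marker_min_coverage <= 100,
              fdr_alpha > 0, fdr_alpha < 1,
              collinearity_threshold > 0, collinearity_threshold <= 1)
  })
  unknown <- setdiff(config$stages,
                     c("simulate", "profile", "type", "dynamics", "select"))
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  class(config) <- "run_config"
  config
}

#' Read an abundance-model configuration
#'
#' YAML file naming the response taxon, infant timepoint, feature list and
#' cross-validation scheme for one LASSO abundance model. Three example
#' configurations ship under \code{inst/extdata} (one-month BLlongum,
#' six-month BLlongum, six-month BLinfantis).
#'
#' @param path YAML file path.
#' @return list with \code{response}, \code{timepoint}, \code{features} and
#'   \code{cv} (scheme, nfolds, repeats), usable with [encode_features()] and
#'   [fit_lasso_cv()].
#' @export
read_model_config <- function(path) {
  m <- yaml::read_yaml(path)
  for (f in c("response", "timepoint", "features"))
    if (is.null(m[[f]]))
      stop("model config is missing field '", f, "'", call. = FALSE)
  m$features <- as.character(unlist(m$features))
  m$cv <- m$cv %||% list(scheme = "repeated_kfold", nfolds = 10, repeats = 10)
  m
}
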