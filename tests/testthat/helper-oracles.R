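# Independent oracles and fixture builders shared across test files.

# All set partitions of 1..n (n <= 9), as lists of integer vectors.
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Brute-force variant-clustering oracle: all partitions whose multi-member
# blocks have mean pairwise identity >= threshold, restricted to those with
# the minimal number of blocks. Returns a list of canonical membership
# vectors (one per optimal partition).
oracle_variant_partition <- function(identity, threshold = 60) {
  n <- nrow(identity)
  parts <- set_partitions(n)
  feasible <- Filter(function(p) {
    all(vapply(p, function(idx) {
      if (length(idx) < 2L) return(TRUE)
      sub <- identity[idx, idx]
      mean(sub[upper.tri(sub)]) >= threshold
    }, logical(1)))
  }, parts)
  sizes <- vapply(feasible, length, integer(1))
  best <- feasible[sizes == min(sizes)]
  lapply(best, function(p) {
    mem <- integer(n)
    for (b in seq_along(p)) mem[p[[b]]] <- b
    # canonical labels: renumber blocks by first appearance
    match(mem, unique(mem))
  })
}

canonical_membership <- function(assignment) {
  match(assignment, unique(assignment))
}

# Block-structured identity matrix: sizes/within per block, constant between.
block_identity <- function(sizes, within, between) {
  total <- sum(sizes)
  m <- matrix(between, total, total)
  at <- 0
  for (j in seq_along(sizes)) {
    idx <- at + seq_len(sizes[j])
    m[idx, idx] <- within[j]
    at <- at + sizes[j]
  }
  diag(m) <- 100
  ids <- sprintf("s%02d", seq_len(total))
  dimnames(m) <- list(ids, ids)
  m
}

# seq -> MAG map spreading sequences over distinct MAGs
spread_mags <- function(ids, n_mags = length(ids)) {
  setNames(sprintf("MAG%03d", rep_len(seq_len(n_mags), length(ids))), ids)
}

# simulation_config with all stochastic layers silenced except what's asked
quiet_config <- function(..., n_pairs = 10, seed = 1) {
  taxa <- c("BLlongum", "BLinfantis", "B.breve", "B.bifidum",
            "B.adolescentis", "B.pseudocatenulatum", "other")
  one <- function(x) setNames(rep(x, length(taxa)), taxa)
  defaults <- list(
    n_pairs = n_pairs, seed = seed, noise_sd = 0,
    carriage_prob = list(mother = one(1), `1m` = one(1), `6m` = one(1)),
    transmission_prob = one(0), maternal_effect = 0, sharing_bonus = 0,
    feeding_effects = list(breast = one(0), formula = one(0), mixed = one(0)))
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

make_hits <- function(pident, evalue, bitscore, qseqid = NULL) {
  n <- length(pident)
  data.frame(
    qseqid = qseqid %||% sprintf("MAG001_g%03d", seq_len(n)),
    sseqid = sprintf("ref_%03d", seq_len(n)),
    pident = pident, length = 300L, mismatch = 10L, gapopen = 0L,
    qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
    evalue = evalue, bitscore = bitscore, qcovs = 90,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
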