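test_that("well-separated identity blocks yield one variant per block", {
  m <- block_identity(c(4, 2), c(85, 75), 30)
  res <- cluster_gh_variants(m, spread_mags(rownames(m)), family = "GH2")
  expect_equal(nrow(res$variants), 2L)
  expect_setequal(res$members[[1]], rownames(m)[1:4])
  expect_setequal(res$members[[2]], rownames(m)[5:6])
  expect_equal(res$variants$mean_identity, c(85, 75))
})

test_that("all-identical sequences form a single variant", {
  m <- block_identity(5, 100, 100)
  res <- cluster_gh_variants(m, spread_mags(rownames(m)))
  expect_equal(nrow(res$variants), 1L)
  expect_length(res$members[[1]], 5L)
})

test_that("singletons and low-prevalence variants are excluded", {
  # variant carried by 2 of 63 MAGs: prevalence 3.2% < 5%
  m <- block_identity(c(4, 2, 1), c(90, 95, 100), 20)
  ids <- rownames(m)
  seq_mags <- setNames(c("MAG001", "MAG002", "MAG003", "MAG004",
                         "MAG005", "MAG006", "MAG007"), ids)
  res <- cluster_gh_variants(m, seq_mags, n_mags = 63)
  expect_equal(nrow(res$variants), 1L)        # only the 4-member variant
  expect_setequal(res$dropped$reason, c("singleton", "low_prevalence"))
  low <- res$dropped[res$dropped$reason == "low_prevalence", ]
  expect_equal(low$n_members, 2L)
  expect_equal(low$prevalence, 2 / 63, tolerance = 1e-12)
  # same blocks against a small roster: nothing dropped for prevalence
  res2 <- cluster_gh_variants(m, seq_mags, n_mags = 7)
  expect_equal(nrow(res2$variants), 2L)
})

test_that("variant clustering equals the brute-force partition oracle", {
  fixtures <- list(
    block_identity(c(4, 2), c(85, 75), 10),
    block_identity(c(3, 3), c(95, 70), 5),
    block_identity(c(2, 2, 2), c(80, 90, 99), 15),
    block_identity(c(5, 3), c(65, 88), 12),
    block_identity(8, 75, NA_real_))
  fixtures[[5]][is.na(fixtures[[5]])] <- 75   # single uniform block
  for (m in fixtures) {
    oracle <- oracle_variant_partition(m, 60)
    expect_length(oracle, 1L)   # fixture admits a unique optimal partition
    res <- cluster_gh_variants(m, spread_mags(rownames(m)))
    expect_identical(canonical_membership(unname(res$assignment)),
                     oracle[[1]])
  }
})

test_that("raising the identity threshold never merges variants", {
  m <- block_identity(c(3, 3, 2), c(90, 72, 85), 25)
  ks <- vapply(c(50, 60, 75, 85, 95), function(thr) {
    res <- cluster_gh_variants(m, spread_mags(rownames(m)),
                               identity_threshold = thr, min_prevalence = 0)
    length(unique(res$assignment))
  }, numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("malformed identity matrices are rejected", {
  m <- block_identity(c(2, 2), c(90, 90), 30)
  bad <- m; bad[1, 2] <- 50
  expect_error(cluster_gh_variants(bad, spread_mags(rownames(m))),
               "symmetric")
  bad2 <- m; bad2[1, 2] <- bad2[2, 1] <- 150
  expect_error(cluster_gh_variants(bad2, spread_mags(rownames(m))),
               "\\[0, 100\\]")
})

test_that("transporter hit filter enforces every threshold inclusively", {
  h <- make_hits(pident = c(80, 60, 59.9, 70, 70),
                 evalue = c(1e-10, 0.001, 1e-8, 0.0011, 1e-8),
                 bitscore = c(49, 50, 300, 300, 300))
  kept <- filter_transporter_hits(h)
  # row 1 fails bitscore (49 < 50); row 2 sits exactly on every boundary;
  # row 3 fails identity; row 4 fails e-value; row 5 passes
  expect_setequal(kept$sseqid, h$sseqid[c(2, 5)])
  expect_equal(nrow(filter_transporter_hits(h[0, ])), 0L)
})

test_that("only the highest-identity surviving hit per query is retained", {
  h <- make_hits(pident = c(72, 88, 95), evalue = 1e-10, bitscore = 200,
                 qseqid = c("q1", "q1", "q2"))
  kept <- filter_transporter_hits(h)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$pident[kept$qseqid == "q1"], 88)
})

test_that("profile matrix counts members and hits per MAG with zero rows", {
  m <- block_identity(c(3, 2), c(90, 95), 10)
  seq_mags <- setNames(c("MAGA", "MAGA", "MAGB", "MAGB", "MAGC"),
                       rownames(m))
  variants <- cluster_gh_variants(m, seq_mags, n_mags = 4,
                                  min_prevalence = 0, family = "GH2")
  hits <- make_hits(pident = c(80, 85, 90), evalue = 1e-9, bitscore = 100,
                    qseqid = c("MAGA_g001", "MAGA_g002", "MAGD_g001"))
  hits$sseqid <- c("gltA", "gltA", "gltB")
  pm <- build_profile_matrix(variants, hits,
                             mag_roster = c("MAGA", "MAGB", "MAGC", "MAGD"),
                             seq_mags = seq_mags)
  expect_equal(pm["MAGA", "GH2_v1"], 2L)
  expect_equal(pm["MAGA", "gltA"], 2L)
  expect_equal(pm["MAGD", "gltB"], 1L)
  expect_equal(unname(pm["MAGD", c("GH2_v1", "GH2_v2")]), c(0L, 0L))
  # totals: matrix sum = retained sequences + retained hits
  expect_equal(sum(pm), 5L + 3L)
  expect_error(build_profile_matrix(variants, hits, mag_roster = c("MAGA"),
                                    seq_mags = seq_mags), "unknown MAG")
})

test_that("profile clustering recovers the three planted archetypes", {
  cfg <- simulation_config(seed = 2, noise_sd = 0.3)
  m <- simulate_mag_repertoires(cfg, n_mags = 60)
  pr <- cluster_profiles(m$counts)
  expect_equal(pr$k, 3L)
  expect_gte(adjusted_rand(pr$assignment, m$labels), 0.9)
})

test_that("forced k and degenerate inputs behave as documented", {
  cfg <- simulation_config(seed = 2, noise_sd = 0.3)
  m <- simulate_mag_repertoires(cfg, n_mags = 20)
  pr2 <- cluster_profiles(m$counts, k = 2)
  expect_equal(length(unique(pr2$assignment)), 2L)
  expect_error(cluster_profiles(m$counts, k = 50), "exceeds")
  const <- matrix(3, 4, 2, dimnames = list(paste0("M", 1:4), c("a", "b")))
  expect_error(suppressWarnings(cluster_profiles(const)), "constant")
})

test_that("duplicated row blocks select k = 2 and reproduce the blocks", {
  block1 <- matrix(rep(c(5, 0, 2, 0), each = 4), 4, 4,
                   dimnames = list(paste0("A", 1:4), paste0("g", 1:4)))
  block2 <- matrix(rep(c(0, 3, 0, 4), each = 4), 4, 4,
                   dimnames = list(paste0("B", 1:4), paste0("g", 1:4)))
  pr <- cluster_profiles(rbind(block1, block2))
  expect_equal(pr$k, 2L)
  truth <- rep(1:2, each = 4)
  expect_equal(adjusted_rand(pr$assignment, truth), 1)
})

test_that("profile clustering is invariant to row order and column rescaling", {
  cfg <- simulation_config(seed = 9, noise_sd = 0.3)
  m <- simulate_mag_repertoires(cfg, n_mags = 30)
  base <- cluster_profiles(m$counts, k = 3)$assignment
  perm <- sample(nrow(m$counts))
  shuffled <- cluster_profiles(m$counts[perm, ], k = 3)$assignment
  expect_equal(adjusted_rand(base[rownames(m$counts)[perm]], shuffled), 1)
  scaled <- sweep(m$counts, 2, seq_len(ncol(m$counts)), `*`)
  rescaled <- cluster_profiles(scaled, k = 3)$assignment
  expect_equal(adjusted_rand(base, rescaled), 1)
})

test_that("log2 fold changes and verdicts follow the 4-fold rule", {
  set.seed(1)
  n_per <- 10
  cl <- rep(1:2, each = n_per)
  flat <- rep(7, 2 * n_per)
  # planted: cluster means 7.5 vs 1.5 -> log2(8/2) = 2, exactly at threshold
  planted <- c(rep(c(7, 8), n_per / 1)[1:n_per], rep(c(1, 2), n_per)[1:n_per])
  counts <- cbind(flat = flat, planted = planted)
  rownames(counts) <- paste0("M", seq_len(2 * n_per))
  res <- test_gene_enrichment(counts, cl)
  rec <- res$records
  flat1 <- rec[rec$gene == "flat" & rec$cluster == "1", ]
  expect_equal(flat1$log2fc, 0)
  expect_equal(flat1$verdict, "none")
  p1 <- rec[rec$gene == "planted" & rec$cluster == "1", ]
  expect_equal(p1$mean_in, 7.5)
  expect_equal(p1$mean_rest, 1.5)
  expect_equal(p1$log2fc, 2)
  expect_equal(p1$verdict, "enriched")   # qualifies exactly at the threshold
  p2 <- rec[rec$gene == "planted" & rec$cluster == "2", ]
  expect_equal(p2$verdict, "depleted")
})

test_that("planted 8-fold genes are flagged and null flags are controlled", {
  flagged_true <- 0; flagged_false <- 0
  for (s in 1:20) {
    set.seed(s)
    cl <- rep(1:3, each = 20)
    planted <- sapply(1:5, function(i) {
      c(rpois(20, 12), rpois(40, 1.5))
    })
    nulls <- sapply(1:45, function(i) rpois(60, 3))
    counts <- cbind(planted, nulls)
    colnames(counts) <- c(paste0("hit", 1:5), paste0("null", 1:45))
    rownames(counts) <- paste0("M", 1:60)
    res <- test_gene_enrichment(counts, cl)
    rec <- res$records
    enr <- rec[rec$verdict == "enriched", ]
    flagged_true <- flagged_true +
      sum(enr$cluster == "1" & grepl("^hit", enr$gene))
    flagged_false <- flagged_false +
      sum(!(enr$cluster == "1" & grepl("^hit", enr$gene)))
    # every planted gene flagged in the planted cluster this seed
    expect_equal(sum(enr$cluster == "1" & grepl("^hit", enr$gene)), 5L)
  }
  fdr <- flagged_false / max(1, flagged_true + flagged_false)
  expect_lte(fdr, 0.05)
})

test_that("under the null the q < 0.05 fraction stays at the nominal level", {
  frac <- vapply(1:10, function(s) {
    set.seed(100 + s)
    cl <- rep(1:3, each = 15)
    counts <- sapply(1:40, function(i) rpois(45, 3))
    colnames(counts) <- paste0("g", 1:40)
    rownames(counts) <- paste0("M", 1:45)
    rec <- test_gene_enrichment(counts, cl)$records
    mean(rec$q < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("tiny clusters are skipped in post-hoc verdicts with a warning", {
  counts <- matrix(rpois(22 * 3, 3), 22, 3,
                   dimnames = list(paste0("M", 1:22), paste0("g", 1:3)))
  cl <- c(rep(1, 10), rep(2, 10), rep(3, 2))
  expect_warning(res <- test_gene_enrichment(counts, cl), "< 3 MAGs")
  rec <- res$records
  expect_true(all(is.na(rec$p[rec$cluster == "3"])))
})
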