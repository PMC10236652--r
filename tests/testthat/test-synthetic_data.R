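test_that("genome simulation is deterministic and internally consistent", {
  g <- fixture_genome()
  g2 <- simulate_genome(genome_params(
    n_contigs = 2L, genes_per_contig = 40L, n_clusters = 6L, seed = 3L))
  expect_identical(g, g2)
  # every truth id resolves; each gene belongs to at most one cluster
  expect_true(all(g$truth$clusters$gene_id %in% g$models$gene_id))
  expect_false(anyDuplicated(g$truth$clusters$gene_id) > 0)
  expect_true(all(c(g$truth$pair_ds$gene_a, g$truth$pair_ds$gene_b) %in%
                    g$truth$clusters$gene_id))
  # proteins are clean translations of the CDS
  expect_false(any(grepl("[*X]", g$proteins)))
  expect_equal(unname(nchar(g$cds)), g$models$cds_length[
    match(names(g$cds), g$models$gene_id)])
  # exons sit inside genes; gene sequences embed in the contig
  for (i in seq_len(nrow(g$models))) {
    m <- g$models[i, ]
    ex <- m$exons[[1]]
    expect_true(all(ex[, "start"] >= m$start & ex[, "end"] <= m$end))
  }
})

test_that("zero planted duplications yield a singleton-only genome", {
  g <- simulate_genome(genome_params(n_contigs = 1L, genes_per_contig = 10L,
                                     n_clusters = 0L, seed = 2L))
  expect_equal(nrow(g$truth$clusters), 0L)
  expect_equal(nrow(g$truth$pair_ds), 0L)
  expect_equal(nrow(g$models), 10L)
})

test_that("requesting more cluster genes than fit on a contig errors", {
  expect_error(simulate_genome(genome_params(
    n_contigs = 1L, genes_per_contig = 3L, n_clusters = 2L,
    cluster_size_range = c(4L, 4L), seed = 1L)), "too short")
})

test_that("planted dS targets are recovered from the emitted CDS", {
  set.seed(21)
  for (tgt in c(0.05, 0.30)) {
    pr <- random_cds_pair(200, tgt)
    est <- ng86_ds(pr$a, pr$b)$dS
    expect_lt(abs(est - tgt) / tgt, 0.20)
  }
  g <- fixture_genome()
  pd <- g$truth$pair_ds
  est <- vapply(seq_len(nrow(pd)), function(i)
    ng86_ds(g$cds[[pd$gene_a[i]]], g$cds[[pd$gene_b[i]]])$dS, 0)
  expect_gt(cor(pd$true_ds, est), 0.95)
})

test_that("long-read simulation respects coverage, length and error knobs", {
  g <- fixture_genome()
  # error-free full-length reads equal contig substrings
  r <- simulate_long_reads(g$genome, coverage = 1,
                           length_mean = max(nchar(g$genome)), seed = 1)
  one <- r$spans[1, ]
  expect_equal(r$reads[[one$read_id]],
               substr(g$genome[[one$contig]], one$start, one$end))
  # coverage 0: empty outputs
  r0 <- simulate_long_reads(g$genome, coverage = 0)
  expect_equal(length(r0$reads), 0L)
  # total emitted bases ~ coverage * genome size
  r30 <- simulate_long_reads(g$genome, coverage = 30, length_mean = 10000,
                             seed = 2)
  expect_lt(abs(sum(nchar(r30$reads)) - 30 * sum(nchar(g$genome))) /
              (30 * sum(nchar(g$genome))), 0.10)
  # errors change the sequence at roughly the requested rate
  re <- simulate_long_reads(g$genome, coverage = 1, length_mean = 20000,
                            error_rate = 0.1, seed = 3)
  expect_gt(mean(abs(nchar(re$reads) - re$spans$end + re$spans$start - 1) >
                   0), 0)
  expect_warning(simulate_long_reads(g$genome, coverage = 0.5,
                                     length_mean = 1e7, seed = 1),
                 "truncated")
})

test_that("family-count simulation plants amplification and single copies", {
  fam <- simulate_family_counts(n_og = 200L, n_amplified = 10L, fold = 4,
                                n_single_copy = 20L, seed = 5)
  expect_equal(dim(fam$counts), c(200L, 14L))
  expect_true(all(fam$counts[fam$single_copy_ogs, ] == 1L))
  amp_mean <- mean(fam$counts[fam$amplified_ogs, fam$groupA])
  base_mean <- mean(fam$counts[setdiff(rownames(fam$counts),
                                       c(fam$amplified_ogs,
                                         fam$single_copy_ogs)), fam$groupA])
  expect_gt(amp_mean / base_mean, 2.5)
  # fold = 1 / none amplified: truth lists no amplified OG
  fam0 <- simulate_family_counts(n_og = 50L, n_amplified = 0L, seed = 5)
  expect_equal(length(fam0$amplified_ogs), 0L)
})

test_that("copy-number read placement is proportional to planted copies", {
  cn_truth <- c(CN1 = 1, CN2 = 5)
  cn <- simulate_copy_number_data(cn_truth, single_copy_ogs = "CN1",
                                  og_length = 600L, coverage_per_copy = 10,
                                  seed = 4)
  bases <- tapply((cn$hits$end - cn$hits$start + 1), cn$hits$og_id, sum)
  expect_equal(unname(bases["CN2"] / bases["CN1"]), 5, tolerance = 0.01)
})

test_that("planted telomeric arrays have exact truth intervals", {
  set.seed(31)
  genome <- c(c1 = tandemdup:::random_dna(30000))
  pl <- data.frame(contig = "c1", start = c(10000L, 20000L),
                   n_units = c(24L, 10L), n_mismatches = c(0L, 1L),
                   stringsAsFactors = FALSE)
  out <- plant_telomeric_arrays(genome, placements = pl, seed = 2)
  expect_equal(out$truth$end - out$truth$start + 1L, c(144L, 60L))
  expect_equal(substr(out$genome[["c1"]], 10000, 10023),
               strrep("TTAGGG", 4))
  # terminal flag from the end window
  pl2 <- data.frame(contig = "c1", start = 1L, n_units = 8L,
                    n_mismatches = 0L)
  out2 <- plant_telomeric_arrays(genome, placements = pl2, seed = 2)
  expect_true(out2$truth$terminal)
  # overlapping placements are rejected
  pl3 <- data.frame(contig = "c1", start = c(100L, 130L),
                    n_units = c(10L, 10L), n_mismatches = 0L)
  expect_error(plant_telomeric_arrays(genome, placements = pl3), "overlap")
})

test_that("synteny pair simulation is deterministic with exact truth", {
  syn <- simulate_synteny_pair(seed = 6)
  syn2 <- simulate_synteny_pair(seed = 6)
  expect_identical(syn, syn2)
  expect_equal(sort(unique(syn$truth$gene_a)), sort(syn$orthologs$gene_a))
  sizes <- table(syn$truth$segment_id)
  expect_true(all(sizes >= 5L))
})
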