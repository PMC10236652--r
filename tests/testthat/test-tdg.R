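mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               identity_pct = 90, aln_length = as.numeric(r[[3]]),
               q_aln_span = as.numeric(r[[3]]), s_aln_span = as.numeric(r[[3]]),
               evalue = as.numeric(r[[4]]), bitscore = as.numeric(r[[5]]),
               self = r[[1]] == r[[2]], stringsAsFactors = FALSE)))
}

test_that("similarity filtering applies the e-value and coverage rules", {
  lens <- c(pA = 100L, pB = 200L, pC = 120L)
  h <- mk_hits(list("pA", "pB", 85, 1e-21, 150),  # kept: cov 0.85, 1e-21
               list("pA", "pC", 85, 1e-19, 140),  # dropped: e-value
               list("pB", "pC", 79, 1e-40, 130),  # dropped: cov 79/120
               list("pA", "pA", 100, 0, 500))     # self, ignored
  kept <- filter_similarity(h, lens)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$gene_a, "pA")
  expect_equal(kept$gene_b, "pB")
  # boundary: exactly 80% coverage and 1e-20 are kept
  h2 <- mk_hits(list("pA", "pC", 80, 1e-20, 140))
  expect_equal(nrow(filter_similarity(h2, lens)), 1L)
  # best supporting hit wins when both directions exist
  h3 <- mk_hits(list("pA", "pB", 85, 1e-21, 150),
                list("pB", "pA", 90, 1e-30, 220))
  expect_equal(filter_similarity(h3, lens)$bitscore, 220)
  expect_error(filter_similarity(h2, lens[1]), "pC")
})

test_that("tandem pairs respect the rank-distance boundary", {
  models <- assign_ranks(data.frame(
    gene_id = sprintf("g%02d", 1:20), contig = rep(c("c1", "c2"), each = 10),
    start = rep(seq(1, 10000, length.out = 10), 2),
    end = rep(seq(500, 10500, length.out = 10), 2), strand = "+",
    cds_length = 300L, utr_length = 0L, n_exons = 1L,
    stringsAsFactors = FALSE))
  pairs <- data.frame(gene_a = c("g01", "g01", "g01", "g05"),
                      gene_b = c("g11", "g10", "g02", "g15"),
                      evalue = 1e-30, bitscore = 100, coverage = 0.9,
                      stringsAsFactors = FALSE)
  # g01-g11: different contigs; g01-g10: rank distance 9 <= 10 kept;
  # g05-g15: different contigs
  tp <- find_tandem_pairs(pairs, models, max_gene_distance = 10L)
  expect_equal(nrow(tp), 2L)
  expect_true(all(tp$rank_distance <= 10L))
  # boundary: distance exactly 10 kept, 11 dropped
  models2 <- assign_ranks(data.frame(
    gene_id = sprintf("h%02d", 1:12), contig = "c1",
    start = seq(1, 12000, length.out = 12),
    end = seq(500, 12500, length.out = 12), strand = "+",
    cds_length = 300L, utr_length = 0L, n_exons = 1L,
    stringsAsFactors = FALSE))
  p10 <- data.frame(gene_a = "h01", gene_b = "h11", evalue = 1e-30,
                    bitscore = 1, coverage = 1)
  p11 <- data.frame(gene_a = "h01", gene_b = "h12", evalue = 1e-30,
                    bitscore = 1, coverage = 1)
  expect_equal(nrow(find_tandem_pairs(p10, models2)), 1L)
  expect_equal(nrow(find_tandem_pairs(p11, models2)), 0L)
  expect_error(find_tandem_pairs(
    data.frame(gene_a = "nope", gene_b = "h01", evalue = 0, bitscore = 1,
               coverage = 1), models2), "absent")
})

test_that("single-linkage clustering equals transitive closure", {
  p <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                  contig = "c1", stringsAsFactors = FALSE)
  cl <- cluster_single_linkage(p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$members, "A,B,C")
  expect_equal(nrow(cluster_single_linkage(p[0, ])), 0L)
  # random instances vs brute-force oracle
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(1:(2 * n), 1)
    e <- data.frame(gene_a = sample(nodes, m, TRUE),
                    gene_b = sample(nodes, m, TRUE),
                    stringsAsFactors = FALSE)
    e <- e[e$gene_a != e$gene_b, , drop = FALSE]
    if (!nrow(e)) next
    got <- cluster_single_linkage(e)
    want <- components_oracle(unique(c(e$gene_a, e$gene_b)),
                              as.matrix(e[, 1:2]))
    want <- want[lengths(want) >= 2 | TRUE]
    expect_equal(canonical_sets(strsplit(got$members, ",")),
                 canonical_sets(want))
  }
})

test_that("re-clustering cluster output changes nothing (idempotence)", {
  det <- fixture_detection()
  again <- cluster_single_linkage(det$pairs,
                                  fixture_genome()$models)
  expect_identical(det$clusters, again)
})

test_that("noise-free simulations are recovered exactly", {
  g <- fixture_genome()
  det <- fixture_detection()
  truth_sets <- split(g$truth$clusters$gene_id, g$truth$clusters$cluster_id)
  expect_equal(canonical_sets(strsplit(det$clusters$members, ",")),
               canonical_sets(truth_sets))
})

test_that("raising the rank window never shrinks total membership", {
  g <- fixture_genome()
  det <- fixture_detection()
  hits <- all_vs_all_similarity(g$proteins, g$models)
  lens <- setNames(nchar(g$proteins), names(g$proteins))
  kept <- filter_similarity(hits, lens,
                            use_bitscore = all(is.na(hits$evalue)))
  sizes <- vapply(c(2L, 5L, 10L, 20L), function(d) {
    cl <- cluster_single_linkage(
      find_tandem_pairs(kept, g$models, max_gene_distance = d), g$models)
    sum(cl$size)
  }, 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("read validation follows strict containment", {
  models <- assign_ranks(data.frame(
    gene_id = c("A", "B", "C"), contig = "c1",
    start = c(10000L, 16000L, 22000L), end = c(14000L, 20000L, 26000L),
    strand = "+", cds_length = 300L, utr_length = 0L, n_exons = 1L,
    stringsAsFactors = FALSE))
  cl <- data.frame(cluster_id = "tdg_A", contig = "c1", size = 3L,
                   members = "A,B,C", span_start = 10000L,
                   span_end = 26000L, stringsAsFactors = FALSE)
  # a read over the whole span validates all pairs and the cluster
  spans <- data.frame(read_id = "r1", contig = "c1", start = 1L,
                      end = 50000L, is_primary = TRUE,
                      stringsAsFactors = FALSE)
  v <- validate_with_reads(cl, spans, models)
  expect_equal(v$summary$frac_pairs_validated, 1)
  expect_equal(v$summary$frac_clusters_validated, 1)
  # read covering A and B fully but only half of C: pair A/B only
  spans2 <- data.frame(read_id = "r2", contig = "c1", start = 9000L,
                       end = 24000L, is_primary = TRUE,
                       stringsAsFactors = FALSE)
  v2 <- validate_with_reads(cl, spans2, models)
  expect_equal(v2$pairs$validated, c(TRUE, FALSE))
  expect_false(v2$clusters$cluster_validated)
  # reads on unknown contigs are skipped with a warning
  spans3 <- data.frame(read_id = "r3", contig = "cX", start = 1L,
                       end = 50000L, is_primary = TRUE,
                       stringsAsFactors = FALSE)
  expect_warning(v3 <- validate_with_reads(cl, spans3, models), "unknown")
  expect_equal(v3$summary$frac_pairs_validated, 0)
})

test_that("cluster statistics summarise sizes and dS-distance bins", {
  cl <- data.frame(cluster_id = c("x", "y", "z"), contig = "c1",
                   size = c(2L, 2L, 3L),
                   members = c("a,b", "c,d", "e,f,g"),
                   span_start = 1L, span_end = 10L, stringsAsFactors = FALSE)
  st <- cluster_statistics(cl)
  expect_equal(st$summary$mean_size, mean(c(2, 2, 3)), tolerance = 0.01)
  expect_equal(st$summary$max_size, 3L)
  empty <- cluster_statistics(cl[0, ])
  expect_equal(empty$summary$n_clusters, 0L)
  # ordered-growth arrays: dS increases with rank distance
  g <- simulate_genome(genome_params(
    n_contigs = 1L, genes_per_contig = 30L, n_clusters = 4L,
    cluster_size_range = c(5L, 7L), growth = "ordered", seed = 17L))
  pd <- g$truth$pair_ds
  est <- data.frame(gene_a = pd$gene_a, gene_b = pd$gene_b,
                    dS = vapply(seq_len(nrow(pd)), function(i)
                      ng86_ds(g$cds[[pd$gene_a[i]]],
                              g$cds[[pd$gene_b[i]]])$dS, 0))
  cl2 <- data.frame(cluster_id = "c", contig = "ctg01", size = 2L,
                    members = "x,y", span_start = 1L, span_end = 2L,
                    stringsAsFactors = FALSE)
  st2 <- cluster_statistics(cl2, est, g$models)
  expect_gt(st2$spearman_ds_distance, 0.5)
  expect_equal(st2$ds_by_distance$rank_distance, c("1", "2", "3", ">=4"))
})
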