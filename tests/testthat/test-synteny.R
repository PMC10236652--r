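mk_syn_models <- function(ids, contig, step = 3000L) {
  m <- data.frame(gene_id = ids, contig = contig,
                  start = (seq_along(ids) - 1L) * step + 1L,
                  end = (seq_along(ids) - 1L) * step + 2000L,
                  strand = "+", cds_length = 900L, utr_length = 0L,
                  n_exons = 1L, stringsAsFactors = FALSE)
  m$exons <- lapply(seq_len(nrow(m)), function(i)
    cbind(start = m$start[i], end = m$end[i]))
  assign_ranks(m)
}

test_that("contig eligibility needs five ortholog-bearing genes", {
  m5 <- mk_syn_models(paste0("a", 1:5), "c1")
  m4 <- mk_syn_models(paste0("b", 1:4), "c2")
  m <- rbind(m5, m4)
  expect_equal(select_contigs(m, c(m5$gene_id, m4$gene_id)), "c1")
  expect_equal(select_contigs(m, character()), character())
})

test_that("collinear, split and inverted blocks chain as expected", {
  ma <- mk_syn_models(sprintf("a%02d", 1:30), "cA")
  mb <- mk_syn_models(sprintf("b%02d", 1:30), "cB")
  ortho <- function(ia, ib)
    data.frame(gene_a = sprintf("a%02d", ia), gene_b = sprintf("b%02d", ib),
               score = 100, stringsAsFactors = FALSE)
  # six collinear pairs: one cluster of six
  cl <- chain_clusters(ortho(1:6, 1:6), ma, mb)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_pairs, 6L)
  # two blocks of 5 separated by 20 ortholog-bearing genes on genome A
  # (the separators pair to a different contig of genome B)
  mm <- mk_syn_models(sprintf("m%02d", 1:20), "cM")
  o2 <- rbind(ortho(c(1:5, 26:30), c(1:5, 6:10)),
              data.frame(gene_a = sprintf("a%02d", 6:25),
                         gene_b = sprintf("m%02d", 1:20),
                         score = 100, stringsAsFactors = FALSE))
  cl2 <- chain_clusters(o2, ma, rbind(mb, mm))
  expect_equal(sum(cl2$contig_b == "cB"), 2L)
  expect_equal(nrow(cl2), 3L)
  # same blocks but gap under 15: single cluster
  o3 <- ortho(c(1:5, 10:14), c(1:5, 6:10))
  cl3 <- chain_clusters(o3, ma, mb)
  expect_equal(nrow(cl3), 1L)
  # inverted block of 5 chains (orientation-agnostic)
  o4 <- ortho(1:5, 5:1)
  cl4 <- chain_clusters(o4, ma, mb)
  expect_equal(nrow(cl4), 1L)
  # clusters below min_size are discarded
  cl5 <- chain_clusters(ortho(1:4, 1:4), ma, mb,
                        min_ortholog_genes = 1L)
  expect_equal(nrow(cl5), 0L)
})

test_that("many-to-many orthologs reduce to best pairs before chaining", {
  o <- data.frame(gene_a = c("a1", "a1", "a2"),
                  gene_b = c("b1", "b2", "b1"),
                  score = c(300, 200, 250), stringsAsFactors = FALSE)
  red <- reduce_to_best_pairs(o)
  expect_equal(nrow(red), 1L)
  expect_equal(red$gene_b, "b1")
  o2 <- data.frame(gene_a = c("a1", "a1", "a2"),
                   gene_b = c("b1", "b2", "b2"),
                   score = c(300, 200, 250), stringsAsFactors = FALSE)
  red2 <- reduce_to_best_pairs(o2)
  expect_equal(red2$gene_a, c("a1", "a2"))
  expect_equal(red2$gene_b, c("b1", "b2"))
})

test_that("chaining matches the brute-force gap-graph oracle", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(10:60, 1)
    ids_a <- sprintf("a%03d", 1:n)
    ids_b <- sprintf("b%03d", 1:n)
    ma <- mk_syn_models(ids_a, "cA")
    perm <- sample.int(n)
    mb <- mk_syn_models(ids_b[perm], "cB")
    o <- data.frame(gene_a = ids_a, gene_b = ids_b, score = 1,
                    stringsAsFactors = FALSE)
    got <- chain_clusters(o, ma, mb, max_gap = 15L, min_size = 1L,
                          min_ortholog_genes = 1L)
    # oracle: ranks are positions in A and the permutation order in B
    orank_a <- stats::setNames(seq_len(n) - 1L, ids_a)
    orank_b <- stats::setNames(order(perm) - 1L, ids_b)
    edges <- list()
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (abs(orank_a[i] - orank_a[j]) - 1L < 15L &&
          abs(orank_b[ids_b[i]] - orank_b[ids_b[j]]) - 1L < 15L)
        edges[[length(edges) + 1L]] <- c(ids_a[i], ids_a[j])
    }
    want <- if (length(edges))
      components_oracle(ids_a, do.call(rbind, edges)) else as.list(ids_a)
    got_sets <- lapply(strsplit(got$pairs, ","), function(p)
      vapply(strsplit(p, "|", fixed = TRUE), `[`, "", 1L))
    expect_equal(canonical_sets(got_sets), canonical_sets(want))
  }
})

test_that("planted syntenic segments are recovered exactly", {
  syn <- simulate_synteny_pair(seed = 11)
  cl <- chain_clusters(syn$orthologs, syn$models_a, syn$models_b)
  truth_sets <- split(paste(syn$truth$gene_a, syn$truth$gene_b, sep = "|"),
                      syn$truth$segment_id)
  det_sets <- strsplit(cl$pairs, ",")
  expect_equal(canonical_sets(det_sets), canonical_sets(truth_sets))
})

test_that("coverage is the union of cluster spans over assembly length", {
  cl <- data.frame(cluster_id = c("s1", "s2"),
                   contig_a = "cA", contig_b = c("cB1", "cB2"),
                   n_pairs = 5L,
                   start_a = c(1L, 150000L), end_a = c(200000L, 350000L),
                   start_b = c(1L, 1L), end_b = c(200000L, 200000L),
                   pairs = "x|y", stringsAsFactors = FALSE)
  cov <- synteny_coverage(cl, list(a = c(cA = 1000000L),
                                   b = c(cB1 = 250000L, cB2 = 250000L)))
  # overlapping spans on A merge: 350000 bp covered of 1 Mb
  expect_equal(cov$fraction[cov$genome == "a"], 0.35)
  expect_equal(cov$fraction[cov$genome == "b"], 0.8)
  expect_error(synteny_coverage(cl, list(a = c(cA = 300000L),
                                         b = c(cB1 = 250000L,
                                               cB2 = 250000L))),
               "exceeds")
})

test_that("dotplot export is deterministic and complete", {
  syn <- simulate_synteny_pair(seed = 12)
  cl <- chain_clusters(syn$orthologs, syn$models_a, syn$models_b)
  dp <- export_dotplot(cl, syn$models_a, syn$models_b)
  expect_equal(nrow(dp$points), sum(cl$n_pairs))
  expect_equal(nrow(dp$links), nrow(cl))
  # shuffled input order gives identical sorted output
  cl_shuf <- cl[sample.int(nrow(cl)), , drop = FALSE]
  dp2 <- export_dotplot(cl_shuf, syn$models_a, syn$models_b)
  expect_equal(dp2$points[, c("cluster_id", "gene_a", "mid_a", "mid_b")],
               dp$points[, c("cluster_id", "gene_a", "mid_a", "mid_b")])
  expect_equal(dp2$links, dp$links)
  empty <- export_dotplot(cl[0, ], syn$models_a, syn$models_b)
  expect_equal(nrow(empty$points), 0L)
})
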