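# Tandemly duplicated gene (TDG) detection: similarity filtering, rank
# distance, single-linkage clustering, and long-read validation.

#' Filter an all-vs-all similarity table into candidate duplicate pairs
#'
#' A pair is kept when at least one direction has e-value below the
#' threshold and an aligned span covering at least `min_cov` of the smaller
#' protein. Self hits are ignored; the best supporting hit (maximum
#' bitscore) is retained per unordered pair. When the table carries no
#' usable e-values (score-only sources), `min_bitscore` is applied instead.
#'
#' @param hits data.frame as from [parse_similarity_table()].
#' @param protein_lengths Named integer vector of protein lengths (aa).
#' @param max_evalue E-value threshold (default 1e-20).
#' @param min_cov Minimum aligned fraction of the smaller protein (0.8).
#' @param min_bitscore Score threshold used when `use_bitscore = TRUE`.
#' @param use_bitscore Filter on bitscore instead of e-value.
#' @return data.frame of undirected pairs: `gene_a`, `gene_b` (sorted),
#'   `evalue`, `bitscore`, `coverage`.
#' @export
filter_similarity <- function(hits, protein_lengths, max_evalue = 1e-20,
                              min_cov = 0.8, min_bitscore = 50,
                              use_bitscore = FALSE) {
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), bitscore = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)
  missing <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     names(protein_lengths))
  if (length(missing))
    stop("no protein length for: ", paste(head(missing, 5), collapse = ", "))
  qlen <- protein_lengths[hits$query_id]
  slen <- protein_lengths[hits$subject_id]
  min_len <- pmin(qlen, slen)
  # coverage is measured on the smaller protein of the pair
  span <- ifelse(qlen <= slen, hits$q_aln_span, hits$s_aln_span)
  coverage <- span / min_len
  ok <- coverage >= min_cov &
    (if (use_bitscore) hits$bitscore >= min_bitscore
     else hits$evalue <= max_evalue)
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  coverage <- coverage[ok]
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  key <- paste(a, b, sep = "\r")
  best <- tapply(seq_along(key), key, function(i)
    i[which.max(hits$bitscore[i])])
  best <- unlist(best, use.names = FALSE)
  out <- data.frame(gene_a = a[best], gene_b = b[best],
                    evalue = hits$evalue[best], bitscore = hits$bitscore[best],
                    coverage = coverage[best], stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict similar pairs to tandem candidates by gene rank distance
#'
#' A similar pair is tandem when both genes lie on the same contig and
#' their per-contig rank distance is at most `max_gene_distance` (the
#' boundary is inclusive: "not distant from more than 10 genes").
#'
#' @param pairs data.frame from [filter_similarity()].
#' @param models Gene model data.frame with ranks.
#' @param max_gene_distance Maximum rank distance (default 10).
#' @return `pairs` restricted and augmented with `contig` and
#'   `rank_distance`; `gene_a` is the lower-ranked gene.
#' @export
find_tandem_pairs <- function(pairs, models, max_gene_distance = 10L) {
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), models$gene_id)
  if (length(missing))
    stop("gene id(s) absent from gene models: ",
         paste(head(missing, 5), collapse = ", "))
  contig <- setNames(models$contig, models$gene_id)
  rank <- setNames(models$rank, models$gene_id)
  same <- contig[pairs$gene_a] == contig[pairs$gene_b]
  dist <- abs(rank[pairs$gene_a] - rank[pairs$gene_b])
  keep <- same & dist <= max_gene_distance
  out <- pairs[keep, , drop = FALSE]
  out$contig <- unname(contig[out$gene_a])
  out$rank_distance <- unname(as.integer(dist[keep]))
  swap <- rank[out$gene_a] > rank[out$gene_b]
  tmp <- out$gene_a[swap]; out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  rownames(out) <- NULL
  out
}

#' Single-linkage clustering of tandem pairs
#'
#' Clusters are the connected components of the pair graph. Cluster ids
#' are deterministic (named after the lexicographically smallest member);
#' members are reported in rank order when gene models are supplied.
#'
#' @param tandem_pairs data.frame from [find_tandem_pairs()].
#' @param models Optional gene models for rank-ordering members and spans.
#' @return data.frame with one row per cluster: `cluster_id`, `contig`,
#'   `size`, `members` (comma-separated, rank-ordered), and when models
#'   are given `span_start`/`span_end` covering all member genes.
#' @export
cluster_single_linkage <- function(tandem_pairs, models = NULL) {
  empty <- data.frame(cluster_id = character(), contig = character(),
                      size = integer(), members = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(tandem_pairs)) return(empty)
  g <- igraph::graph_from_data_frame(
    tandem_pairs[, c("gene_a", "gene_b")], directed = FALSE)
  comp <- igraph::components(g)
  genes <- names(comp$membership)
  contig <- if (!is.null(tandem_pairs$contig))
    setNames(tandem_pairs$contig, tandem_pairs$gene_a)[genes] else NULL
  out <- lapply(seq_len(comp$no), function(k) {
    mem <- sort(genes[comp$membership == k])
    ctg <- NA_character_; span <- c(NA_integer_, NA_integer_)
    if (!is.null(models)) {
      sub <- models[match(mem, models$gene_id), , drop = FALSE]
      if (anyNA(sub$gene_id)) stop("cluster member missing from models")
      ctg <- sub$contig[1]
      mem <- sub$gene_id[order(sub$rank)]
      span <- c(min(sub$start), max(sub$end))
    } else if (!is.null(tandem_pairs$contig)) {
      ctg <- tandem_pairs$contig[tandem_pairs$gene_a %in% mem |
                                   tandem_pairs$gene_b %in% mem][1]
    }
    data.frame(cluster_id = paste0("tdg_", mem[1]), contig = ctg,
               size = length(mem), members = paste(mem, collapse = ","),
               span_start = span[1], span_end = span[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

cluster_members <- function(clusters)
  strsplit(clusters$members, ",", fixed = TRUE)

#' Validate tandem clusters with spanning long reads
#'
#' An adjacent member pair (by rank) is validated when at least one primary
#' read alignment completely contains both gene intervals; a cluster is
#' validated when one read contains all member genes. Containment is
#' strict on the aligned reference interval.
#'
#' @param clusters data.frame from [cluster_single_linkage()] (with spans).
#' @param read_spans data.frame from [parse_read_spans()] (primary-only).
#' @param models Gene model data.frame.
#' @return List: `clusters` (input plus `validated_pairs`, `n_pairs`,
#'   `cluster_validated`), `pairs` (per adjacent pair validation), and
#'   `summary` (fractions of validated pairs and clusters).
#' @export
validate_with_reads <- function(clusters, read_spans, models) {
  if (any(!read_spans$is_primary))
    read_spans <- read_spans[read_spans$is_primary, , drop = FALSE]
  unknown <- setdiff(unique(read_spans$contig), unique(models$contig))
  if (length(unknown)) {
    warning("reads on unknown contig(s) skipped: ",
            paste(unknown, collapse = ", "))
    read_spans <- read_spans[!read_spans$contig %in% unknown, , drop = FALSE]
  }
  gene_start <- setNames(models$start, models$gene_id)
  gene_end <- setNames(models$end, models$gene_id)
  by_ctg <- split(read_spans, read_spans$contig)
  covers <- function(ctg, lo, hi) {
    rs <- by_ctg[[ctg]]
    !is.null(rs) && any(rs$start <= lo & rs$end >= hi)
  }
  pair_rows <- list()
  clusters$validated_pairs <- 0L
  clusters$n_pairs <- 0L
  clusters$cluster_validated <- FALSE
  mems <- cluster_members(clusters)
  for (i in seq_len(nrow(clusters))) {
    mem <- mems[[i]]
    ctg <- clusters$contig[i]
    ok_pairs <- 0L
    if (length(mem) >= 2L) {
      for (j in seq_len(length(mem) - 1L)) {
        a <- mem[j]; b <- mem[j + 1L]
        lo <- min(gene_start[a], gene_start[b])
        hi <- max(gene_end[a], gene_end[b])
        v <- covers(ctg, lo, hi)
        ok_pairs <- ok_pairs + v
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          cluster_id = clusters$cluster_id[i], gene_a = a, gene_b = b,
          contig = ctg, validated = v, stringsAsFactors = FALSE)
      }
    }
    clusters$validated_pairs[i] <- ok_pairs
    clusters$n_pairs[i] <- length(mem) - 1L
    clusters$cluster_validated[i] <-
      covers(ctg, min(gene_start[mem]), max(gene_end[mem]))
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(cluster_id = character(), gene_a = character(),
               gene_b = character(), contig = character(),
               validated = logical(), stringsAsFactors = FALSE)
  summary <- data.frame(
    n_pairs = nrow(pairs),
    frac_pairs_validated = if (nrow(pairs)) mean(pairs$validated) else
      NA_real_,
    n_clusters = nrow(clusters),
    frac_clusters_validated = if (nrow(clusters))
      mean(clusters$cluster_validated) else NA_real_)
  list(clusters = clusters, pairs = pairs, summary = summary)
}

#' Per-cluster and global TDG report
#'
#' Summarises cluster sizes and, when dS estimates are available for member
#' pairs, the dS distribution across gene rank-distance bins (1, 2, 3, >=4)
#' together with the Spearman correlation between dS and rank distance.
#'
#' @param clusters data.frame from [cluster_single_linkage()].
#' @param ds_estimates Optional data.frame with `gene_a`, `gene_b`, `dS`.
#' @param models Gene model data.frame (for rank distances).
#' @return List `sizes` (size histogram data.frame), `summary`
#'   (n_clusters, n_genes, mean/max size), `ds_by_distance` (per-bin n,
#'   median and mean dS) and `spearman_ds_distance`.
#' @export
cluster_statistics <- function(clusters, ds_estimates = NULL, models = NULL) {
  if (!nrow(clusters))
    return(list(sizes = data.frame(size = integer(), n = integer()),
                summary = data.frame(n_clusters = 0L, n_genes = 0L,
                                     mean_size = NA_real_, max_size = NA),
                ds_by_distance = NULL, spearman_ds_distance = NA_real_))
  tab <- table(clusters$size)
  sizes <- data.frame(size = as.integer(names(tab)), n = as.integer(tab))
  out <- list(sizes = sizes,
              summary = data.frame(n_clusters = nrow(clusters),
                                   n_genes = sum(clusters$size),
                                   mean_size = mean(clusters$size),
                                   max_size = max(clusters$size)),
              ds_by_distance = NULL, spearman_ds_distance = NA_real_)
  if (!is.null(ds_estimates) && nrow(ds_estimates) && !is.null(models)) {
    rank <- setNames(models$rank, models$gene_id)
    d <- ds_estimates
    d$rank_distance <- abs(rank[d$gene_a] - rank[d$gene_b])
    d <- d[!is.na(d$dS), , drop = FALSE]
    d$bin <- cut(d$rank_distance, c(0, 1, 2, 3, Inf),
                 labels = c("1", "2", "3", ">=4"))
    agg_n <- tapply(d$dS, d$bin, length)
    agg_med <- tapply(d$dS, d$bin, median)
    agg_mean <- tapply(d$dS, d$bin, mean)
    out$ds_by_distance <- data.frame(
      rank_distance = names(agg_n),
      n = as.integer(ifelse(is.na(agg_n), 0L, agg_n)),
      median_ds = as.numeric(agg_med), mean_ds = as.numeric(agg_mean))
    if (nrow(d) >= 3L && stats::sd(d$rank_distance) > 0)
      out$spearman_ds_distance <-
        suppressWarnings(cor(d$dS, d$rank_distance, method = "spearman"))
  }
  out
}

#' All-vs-all protein similarity
#'
#' Runs NCBI blastp (makeblastdb + blastp, tabular output) when available;
#' otherwise falls back to a rank-windowed Smith-Waterman comparison
#' (candidate pairs within `max_gene_distance` on a contig), reporting
#' bitscore-less records that are filtered by score downstream.
#'
#' @param proteins Named character vector of protein sequences.
#' @param models Gene models (required for the windowed fallback).
#' @param max_gene_distance Rank window for the fallback.
#' @param evalue blastp e-value cutoff passed to the search (pre-filter
#'   only; the detection threshold is applied by [filter_similarity()]).
#' @return data.frame in the layout of [parse_similarity_table()].
#' @export
all_vs_all_similarity <- function(proteins, models = NULL,
                                  max_gene_distance = 10L, evalue = 1e-6) {
  if (nzchar(Sys.which("blastp")) && nzchar(Sys.which("makeblastdb"))) {
    dir <- tempfile("blast")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    fa <- file.path(dir, "prot.fa")
    write_fasta(proteins, fa)
    db <- file.path(dir, "db")
    out <- file.path(dir, "hits.tsv")
    r1 <- system2("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db),
                  stdout = FALSE, stderr = FALSE)
    if (r1 != 0) stop("makeblastdb failed")
    r2 <- system2("blastp", c("-query", fa, "-db", db, "-outfmt", "6",
                              "-evalue", format(evalue), "-num_threads", "1",
                              "-seg", "no", "-out", out),
                  stdout = FALSE, stderr = FALSE)
    if (r2 != 0) stop("blastp failed")
    return(parse_similarity_table(out))
  }
  if (is.null(models))
    stop("blastp unavailable and no gene models for the windowed fallback")
  rows <- list()
  for (ctg in unique(models$contig)) {
    sub <- models[models$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    n <- nrow(sub)
    for (i in seq_len(n)) {
      for (j in seq_len(min(n, i + max_gene_distance))[-seq_len(i)]) {
        a <- sub$gene_id[i]; b <- sub$gene_id[j]
        al <- align_local(proteins[[a]], proteins[[b]],
                          query_id = a, target_id = b)
        if (al$score <= 0 || !nrow(al$blocks)) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = a, subject_id = b, identity_pct = al$identity_pct,
          aln_length = sum(al$blocks$qend - al$blocks$qstart + 1L),
          q_aln_span = max(al$blocks$qend) - min(al$blocks$qstart) + 1L,
          s_aln_span = max(al$blocks$tend) - min(al$blocks$tstart) + 1L,
          evalue = NA_real_, bitscore = al$score, self = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(parse_similarity_table(textConnection(character())))
  do.call(rbind, rows)
}

#' End-to-end TDG detection on an annotated proteome
#'
#' Convenience wrapper: all-vs-all similarity, similarity filter, rank
#' filter and single-linkage clustering with the published thresholds.
#'
#' @param proteins Named character vector of proteins.
#' @param models Gene model data.frame.
#' @param config Configuration list (see [default_config()]).
#' @return List `pairs` (tandem pairs) and `clusters`.
#' @export
detect_tdg <- function(proteins, models, config = default_config()) {
  config <- validate_config(config)
  hits <- all_vs_all_similarity(proteins, models,
                                max_gene_distance = config$max_gene_distance)
  use_bs <- all(is.na(hits$evalue))
  lens <- setNames(nchar(proteins), names(proteins))
  kept <- filter_similarity(hits, lens, max_evalue = config$max_evalue,
                            min_cov = config$min_coverage,
                            min_bitscore = config$min_bitscore,
                            use_bitscore = use_bs)
  pairs <- find_tandem_pairs(kept, models,
                             max_gene_distance = config$max_gene_distance)
  list(pairs = pairs, clusters = cluster_single_linkage(pairs, models))
}
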