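# Synteny block chaining between two annotated genomes, genome coverage by
# syntenic blocks, and plot-table export.

# rank among ortholog-bearing genes only, per contig, by start position
ortholog_ranks <- function(models, genes) {
  sub <- models[models$gene_id %in% genes, , drop = FALSE]
  sub <- sub[order(sub$contig, sub$start, sub$gene_id), , drop = FALSE]
  sub$orank <- stats::ave(seq_len(nrow(sub)), sub$contig,
                          FUN = seq_along) - 1L
  sub
}

#' Reduce a many-to-many ortholog table to best pairs
#'
#' Pairs are accepted greedily by descending score (ties by gene ids), so
#' that each gene appears in at most one pair.
#'
#' @param orthologs data.frame `gene_a`, `gene_b`, `score`.
#' @return The reduced data.frame.
#' @export
reduce_to_best_pairs <- function(orthologs) {
  o <- orthologs[order(-orthologs$score, orthologs$gene_a,
                       orthologs$gene_b), , drop = FALSE]
  seen_a <- character(); seen_b <- character(); sel <- logical(nrow(o))
  for (i in seq_len(nrow(o))) {
    if (!(o$gene_a[i] %in% seen_a) && !(o$gene_b[i] %in% seen_b)) {
      sel[i] <- TRUE
      seen_a <- c(seen_a, o$gene_a[i]); seen_b <- c(seen_b, o$gene_b[i])
    }
  }
  out <- o[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select contigs eligible for synteny comparison
#'
#' @param models Gene model data.frame for one genome.
#' @param ortholog_genes Character vector of ortholog-bearing gene ids in
#'   that genome.
#' @param min_ortholog_genes Minimum ortholog-bearing genes per contig (5).
#' @return Character vector of contig names.
#' @export
select_contigs <- function(models, ortholog_genes, min_ortholog_genes = 5L) {
  sub <- models[models$gene_id %in% ortholog_genes, , drop = FALSE]
  if (!nrow(sub)) return(character())
  tab <- table(sub$contig)
  names(tab)[tab >= min_ortholog_genes]
}

#' Chain orthologous gene pairs into syntenic clusters
#'
#' Pairs sharing a contig pair are chained (single linkage) when separated
#' by fewer than `max_gap` other orthologous genes, measured in ranks
#' among ortholog-bearing genes; with `both_genomes = TRUE` (default) the
#' gap condition must hold on both genomes. Chaining is
#' orientation-agnostic. Clusters smaller than `min_size` pairs are
#' discarded, as are pairs on contigs with fewer than
#' `min_ortholog_genes` ortholog-bearing genes.
#'
#' @param orthologs data.frame `gene_a`, `gene_b` (and `score` when
#'   many-to-many; reduced with [reduce_to_best_pairs()] first).
#' @param models_a,models_b Gene model data.frames of the two genomes.
#' @param max_gap Strict upper bound on intervening ortholog genes (15).
#' @param min_size Minimum pairs per cluster (5).
#' @param min_ortholog_genes Contig eligibility threshold (5).
#' @param both_genomes Require the gap condition on both genomes.
#' @return data.frame: `cluster_id`, `contig_a`, `contig_b`, `n_pairs`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, `pairs` (comma-separated
#'   `gene_a|gene_b`, ordered along genome A).
#' @export
chain_clusters <- function(orthologs, models_a, models_b, max_gap = 15L,
                           min_size = 5L, min_ortholog_genes = 5L,
                           both_genomes = TRUE) {
  empty <- data.frame(cluster_id = character(), contig_a = character(),
                      contig_b = character(), n_pairs = integer(),
                      start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      pairs = character(), stringsAsFactors = FALSE)
  if (!nrow(orthologs)) return(empty)
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b)) {
    if (is.null(orthologs$score))
      stop("gene appears in several ortholog pairs and no score column ",
           "is available for best-pair reduction")
    orthologs <- reduce_to_best_pairs(orthologs)
  }
  ra <- ortholog_ranks(models_a, orthologs$gene_a)
  rb <- ortholog_ranks(models_b, orthologs$gene_b)
  ok_a <- select_contigs(models_a, orthologs$gene_a, min_ortholog_genes)
  ok_b <- select_contigs(models_b, orthologs$gene_b, min_ortholog_genes)
  p <- orthologs
  p$contig_a <- ra$contig[match(p$gene_a, ra$gene_id)]
  p$contig_b <- rb$contig[match(p$gene_b, rb$gene_id)]
  p$orank_a <- ra$orank[match(p$gene_a, ra$gene_id)]
  p$orank_b <- rb$orank[match(p$gene_b, rb$gene_id)]
  p$start_a <- ra$start[match(p$gene_a, ra$gene_id)]
  p$end_a <- ra$end[match(p$gene_a, ra$gene_id)]
  p$start_b <- rb$start[match(p$gene_b, rb$gene_id)]
  p$end_b <- rb$end[match(p$gene_b, rb$gene_id)]
  if (anyNA(p$contig_a) || anyNA(p$contig_b))
    stop("ortholog pair references a gene absent from the models")
  p <- p[p$contig_a %in% ok_a & p$contig_b %in% ok_b, , drop = FALSE]
  if (!nrow(p)) return(empty)
  key <- paste(p$contig_a, p$contig_b, sep = "\r")
  clusters <- list()
  for (k in unique(key)) {
    q <- p[key == k, , drop = FALSE]
    n <- nrow(q)
    if (n == 1L) { comp <- 1L } else {
      # intervening ortholog genes = rank gap - 1; chain when < max_gap
      edges <- list()
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        gap_a <- abs(q$orank_a[i] - q$orank_a[j]) - 1L
        gap_b <- abs(q$orank_b[i] - q$orank_b[j]) - 1L
        ok <- if (both_genomes) gap_a < max_gap && gap_b < max_gap
        else gap_a < max_gap || gap_b < max_gap
        if (ok) edges[[length(edges) + 1L]] <- c(i, j)
      }
      if (length(edges)) {
        g <- igraph::graph_from_edgelist(do.call(rbind, edges),
                                         directed = FALSE)
        g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
        comp <- igraph::components(g)$membership
      } else comp <- seq_len(n)
    }
    for (cc in unique(comp)) {
      m <- q[comp == cc, , drop = FALSE]
      if (nrow(m) < min_size) next
      m <- m[order(m$orank_a), , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- data.frame(
        cluster_id = paste0("syn_", m$gene_a[1]),
        contig_a = m$contig_a[1], contig_b = m$contig_b[1],
        n_pairs = nrow(m),
        start_a = min(m$start_a), end_a = max(m$end_a),
        start_b = min(m$start_b), end_b = max(m$end_b),
        pairs = paste(paste(m$gene_a, m$gene_b, sep = "|"), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(clusters)) return(empty)
  out <- do.call(rbind, clusters)
  out <- out[order(out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of each genome covered by syntenic blocks
#'
#' @param clusters data.frame from [chain_clusters()].
#' @param assembly_lengths List with named length vectors `a` and `b`
#'   (contig name -> length in bp).
#' @return data.frame `genome`, `covered_bp`, `assembly_bp`, `fraction`.
#' @export
synteny_coverage <- function(clusters, assembly_lengths) {
  cover_one <- function(ctg_col, s_col, e_col, lens) {
    total <- 0
    for (ctg in unique(clusters[[ctg_col]])) {
      if (!ctg %in% names(lens))
        stop("cluster contig absent from assembly lengths: ", ctg)
      sub <- clusters[clusters[[ctg_col]] == ctg, , drop = FALSE]
      if (any(sub[[e_col]] > lens[[ctg]]))
        stop("cluster span exceeds contig length on ", ctg)
      total <- total +
        sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(sub[[s_col]], sub[[e_col]]))))
    }
    total
  }
  ca <- if (nrow(clusters))
    cover_one("contig_a", "start_a", "end_a", assembly_lengths$a) else 0
  cb <- if (nrow(clusters))
    cover_one("contig_b", "start_b", "end_b", assembly_lengths$b) else 0
  data.frame(genome = c("a", "b"), covered_bp = c(ca, cb),
             assembly_bp = c(sum(assembly_lengths$a),
                             sum(assembly_lengths$b)),
             fraction = c(ca / sum(assembly_lengths$a),
                          cb / sum(assembly_lengths$b)))
}

#' Export dotplot points and circular-link records for syntenic clusters
#'
#' One point per ortholog pair (gene midpoints on both genomes, with the
#' cluster's colour index) and one link record per cluster; output is
#' restricted to cluster members and deterministically sorted.
#'
#' @param clusters data.frame from [chain_clusters()].
#' @param models_a,models_b Gene model data.frames.
#' @return List `points` and `links` data.frames.
#' @export
export_dotplot <- function(clusters, models_a, models_b) {
  points <- list()
  mid_a <- setNames((models_a$start + models_a$end) / 2, models_a$gene_id)
  mid_b <- setNames((models_b$start + models_b$end) / 2, models_b$gene_id)
  for (i in seq_len(nrow(clusters))) {
    prs <- strsplit(strsplit(clusters$pairs[i], ",", fixed = TRUE)[[1]],
                    "|", fixed = TRUE)
    ga <- vapply(prs, `[`, "", 1L); gb <- vapply(prs, `[`, "", 2L)
    points[[i]] <- data.frame(
      cluster_id = clusters$cluster_id[i], color_index = i,
      gene_a = ga, gene_b = gb,
      contig_a = clusters$contig_a[i], mid_a = unname(mid_a[ga]),
      contig_b = clusters$contig_b[i], mid_b = unname(mid_b[gb]),
      stringsAsFactors = FALSE)
  }
  points <- if (length(points)) do.call(rbind, points) else
    data.frame(cluster_id = character(), color_index = integer(),
               gene_a = character(), gene_b = character(),
               contig_a = character(), mid_a = numeric(),
               contig_b = character(), mid_b = numeric(),
               stringsAsFactors = FALSE)
  points <- points[order(points$cluster_id, points$gene_a), , drop = FALSE]
  rownames(points) <- NULL
  links <- clusters[order(clusters$cluster_id),
                    c("cluster_id", "contig_a", "start_a", "end_a",
                      "contig_b", "start_b", "end_b"), drop = FALSE]
  rownames(links) <- NULL
  list(points = points, links = links)
}
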