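# End-to-end orchestration on synthetic data: simulate -> detect ->
# validate -> age -> screen -> synteny -> telomere, with one consolidated
# report and a reproducibility manifest.

#' Estimate dS for within-cluster adjacent duplicate pairs
#'
#' Protein pairs are locally aligned, the alignment is back-propagated to
#' the CDS pair (codon alignment; gap columns dropped pairwise), and the
#' Nei-Gojobori estimator applied.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param cds Named character vector of CDS sequences.
#' @param proteins Named character vector of proteins.
#' @return data.frame: pair ids plus the [ng86_ds()] fields.
#' @export
pair_ds_estimates <- function(pairs, cds, proteins) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    al <- align_local(proteins[[a]], proteins[[b]])
    if (!nrow(al$blocks)) return(NULL)
    ca <- character(); cb <- character()
    for (j in seq_len(nrow(al$blocks))) {
      blk <- al$blocks[j, ]
      ca <- c(ca, substr(cds[[a]], (blk$qstart - 1L) * 3L + 1L,
                         blk$qend * 3L))
      cb <- c(cb, substr(cds[[b]], (blk$tstart - 1L) * 3L + 1L,
                         blk$tend * 3L))
    }
    est <- ng86_ds(paste(ca, collapse = ""), paste(cb, collapse = ""),
                   ids = c(a, b))
    names(est)[1:2] <- c("gene_a", "gene_b")
    est
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      dS = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

adjacent_member_pairs <- function(clusters) {
  mems <- cluster_members(clusters)
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    mem <- mems[[i]]
    if (length(mem) < 2L) next
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = clusters$cluster_id[i], gene_a = mem[-length(mem)],
      gene_b = mem[-1L], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cluster_id = character(), gene_a = character(),
                      gene_b = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Run the full pipeline on simulated data
#'
#' Simulates a genome with planted tandem arrays and telomeric repeats,
#' long reads, an orthogroup count matrix with planted amplified families,
#' a copy-number read-hit table and a syntenic genome pair, then runs
#' every analysis stage and aggregates a report: TDG counts and fraction
#' of the gene catalogue, cluster size distribution, read-validation
#' fractions, dS-by-rank-distance bins, amplification calls, synteny
#' coverage and the ITS table. All randomness derives from
#' `config$seed`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param outdir Optional directory; when given, report tables are written
#'   as TSV and a manifest with file checksums is produced.
#' @param sim Optional list of simulation overrides passed to
#'   [genome_params()] (e.g. smaller problem sizes).
#' @return List of class `"tdg_run"`: `report` (named list of data.frames
#'   and scalars), `truth`, `manifest` (when `outdir` given).
#' @export
run_all <- function(config = default_config(), outdir = NULL, sim = list()) {
  config <- validate_config(config)
  seed <- config$seed

  # --- simulate ------------------------------------------------------------
  gp <- do.call(genome_params, c(list(seed = seed), sim))
  g <- simulate_genome(gp)
  tel <- plant_telomeric_arrays(g$genome, seed = seed)
  g$genome <- tel$genome
  read_len <- min(80000L, floor(0.5 * min(nchar(g$genome))))
  reads <- simulate_long_reads(g$genome, coverage = 20,
                               length_mean = read_len, seed = seed)
  fam <- simulate_family_counts(n_og = 400L, n_amplified = 8L, fold = 4,
                                n_single_copy = 30L, seed = seed)
  cn_truth <- setNames(rep(c(1, 2, 5, 10), each = 10L),
                       sprintf("CN%03d", 1:40))
  cn <- simulate_copy_number_data(cn_truth,
                                  single_copy_ogs = names(cn_truth)[1:10],
                                  seed = seed)
  syn <- simulate_synteny_pair(seed = seed)

  # --- detect & validate ---------------------------------------------------
  det <- detect_tdg(g$proteins, g$models, config)
  val <- validate_with_reads(det$clusters, reads$spans, g$models)
  adj <- adjacent_member_pairs(det$clusters)
  ds <- pair_ds_estimates(adj, g$cds, g$proteins)
  stats <- cluster_statistics(det$clusters, ds, g$models)

  # --- screens -------------------------------------------------------------
  screen <- amplification_screen(fam$counts, fam$groupA, fam$groupB,
                                 alpha = config$screen_alpha,
                                 method = config$screen_method)
  cne <- estimate_copy_numbers(cn$hits,
                               setNames(nchar(cn$consensus),
                                        names(cn$consensus)),
                               cn$single_copy_ogs,
                               outlier_mad = config$depth_outlier_mad)

  # --- synteny & telomere --------------------------------------------------
  sclust <- chain_clusters(syn$orthologs, syn$models_a, syn$models_b,
                           max_gap = config$synteny_max_gap,
                           min_size = config$synteny_min_size,
                           min_ortholog_genes = config$min_ortholog_genes,
                           both_genomes = config$synteny_both_genomes)
  scov <- synteny_coverage(sclust, syn$assembly_lengths)
  its <- scan_telomeres(g$genome, config)

  n_genes <- nrow(g$models)
  n_tdg <- sum(det$clusters$size)
  report <- list(
    tdg_summary = data.frame(
      n_genes = n_genes, n_tdg = n_tdg,
      tdg_fraction = if (n_genes) n_tdg / n_genes else 0,
      n_clusters = nrow(det$clusters)),
    cluster_sizes = stats$sizes,
    validation = val$summary,
    ds_by_distance = stats$ds_by_distance,
    spearman_ds_distance = stats$spearman_ds_distance,
    amplification = screen[screen$call != "none", , drop = FALSE],
    copy_numbers = cne$estimates,
    synteny_clusters = sclust,
    synteny_coverage = scov,
    its = its)
  out <- list(report = report,
              truth = list(genome = g$truth, telomere = tel$truth,
                           families = fam, copy_number = cn$truth,
                           synteny = syn$truth),
              clusters = det$clusters, config = config)
  class(out) <- "tdg_run"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    emit <- function(name, df) {
      if (is.null(df) || !is.data.frame(df)) return()
      path <- file.path(outdir, paste0(name, ".tsv"))
      write_tsv(df, path)
      files[[length(files) + 1L]] <<- path
    }
    for (nm in names(report)) if (is.data.frame(report[[nm]]))
      emit(nm, report[[nm]])
    write_config(config, file.path(outdir, "run_config.txt"))
    files[[length(files) + 1L]] <- file.path(outdir, "run_config.txt")
    manifest <- data.frame(file = basename(unlist(files)),
                           md5 = unname(tools::md5sum(unlist(files))),
                           stringsAsFactors = FALSE)
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))
    out$manifest <- manifest
  }
  out
}

#' @export
print.tdg_run <- function(x, ...) {
  r <- x$report
  cat("tandemdup run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  genes: %d, TDG: %d (%.1f%%) in %d clusters\n",
              r$tdg_summary$n_genes, r$tdg_summary$n_tdg,
              100 * r$tdg_summary$tdg_fraction, r$tdg_summary$n_clusters))
  cat(sprintf("  validated pairs: %.1f%%, validated clusters: %.1f%%\n",
              100 * r$validation$frac_pairs_validated,
              100 * r$validation$frac_clusters_validated))
  cat(sprintf("  amplified OG calls: %d\n", nrow(r$amplification)))
  cat(sprintf("  synteny coverage: %.1f%% / %.1f%%\n",
              100 * r$synteny_coverage$fraction[1],
              100 * r$synteny_coverage$fraction[2]))
  cat(sprintf("  ITS records: %d\n", nrow(r$its)))
  invisible(x)
}
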