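# Long-read and short-read-depth simulators with ground truth.

#' Simulate long reads from a genome
#'
#' Reads are sampled uniformly along each contig at the requested coverage;
#' lengths are fixed or lognormal; sequencing errors are injected at
#' `error_rate` with a substitution/insertion/deletion split (default
#' 60/20/20). True origin intervals are returned as alignment spans.
#'
#' @param genome Named character vector of contig sequences.
#' @param coverage Mean coverage depth.
#' @param length_mean Mean read length (bp).
#' @param length_sdlog Lognormal sdlog; 0 gives fixed-length reads.
#' @param error_rate Total per-base error rate.
#' @param error_split Proportions (substitution, insertion, deletion).
#' @param seed Integer seed.
#' @return List with `reads` (named character vector) and `spans`
#'   (data.frame `read_id`, `contig`, `start`, `end` 1-based inclusive,
#'   `read_length`, `contig_length`, `is_primary`).
#' @export
simulate_long_reads <- function(genome, coverage = 20, length_mean = 20000,
                                length_sdlog = 0, error_rate = 0,
                                error_split = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(genome) >= 1L, all(nzchar(genome)))
  empty <- list(reads = character(),
                spans = data.frame(read_id = character(), contig = character(),
                                   start = integer(), end = integer(),
                                   read_length = integer(),
                                   contig_length = integer(),
                                   is_primary = logical()))
  if (coverage <= 0) return(empty)
  if (length_mean > max(nchar(genome)))
    warning("mean read length exceeds contig length; reads are truncated")
  with_seed(derive_seed(seed, "long_reads"), {
    reads <- character(); spans <- list(); rid <- 0L
    for (ctg in names(genome)) {
      clen <- nchar(genome[[ctg]])
      # fragments may hang off either contig end and are clipped, so that
      # spanning probability is uniform along the contig (edge clusters
      # are not systematically missed); read count compensates for the
      # clipped bases to keep the realized depth near `coverage`
      L0 <- min(round(length_mean), clen)
      n <- max(1L, ceiling(coverage * (clen + L0 - 1) / L0))
      lens <- if (length_sdlog > 0)
        pmax(500L, round(stats::rlnorm(
          n, log(length_mean) - length_sdlog^2 / 2, length_sdlog)))
      else rep(L0, n)
      lens <- pmin(lens, clen)
      for (k in seq_len(n)) {
        L <- lens[k]
        s0 <- sample.int(clen + L - 1L, 1L) - (L - 1L)
        a <- max(1L, s0); b <- min(clen, s0 + L - 1L)
        rid <- rid + 1L
        id <- sprintf("read%05d", rid)
        s <- substr(genome[[ctg]], a, b)
        if (error_rate > 0) s <- inject_read_errors(s, error_rate, error_split)
        reads[[id]] <- s
        spans[[rid]] <- data.frame(
          read_id = id, contig = ctg, start = a, end = b,
          read_length = nchar(s), contig_length = clen,
          is_primary = TRUE, stringsAsFactors = FALSE)
      }
    }
    list(reads = reads, spans = do.call(rbind, spans))
  })
}

inject_read_errors <- function(seq, rate, split = c(0.6, 0.2, 0.2)) {
  chars <- strsplit(seq, "")[[1]]
  n_err <- stats::rbinom(1L, length(chars), rate)
  if (n_err == 0L) return(seq)
  pos <- sort(sample.int(length(chars), n_err))
  kind <- sample(c("S", "I", "D"), n_err, replace = TRUE, prob = split)
  bases <- c("A", "C", "G", "T")
  out <- as.list(chars)
  for (k in seq_len(n_err)) {
    p <- pos[k]
    if (kind[k] == "S") out[[p]] <- sample(setdiff(bases, chars[p]), 1L)
    else if (kind[k] == "I") out[[p]] <- c(chars[p], sample(bases, 1L))
    else out[[p]] <- character()
  }
  paste(unlist(out), collapse = "")
}

#' Simulate orthogroup gene-count matrices with planted amplified families
#'
#' Per-species counts are Poisson with a common baseline rate; a planted
#' subset of orthogroups has its group-A rate multiplied by `fold`. A
#' designated block of single-copy orthogroups has count 1 in every
#' species.
#'
#' @param n_og Number of orthogroups.
#' @param n_groupA,n_groupB Species per group (defaults 11 coral-like vs 3
#'   outgroup-like).
#' @param baseline_rate Poisson mean gene count per species.
#' @param n_amplified Number of planted group-A-amplified orthogroups.
#' @param fold Amplification factor.
#' @param n_single_copy Number of forced single-copy orthogroups.
#' @param seed Integer seed.
#' @return List `counts` (matrix OG x species), `groupA`, `groupB`
#'   (species name vectors), `amplified_ogs`, `single_copy_ogs`.
#' @export
simulate_family_counts <- function(n_og = 500L, n_groupA = 11L,
                                   n_groupB = 3L, baseline_rate = 3,
                                   n_amplified = 0L, fold = 4,
                                   n_single_copy = 0L, seed = 1L) {
  stopifnot(n_single_copy + n_amplified <= n_og)
  groupA <- sprintf("spA%02d", seq_len(n_groupA))
  groupB <- sprintf("spB%02d", seq_len(n_groupB))
  ogs <- sprintf("OG%05d", seq_len(n_og))
  with_seed(derive_seed(seed, "family_counts"), {
    counts <- matrix(rpois(n_og * (n_groupA + n_groupB), baseline_rate),
                     nrow = n_og, dimnames = list(ogs, c(groupA, groupB)))
    single <- ogs[seq_len(n_single_copy)]
    counts[single, ] <- 1L
    amplified <- if (n_amplified > 0L)
      ogs[n_single_copy + seq_len(n_amplified)] else character()
    if (length(amplified))
      counts[amplified, groupA] <-
        rpois(length(amplified) * n_groupA, baseline_rate * fold)
    list(counts = counts, groupA = groupA, groupB = groupB,
         amplified_ogs = amplified,
         single_copy_ogs = single)
  })
}

#' Simulate consensus sequences and a short-read hit table for copy-number
#' estimation
#'
#' One consensus per orthogroup; reads of fixed length are placed with
#' evenly spaced starts (uniform coverage) at a depth proportional to the
#' true copy number. A fraction of reads can be made ambiguous (a second
#' equal-score hit), exercising the unique-best-hit rule.
#'
#' @param copy_numbers Named numeric vector: true copy number per OG for
#'   the profiled species.
#' @param single_copy_ogs Names of the OGs forming the normalisation set
#'   (their copy number should be 1).
#' @param og_length Consensus length in amino acids times 3 is not assumed;
#'   lengths are in residues of the consensus coordinate system used by the
#'   hit table (default 1200).
#' @param read_length Read (hit) length in the same units (default 100,
#'   reads trimmed to a fixed length upstream).
#' @param coverage_per_copy Depth contributed by one gene copy.
#' @param p_ambiguous Fraction of reads given a second equal-score hit.
#' @param poisson_jitter If TRUE, per-OG read counts are Poisson-perturbed.
#' @param seed Integer seed.
#' @return List `consensus` (named character), `hits` (data.frame
#'   `read_id`, `og_id`, `start`, `end`, `score`), `truth` (copy numbers),
#'   `single_copy_ogs`.
#' @export
simulate_copy_number_data <- function(copy_numbers, single_copy_ogs,
                                      og_length = 1200L, read_length = 100L,
                                      coverage_per_copy = 30,
                                      p_ambiguous = 0, poisson_jitter = FALSE,
                                      seed = 1L) {
  stopifnot(!is.null(names(copy_numbers)),
            all(single_copy_ogs %in% names(copy_numbers)))
  ogs <- names(copy_numbers)
  with_seed(derive_seed(seed, "copy_number"), {
    consensus <- setNames(vapply(ogs, function(o)
      random_dna(og_length), ""), ogs)
    hits <- list(); rid <- 0L
    for (o in ogs) {
      n_reads <- copy_numbers[[o]] * coverage_per_copy * og_length /
        read_length
      n_reads <- if (poisson_jitter) rpois(1L, n_reads) else round(n_reads)
      if (n_reads == 0L) next
      starts <- round(seq(1L, og_length - read_length + 1L,
                          length.out = n_reads))
      ids <- sprintf("sr%07d", rid + seq_len(n_reads))
      rid <- rid + n_reads
      h <- data.frame(read_id = ids, og_id = o, start = starts,
                      end = starts + read_length - 1L, score = 200,
                      stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <- h
    }
    hits <- do.call(rbind, hits)
    if (p_ambiguous > 0 && length(ogs) > 1L) {
      amb <- which(runif(nrow(hits)) < p_ambiguous)
      if (length(amb)) {
        dup <- hits[amb, , drop = FALSE]
        dup$og_id <- vapply(dup$og_id, function(o)
          sample(setdiff(ogs, o), 1L), "")
        hits <- rbind(hits, dup)
      }
    }
    rownames(hits) <- NULL
    list(consensus = consensus, hits = hits, truth = copy_numbers,
         single_copy_ogs = single_copy_ogs)
  })
}

#' Simulate a pair of genomes with conserved syntenic segments
#'
#' Genome A carries `n_genes` ortholog-bearing genes in order; genome B is
#' built from contiguous segments of that order (each at least
#' `min_segment` genes), shuffled over contigs and optionally inverted.
#' Orthology is the identity map, so the true syntenic segments are known
#' exactly.
#'
#' @param n_genes Ortholog-bearing genes in genome A.
#' @param n_segments Number of conserved segments.
#' @param min_segment Minimum genes per segment.
#' @param n_contigs_b Contigs in genome B; the default (one per segment)
#'   keeps planted segments unambiguous, since two segments that are
#'   adjacent in both genomes would legitimately chain into one cluster.
#' @param invert_frac Fraction of segments inverted in B.
#' @param gene_span,spacer Gene length and intergenic spacing (bp).
#' @param seed Integer seed.
#' @return List `models_a`, `models_b` (gene model data.frames),
#'   `orthologs` (data.frame `gene_a`, `gene_b`, `score`), `truth`
#'   (data.frame `segment_id`, `gene_a`, `gene_b`), `assembly_lengths`.
#' @export
simulate_synteny_pair <- function(n_genes = 120L, n_segments = 10L,
                                  min_segment = 5L, n_contigs_b = n_segments,
                                  invert_frac = 0.3, gene_span = 2000L,
                                  spacer = 1000L, seed = 1L) {
  stopifnot(n_segments * min_segment <= n_genes)
  with_seed(derive_seed(seed, "synteny"), {
    extra <- n_genes - n_segments * min_segment
    add <- if (n_segments > 1L)
      tabulate(sample.int(n_segments, extra, replace = TRUE), n_segments)
    else extra
    sizes <- min_segment + add
    seg_of <- rep(seq_len(n_segments), sizes)
    ids_a <- sprintf("A%04d", seq_len(n_genes))
    ids_b <- sprintf("B%04d", seq_len(n_genes))

    mk_models <- function(ids, contig, offsets) {
      start <- offsets
      data.frame(gene_id = ids, contig = contig, start = start,
                 end = start + gene_span - 1L, strand = "+",
                 cds_length = 900L, utr_length = 0L, n_exons = 1L,
                 stringsAsFactors = FALSE)
    }
    step <- gene_span + spacer
    ma <- mk_models(ids_a, "chrA1", (seq_len(n_genes) - 1L) * step + 1L)
    ma$exons <- lapply(seq_len(n_genes), function(i)
      cbind(start = ma$start[i], end = ma$end[i]))
    ma <- assign_ranks(ma)

    seg_order <- sample.int(n_segments)
    inverted <- runif(n_segments) < invert_frac
    contig_b <- rep_len(seq_len(n_contigs_b), n_segments)
    rows_b <- list(); pos_b <- integer(n_contigs_b)
    truth <- list()
    for (s in seg_order) {
      g <- which(seg_of == s)
      if (inverted[s]) g <- rev(g)
      cb <- contig_b[s]
      for (gi in g) {
        pos_b[cb] <- pos_b[cb] + 1L
        rows_b[[length(rows_b) + 1L]] <- data.frame(
          gene_id = ids_b[gi], contig = sprintf("chrB%d", cb),
          start = (pos_b[cb] - 1L) * step + 1L,
          end = (pos_b[cb] - 1L) * step + gene_span,
          strand = if (inverted[s]) "-" else "+",
          cds_length = 900L, utr_length = 0L, n_exons = 1L,
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        segment_id = sprintf("seg%02d", s), gene_a = ids_a[which(seg_of == s)],
        gene_b = ids_b[which(seg_of == s)], stringsAsFactors = FALSE)
    }
    mb <- do.call(rbind, rows_b)
    mb$exons <- lapply(seq_len(nrow(mb)), function(i)
      cbind(start = mb$start[i], end = mb$end[i]))
    mb <- assign_ranks(mb)
    orthologs <- data.frame(gene_a = ids_a, gene_b = ids_b, score = 500,
                            stringsAsFactors = FALSE)
    lens_b <- tapply(mb$end, mb$contig, max) + spacer
    list(models_a = ma, models_b = mb, orthologs = orthologs,
         truth = do.call(rbind, truth),
         assembly_lengths = list(
           a = c(chrA1 = max(ma$end) + spacer),
           b = setNames(as.integer(lens_b), names(lens_b))))
  })
}
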