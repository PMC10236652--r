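# Tandem-array-aware annotation refinement: recursive splitting of spliced
# alignments across long introns, plus the mapping-noise and gene-candidate
# filters applied around gene calling.

#' Construct a spliced alignment record
#'
#' @param query_id Protein identifier.
#' @param contig Target contig name.
#' @param strand Alignment strand.
#' @param blocks data.frame with `qstart`, `qend` (protein aa), `tstart`,
#'   `tend` (genomic bp, 1-based inclusive) and `score` per block; blocks
#'   must be monotone and non-overlapping on both sequences.
#' @param proteome Optional source proteome label (used by the
#'   mapping-noise filters).
#' @return List of class `"spliced_aln"` with derived `introns`
#'   (data.frame `start`, `end`, `length`) and `total_score`.
#' @export
spliced_alignment <- function(query_id, contig, strand, blocks,
                              proteome = NA_character_) {
  blocks <- blocks[order(blocks$tstart), , drop = FALSE]
  if (nrow(blocks) > 1L) {
    if (any(blocks$tstart[-1] <= blocks$tend[-nrow(blocks)]))
      stop("overlapping alignment blocks on the target")
    qs <- blocks[order(blocks$qstart), ]
    if (any(qs$qstart[-1] <= qs$qend[-nrow(qs)]))
      stop("overlapping alignment blocks on the query")
  }
  introns <- if (nrow(blocks) > 1L)
    data.frame(start = blocks$tend[-nrow(blocks)] + 1L,
               end = blocks$tstart[-1] - 1L,
               length = blocks$tstart[-1] - blocks$tend[-nrow(blocks)] - 1L)
  else data.frame(start = integer(), end = integer(), length = integer())
  structure(list(query_id = query_id, contig = contig, strand = strand,
                 blocks = blocks, introns = introns,
                 total_score = sum(blocks$score), proteome = proteome),
            class = "spliced_aln")
}

default_realigner <- function(protein, window, window_offset)
  realign_protein_to_dna(protein, window, window_offset = window_offset)

#' Recursively split spliced alignments across long introns
#'
#' For each intron longer than `max_intron` (longest first), the alignment
#' is cut at the intron midpoint and the full query is realigned on the two
#' resulting genomic regions. The split is accepted when the two new scores
#' sum to more than the original alignment score (with a relative margin
#' `min_rel_gain` guarding the strict inequality against local-alignment
#' score noise, since a genuine long intron yields two partial matches that
#' sum back to roughly the original score, whereas a chimera over tandem
#' copies roughly doubles it). The process recurses into both halves, so a
#' chimera over k copies resolves into k alignments.
#'
#' @param aln A `"spliced_aln"`.
#' @param genome Named character vector of contig sequences.
#' @param protein Query protein sequence.
#' @param realigner Function `(protein, window, window_offset)` returning
#'   an object with a `score`; defaults to [realign_protein_to_dna()].
#' @param max_intron Intron length (bp) that triggers a split attempt.
#' @param min_rel_gain Required relative score gain for acceptance.
#' @return List of `"spliced_aln"` objects (the input unchanged when no
#'   accepted split exists).
#' @export
split_long_introns <- function(aln, genome, protein,
                               realigner = default_realigner,
                               max_intron = 5000L, min_rel_gain = 0.05) {
  long <- which(aln$introns$length > max_intron)
  if (!length(long)) return(list(aln))
  i <- long[which.max(aln$introns$length[long])]
  mid <- aln$introns$start[i] + aln$introns$length[i] %/% 2L
  contig_seq <- genome[[aln$contig]]
  if (is.null(contig_seq)) stop("alignment contig absent from genome: ",
                                aln$contig)
  left_blocks <- aln$blocks[seq_len(i), , drop = FALSE]
  right_blocks <- aln$blocks[-seq_len(i), , drop = FALSE]
  left_lo <- min(left_blocks$tstart); left_hi <- mid
  right_lo <- mid + 1L; right_hi <- max(right_blocks$tend)
  score_left <- realigner(protein, substr(contig_seq, left_lo, left_hi),
                          left_lo)$score
  score_right <- realigner(protein, substr(contig_seq, right_lo, right_hi),
                           right_lo)$score
  if (score_left + score_right <= aln$total_score * (1 + min_rel_gain))
    return(list(aln))
  mk <- function(blocks) spliced_alignment(aln$query_id, aln$contig,
                                           aln$strand, blocks, aln$proteome)
  c(split_long_introns(mk(left_blocks), genome, protein, realigner,
                       max_intron, min_rel_gain),
    split_long_introns(mk(right_blocks), genome, protein, realigner,
                       max_intron, min_rel_gain))
}

aln_span <- function(a) c(min(a$blocks$tstart), max(a$blocks$tend))

#' Remove intronless alignments from noisy proteome mappings
#'
#' Per source proteome: when single-block (intronless) alignments make up
#' more than `max_fraction` of that proteome's alignments, all of them are
#' removed; otherwise the proteome is left untouched.
#'
#' @param alignments List of `"spliced_aln"` (with `proteome` set).
#' @param max_fraction Trigger fraction (default 0.40, strict ">").
#' @return Filtered list.
#' @export
filter_intronless <- function(alignments, max_fraction = 0.40) {
  if (!length(alignments)) return(alignments)
  prot <- vapply(alignments, `[[`, "", "proteome")
  intronless <- vapply(alignments, function(a) nrow(a$blocks) == 1L, TRUE)
  drop <- logical(length(alignments))
  for (p in unique(prot)) {
    sel <- which(if (is.na(p)) is.na(prot) else !is.na(prot) & prot == p)
    if (mean(intronless[sel]) > max_fraction)
      drop[sel[intronless[sel]]] <- TRUE
  }
  alignments[!drop]
}

intron_keys <- function(a) {
  if (!nrow(a$introns)) return(character())
  paste(a$contig, a$introns$start, a$introns$end)
}

exon_keys <- function(a)
  paste(a$contig, a$blocks$tstart, a$blocks$tend)

#' Remove alignments carrying unique introns over many shared exons
#'
#' An intron is unique when its exact coordinates occur in exactly one
#' alignment. An alignment with at least one unique intron is removed when
#' its genomic span fully contains at least `min_exons_covered` distinct
#' exon coordinates from the set observed across all alignments.
#'
#' @param alignments List of `"spliced_aln"`.
#' @param min_exons_covered Exon-cover threshold (default 10).
#' @return Filtered list.
#' @export
filter_unique_introns <- function(alignments, min_exons_covered = 10L) {
  if (!length(alignments)) return(alignments)
  all_introns <- unlist(lapply(alignments, intron_keys))
  intron_count <- table(all_introns)
  exon_tab <- unique(do.call(rbind, lapply(alignments, function(a)
    data.frame(contig = a$contig, start = a$blocks$tstart,
               end = a$blocks$tend, stringsAsFactors = FALSE))))
  keep <- vapply(alignments, function(a) {
    ik <- intron_keys(a)
    if (!length(ik) || !any(intron_count[ik] == 1L)) return(TRUE)
    span <- aln_span(a)
    covered <- sum(exon_tab$contig == a$contig &
                     exon_tab$start >= span[1] & exon_tab$end <= span[2])
    covered < min_exons_covered
  }, TRUE)
  alignments[keep]
}

#' Gene-candidate filter
#'
#' Applies, in order: (1) single-exon genes with CDS length <= `min_cds_aa`
#' amino acids are removed; (2) of the remainder, a gene is kept when it
#' has homology support in more than one species, or when it is spliced
#' with CDS/UTR length ratio >= `min_cds_utr_ratio` (a UTR length of 0 is
#' treated as an unconstrained ratio).
#'
#' @param genes Gene model data.frame (with `n_exons`, `cds_length`,
#'   `utr_length`).
#' @param homology_species_counts Named integer vector: species with
#'   homology support per gene (missing genes count 0).
#' @param min_cds_aa CDS threshold in amino acids (default 100).
#' @param min_cds_utr_ratio CDS/UTR ratio threshold (default 0.75).
#' @return The kept genes.
#' @export
filter_gene_candidates <- function(genes, homology_species_counts,
                                   min_cds_aa = 100L,
                                   min_cds_utr_ratio = 0.75) {
  hom <- homology_species_counts[genes$gene_id]
  hom[is.na(hom)] <- 0L
  single_exon <- genes$n_exons == 1L
  tiny <- single_exon & genes$cds_length <= 3L * min_cds_aa
  genes <- genes[!tiny, , drop = FALSE]
  hom <- hom[!tiny]
  ratio <- ifelse(genes$utr_length > 0L,
                  genes$cds_length / genes$utr_length, Inf)
  keep <- hom > 1L | (genes$n_exons > 1L & ratio >= min_cds_utr_ratio)
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a chimeric (or genuine long-intron) spliced-alignment fixture
#'
#' Plants `k` tandem copies of a gene separated by `gap` bp of random
#' sequence and returns the chimeric alignment a spliced aligner would
#' produce (the query protein's match spread over all copies), together
#' with the genome, query protein and true locus intervals. With
#' `k = 1, n_exons = 2` the fixture is a genuine two-exon gene whose
#' single intron has length `gap`.
#'
#' @param k Number of tandem copies.
#' @param gap Separation (bp) between copies, or the intron length when
#'   `k = 1, n_exons = 2`.
#' @param n_aa Protein length.
#' @param n_exons Exons per copy (1 keeps each copy a single block).
#' @param divergence dS-scale divergence applied to each copy.
#' @param flank Random flank length.
#' @param seed Integer seed.
#' @return List `genome`, `protein`, `aln` (`"spliced_aln"`), `loci`
#'   (data.frame of true copy intervals).
#' @export
simulate_chimeric_alignment <- function(k = 2L, gap = 8000L, n_aa = 180L,
                                        n_exons = 1L, divergence = 0.05,
                                        flank = 2000L, seed = 1L) {
  stopifnot(k >= 1L)
  with_seed(derive_seed(seed, "chimera"), {
    cds <- random_cds(n_aa)
    protein <- translate_chr(cds)
    mat <- blosum62()
    seg_score <- function(q_aa, t_aa)
      sum(mat[cbind(strsplit(q_aa, "")[[1]], strsplit(t_aa, "")[[1]])])
    seq_parts <- list(random_dna(flank))
    pos <- flank
    blocks <- list(); loci <- list()
    if (k == 1L && n_exons == 2L) {
      # genuine two-exon gene whose single intron has length `gap`
      half <- n_aa %/% 2L
      ex1 <- substr(cds, 1L, half * 3L)
      ex2 <- substr(cds, half * 3L + 1L, n_aa * 3L)
      gstart <- pos + 1L
      for (part in list(list(seq = ex1, qs = 1L, qe = half),
                        list(seq = ex2, qs = half + 1L, qe = n_aa))) {
        if (part$qs > 1L) {
          seq_parts[[length(seq_parts) + 1L]] <- random_dna(gap)
          pos <- pos + gap
        }
        seq_parts[[length(seq_parts) + 1L]] <- part$seq
        blocks[[length(blocks) + 1L]] <- data.frame(
          qstart = part$qs, qend = part$qe, tstart = pos + 1L,
          tend = pos + nchar(part$seq),
          score = seg_score(substr(protein, part$qs, part$qe),
                            translate_chr(part$seq)))
        pos <- pos + nchar(part$seq)
      }
      loci[[1L]] <- data.frame(copy = 1L, start = gstart, end = pos)
    } else {
      # chimera: k full tandem copies; the alignment spreads consecutive
      # query segments over consecutive copies
      bounds <- round(seq(0L, n_aa, length.out = k + 1L))
      for (copy in seq_len(k)) {
        copy_cds <- if (copy == 1L) cds else mutate_cds(cds, divergence)
        copy_start <- pos + 1L
        seq_parts[[length(seq_parts) + 1L]] <- copy_cds
        qs <- bounds[copy] + 1L; qe <- bounds[copy + 1L]
        t_sub <- substr(copy_cds, (qs - 1L) * 3L + 1L, qe * 3L)
        blocks[[length(blocks) + 1L]] <- data.frame(
          qstart = qs, qend = qe,
          tstart = copy_start + (qs - 1L) * 3L,
          tend = copy_start + qe * 3L - 1L,
          score = seg_score(substr(protein, qs, qe), translate_chr(t_sub)))
        pos <- pos + nchar(copy_cds)
        loci[[copy]] <- data.frame(copy = copy, start = copy_start,
                                   end = pos)
        if (copy < k) {
          seq_parts[[length(seq_parts) + 1L]] <- random_dna(gap)
          pos <- pos + gap
        }
      }
    }
    seq_parts[[length(seq_parts) + 1L]] <- random_dna(flank)
    genome <- c(ctg1 = paste(unlist(seq_parts), collapse = ""))
    aln <- spliced_alignment("query1", "ctg1", "+", do.call(rbind, blocks))
    list(genome = genome, protein = protein, aln = aln,
         loci = do.call(rbind, loci))
  })
}
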