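# Sequence-level primitives: local protein alignment, six-frame translated
# realignment, Nei-Gojobori (1986) dS/dN, and duplicate-pair gene-structure
# comparison.

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment with a substitution matrix and affine
#' gaps (a gap of length L costs `gap_open + L * gap_extend`). Defaults are
#' BLOSUM62 with open 11 / extend 1. The empty alignment (score 0) is
#' returned when no positive-scoring alignment exists.
#'
#' @param protein_a,protein_b Amino-acid sequences (character or
#'   [Biostrings::AAString]).
#' @param matrix Substitution matrix (defaults to BLOSUM62).
#' @param gap_open,gap_extend Affine gap parameters.
#' @param query_id,target_id Optional sequence identifiers.
#' @return A list of class `"aln_result"`: `score`, `identity_pct`,
#'   `blocks` (data.frame `qstart`, `qend`, `tstart`, `tend`, 1-based
#'   inclusive, gap-free segments monotone on both sequences).
#' @export
align_local <- function(protein_a, protein_b, matrix = blosum62(),
                        gap_open = 11, gap_extend = 1,
                        query_id = "query", target_id = "target") {
  a <- toupper(as.character(protein_a)); b <- toupper(as.character(protein_b))
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  for (s in list(a, b)) {
    bad <- regexpr(sprintf("[^%s]", paste(rownames(matrix), collapse = "")), s)
    if (bad > 0)
      stop("invalid residue '", substr(s, bad, bad), "' at position ", bad)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(query_id = query_id, target_id = target_id,
                          score = 0, identity_pct = NA_real_,
                          blocks = data.frame(qstart = integer(),
                                              qend = integer(),
                                              tstart = integer(),
                                              tend = integer())),
                     class = "aln_result"))
  }
  # decompose the aligned region into gap-free blocks
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  qpos <- Biostrings::start(Biostrings::pattern(pa))
  tpos <- Biostrings::start(Biostrings::subject(pa))
  pc <- strsplit(pat, "")[[1]]; sc2 <- strsplit(sub, "")[[1]]
  blocks <- list(); qs <- ts <- NA_integer_; qlen <- 0L
  flush <- function() {
    if (qlen > 0L)
      blocks[[length(blocks) + 1L]] <<- c(qs, qs + qlen - 1L, ts,
                                          ts + qlen - 1L)
    qlen <<- 0L
  }
  for (i in seq_along(pc)) {
    if (pc[i] != "-" && sc2[i] != "-") {
      if (qlen == 0L) { qs <- qpos; ts <- tpos }
      qlen <- qlen + 1L
      qpos <- qpos + 1L; tpos <- tpos + 1L
    } else {
      flush()
      if (pc[i] != "-") qpos <- qpos + 1L
      if (sc2[i] != "-") tpos <- tpos + 1L
    }
  }
  flush()
  bm <- do.call(rbind, blocks)
  structure(list(
    query_id = query_id, target_id = target_id, score = sc,
    identity_pct = Biostrings::pid(pa),
    blocks = data.frame(qstart = bm[, 1], qend = bm[, 2],
                        tstart = bm[, 3], tend = bm[, 4])),
    class = "aln_result")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

translate_chr <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3L
  if (n < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, n)), if.fuzzy.codon = "X")))
}

#' Splice-less translated realignment of a protein to a genomic window
#'
#' Translates the window in all six frames and locally aligns the protein
#' to each translation; the best-scoring frame wins. Aligned coordinates
#' are mapped back to genomic base pairs (1-based inclusive, relative to
#' `window_offset`).
#'
#' @param protein Amino-acid sequence.
#' @param genomic_window Nucleotide sequence of the window.
#' @param window_offset Genomic coordinate of the window's first base
#'   (1-based); output block coordinates are absolute.
#' @param matrix,gap_open,gap_extend Scoring, as in [align_local()].
#' @return An `"aln_result"` with additional fields `strand` and `frame`
#'   (0..2), and blocks carrying genomic `tstart`/`tend`.
#' @export
realign_protein_to_dna <- function(protein, genomic_window,
                                   window_offset = 1L,
                                   matrix = blosum62(), gap_open = 11,
                                   gap_extend = 1) {
  win <- toupper(as.character(genomic_window))
  if (nchar(win) < 3L) stop("genomic window shorter than 3 bp")
  L <- nchar(win)
  best <- NULL
  for (strand in c("+", "-")) {
    seq_s <- if (strand == "+") win else revcomp(win)
    for (frame in 0:2) {
      aa <- translate_chr(substr(seq_s, frame + 1L, L))
      if (!nzchar(aa)) next
      al <- align_local(protein, aa, matrix = matrix, gap_open = gap_open,
                        gap_extend = gap_extend)
      if (is.null(best) || al$score > best$score) {
        best <- al; best$strand <- strand; best$frame <- frame
      }
    }
  }
  if (is.null(best)) stop("window too short to translate in any frame")
  if (nrow(best$blocks)) {
    b <- best$blocks
    if (best$strand == "+") {
      b$tstart_g <- window_offset + best$frame + (b$tstart - 1L) * 3L
      b$tend_g <- window_offset + best$frame + b$tend * 3L - 1L
    } else {
      # aa position p on the reverse strand covers genomic
      # [end - frame - 3p + 1, end - frame - 3(p-1)]
      end_g <- window_offset + L - 1L
      b$tstart_g <- end_g - best$frame - b$tend * 3L + 1L
      b$tend_g <- end_g - best$frame - (b$tstart - 1L) * 3L
    }
    best$blocks <- b
  }
  best
}

## ---- Nei-Gojobori (1986) -------------------------------------------------

codon_index <- function(codons) {
  base_idx <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  1L + 16L * base_idx[substr(codons, 1, 1)] +
    4L * base_idx[substr(codons, 2, 2)] + base_idx[substr(codons, 3, 3)]
}

ng86_tables <- function() {
  if (!is.null(.pkg_cache$ng86)) return(.pkg_cache$ng86)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- codons[order(codons)]  # index layout must match codon_index()
  codons <- codons[codon_index(codons)]  # identity; keeps layout explicit
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  # synonymous site fraction per codon: for each position, the share of the
  # three alternative bases giving the same amino acid (changes to stop
  # codons count as nonsynonymous)
  syn_sites <- numeric(64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") { syn_sites[i] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codons[i], pos, pos))) {
        alt <- codons[i]
        substr(alt, pos, pos) <- b
        j <- codon_index(alt)
        if (aa[j] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }
  # pairwise expected synonymous / nonsynonymous differences, averaging
  # with equal weight over mutational pathways; pathways through stop
  # codons are discarded (all-blocked pairs fall back to all pathways)
  Sd <- Nd <- matrix(0, 64, 64)
  perms <- list(`1` = list(1L), `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(64)) {
    for (j in seq_len(64)) {
      if (i == j || aa[i] == "*" || aa[j] == "*") next
      diffpos <- which(strsplit(codons[i], "")[[1]] !=
                         strsplit(codons[j], "")[[1]])
      nd <- length(diffpos)
      paths <- lapply(perms[[as.character(nd)]], function(p) diffpos[p])
      walk <- function(order_) {
        cur <- codons[i]; syn <- 0; non <- 0; blocked <- FALSE
        for (pos in order_) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(codons[j], pos, pos)
          ai <- aa[codon_index(cur)]; aj <- aa[codon_index(nxt)]
          if (aj == "*") blocked <- TRUE
          if (identical(ai, aj)) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        c(syn, non, blocked)
      }
      res <- t(vapply(paths, walk, numeric(3)))
      keep <- res[, 3] == 0
      if (!any(keep)) keep <- rep(TRUE, nrow(res))
      Sd[i, j] <- mean(res[keep, 1])
      Nd[i, j] <- mean(res[keep, 2])
    }
  }
  .pkg_cache$ng86 <- list(codons = codons, aa = aa, syn_sites = syn_sites,
                          Sd = Sd, Nd = Nd)
  .pkg_cache$ng86
}

split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous substitution rates
#'
#' Pathway-counting estimator on a pair of aligned coding sequences:
#' synonymous/nonsynonymous sites are counted per codon (changes to stop
#' codons count as nonsynonymous), observed differences are averaged with
#' equal weight over mutational pathways (pathways through stop codons
#' discarded), and proportions are Jukes-Cantor corrected. Codon columns
#' containing a gap in either sequence are skipped; an internal stop codon
#' is an error.
#'
#' @param cds_a,cds_b Aligned CDS sequences of equal length, a multiple
#'   of 3, over `ACGT-`.
#' @param ids Optional character(2) pair identifiers.
#' @return A one-row data.frame of class `"ds_estimate"`: `id_a`, `id_b`,
#'   `codons` (compared codon count), `S`, `N`, `Sd`, `Nd`, `ps`, `pn`,
#'   `dS`, `dN` (NA when saturated), `saturated`.
#' @export
ng86_ds <- function(cds_a, cds_b, ids = c("a", "b")) {
  a <- toupper(as.character(cds_a)); b <- toupper(as.character(cds_b))
  if (nchar(a) != nchar(b)) stop("aligned CDS lengths differ")
  if (nchar(a) %% 3L != 0L) stop("aligned CDS length not a multiple of 3")
  if (grepl("[^ACGT-]", a) || grepl("[^ACGT-]", b))
    stop("CDS contains characters outside ACGT-")
  ca <- split_codons(a); cb <- split_codons(b)
  gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ca <- ca[!gap]; cb <- cb[!gap]
  if (!length(ca)) stop("no gap-free codon columns to compare")
  tab <- ng86_tables()
  ia <- codon_index(ca); ib <- codon_index(cb)
  stop_a <- which(tab$aa[ia] == "*"); stop_b <- which(tab$aa[ib] == "*")
  if (length(stop_a)) stop("internal stop codon in first CDS at codon ",
                           stop_a[1])
  if (length(stop_b)) stop("internal stop codon in second CDS at codon ",
                           stop_b[1])
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * length(ia) - S
  Sd <- sum(tab$Sd[cbind(ia, ib)])
  Nd <- sum(tab$Nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  out <- data.frame(id_a = ids[1], id_b = ids[2], codons = length(ia),
                    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                    dS = jc(ps), dN = jc(pn),
                    saturated = ps >= 3 / 4, stringsAsFactors = FALSE)
  class(out) <- c("ds_estimate", class(out))
  out
}

## ---- gene structure comparison -------------------------------------------

exon_intron_lengths <- function(gene) {
  ex <- gene$exons[[1]]
  if (is.null(ex) || nrow(ex) == 0L) stop("gene without exons: ",
                                          gene$gene_id)
  ex <- ex[order(ex[, "start"]), , drop = FALSE]
  exl <- ex[, "end"] - ex[, "start"] + 1L
  inl <- if (nrow(ex) > 1L)
    ex[-1L, "start"] - ex[-nrow(ex), "end"] - 1L else integer()
  if (gene$strand == "-") { exl <- rev(exl); inl <- rev(inl) }
  list(exons = as.integer(exl), introns = as.integer(inl))
}

#' Compare exon/intron structures of a duplicate gene pair
#'
#' Exon and intron length vectors are compared positionally after orienting
#' both genes 5' to 3'. The conservation class summarises the comparison:
#' `fully_conserved` (equal exon and intron lengths), `exons_conserved`
#' (equal exon lengths, introns drifted), or `divergent`.
#'
#' @param gene_a,gene_b One-row gene model data.frames.
#' @return A one-row data.frame: pair ids, `exon_count_equal`,
#'   `exon_lengths_equal`, `intron_lengths_equal`, `conservation_class`.
#' @export
compare_structures <- function(gene_a, gene_b) {
  sa <- exon_intron_lengths(gene_a); sb <- exon_intron_lengths(gene_b)
  count_eq <- length(sa$exons) == length(sb$exons)
  ex_eq <- count_eq && all(sa$exons == sb$exons)
  in_eq <- count_eq && length(sa$introns) == length(sb$introns) &&
    all(sa$introns == sb$introns)
  cls <- if (ex_eq && in_eq) "fully_conserved"
  else if (ex_eq) "exons_conserved" else "divergent"
  data.frame(gene_a = gene_a$gene_id, gene_b = gene_b$gene_id,
             exon_count_equal = count_eq, exon_lengths_equal = ex_eq,
             intron_lengths_equal = in_eq, conservation_class = cls,
             stringsAsFactors = FALSE)
}
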