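# Orthogroup-level machinery: consensus construction with outlier removal
# and unspecific-region masking, single-copy set selection, depth-based
# copy-number estimation, the binomial amplification screen, and
# domain-prevalence classification.

msa_matrix <- function(msa) {
  msa <- as.character(msa)
  if (length(unique(nchar(msa))) != 1L)
    stop("ragged MSA: aligned sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Remove outlier sequences from a multiple alignment
#'
#' Each sequence's score is its mean pairwise distance (fraction of
#' differing columns; gap-vs-residue counts as a difference, columns where
#' both sequences are gapped are ignored) to all other rows. Sequences
#' scoring above mean + `sd_threshold` standard deviations are removed.
#' Alignments of fewer than 3 sequences are returned unchanged.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param sd_threshold Outlier threshold in standard deviations (1.5).
#' @return List `msa` (filtered) and `outliers` (removed names).
#' @export
remove_outlier_sequences <- function(msa, sd_threshold = 1.5) {
  if (length(msa) < 3L) return(list(msa = msa, outliers = character()))
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both_gap <- m[i, ] == "-" & m[j, ] == "-"
    cols <- sum(!both_gap)
    d[i, j] <- d[j, i] <- if (cols)
      sum(m[i, !both_gap] != m[j, !both_gap]) / cols else 0
  }
  score <- rowSums(d) / (n - 1L)
  thr <- mean(score) + sd_threshold * stats::sd(score)
  out <- which(score > thr)
  list(msa = msa[setdiff(seq_len(n), out)],
       outliers = if (is.null(names(msa))) as.character(out) else
         names(msa)[out])
}

#' Build an orthogroup consensus from a multiple alignment
#'
#' The consensus is the column-wise majority residue over columns with
#' fewer than `max_gap_frac` gaps (ties broken alphabetically). When the
#' consensus exceeds the median input sequence length by more than
#' `excess_frac` of that median, one further round of outlier removal is
#' run and the consensus rebuilt.
#'
#' @param msa Named character vector of aligned sequences (already
#'   outlier-filtered once).
#' @param max_gap_frac Maximum gap occupancy for a column to be emitted.
#' @param excess_frac Length-excess fraction triggering the second outlier
#'   pass (default 0.15).
#' @param sd_threshold Threshold for the conditional second pass.
#' @return List of class `"consensus_profile"`: `consensus` (string),
#'   `n_sequences_used`, `outliers_removed`, `second_pass` (logical).
#' @export
build_consensus <- function(msa, max_gap_frac = 0.5, excess_frac = 0.15,
                            sd_threshold = 1.5) {
  if (!length(msa)) stop("empty MSA")
  emit <- function(msa) {
    m <- msa_matrix(msa)
    keep <- colMeans(m == "-") < max_gap_frac
    cons <- apply(m[, keep, drop = FALSE], 2, function(col) {
      col <- col[col != "-"]
      if (!length(col)) return("X")
      tab <- sort(table(col), decreasing = TRUE)
      names(tab)[1]
    })
    paste(cons, collapse = "")
  }
  cons <- emit(msa)
  med <- median(nchar(gsub("-", "", msa, fixed = TRUE)))
  removed <- character(); second <- FALSE
  if (nchar(cons) - med > excess_frac * med) {
    second <- TRUE
    flt <- remove_outlier_sequences(msa, sd_threshold)
    removed <- flt$outliers
    if (!length(flt$msa)) stop("empty MSA after outlier filtering")
    cons <- emit(flt$msa)
    msa <- flt$msa
  }
  structure(list(consensus = cons, n_sequences_used = length(msa),
                 outliers_removed = removed, second_pass = second),
            class = "consensus_profile")
}

#' Mask unspecific regions shared between orthogroup consensuses
#'
#' All-vs-all comparison of the consensus set: any stretch of at least
#' `window` amino acids of one consensus aligning to a different consensus
#' at >= `min_identity` identity (typically a common domain) is masked on
#' both sides. Consensuses whose masked fraction exceeds
#' `flag_fraction` are tagged unspecific.
#'
#' @param consensus_set Named character vector of consensus sequences.
#' @param window Minimum shared-segment length in aa (default 30).
#' @param min_identity Identity threshold (default 0.85).
#' @param flag_fraction Masked-fraction threshold for the unspecific flag.
#' @return List `masks` (per OG, an [IRanges::IRanges] of masked aa
#'   intervals, 1-based inclusive), `unspecific` (named logical),
#'   `masked_fraction` (named numeric).
#' @export
mask_unspecific_regions <- function(consensus_set, window = 30L,
                                    min_identity = 0.85,
                                    flag_fraction = 0.5) {
  if (length(consensus_set) < 2L)
    stop("need at least two consensuses to compare")
  ids <- names(consensus_set)
  masks <- setNames(lapply(ids, function(i) IRanges::IRanges()), ids)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      al <- align_local(consensus_set[[i]], consensus_set[[j]])
      if (!nrow(al$blocks)) next
      qlen <- sum(al$blocks$qend - al$blocks$qstart + 1L)
      if (qlen >= window && !is.na(al$identity_pct) &&
          al$identity_pct >= 100 * min_identity) {
        masks[[ids[i]]] <- c(masks[[ids[i]]],
                             IRanges::IRanges(min(al$blocks$qstart),
                                              max(al$blocks$qend)))
        masks[[ids[j]]] <- c(masks[[ids[j]]],
                             IRanges::IRanges(min(al$blocks$tstart),
                                              max(al$blocks$tend)))
      }
    }
  }
  masks <- lapply(masks, IRanges::reduce)
  masked_frac <- vapply(ids, function(k)
    sum(IRanges::width(masks[[k]])) / nchar(consensus_set[[k]]), 0)
  list(masks = masks, unspecific = masked_frac > flag_fraction,
       masked_fraction = masked_frac)
}

#' Select single-copy orthogroups
#'
#' An orthogroup is kept when it has exactly one gene in at least
#' `min_species_exact_one` species (default: all but one) and carries no
#' exclusion flag.
#'
#' @param count_matrix Integer matrix (OG x species).
#' @param min_species_exact_one Minimum species at exactly one copy;
#'   default `ncol(count_matrix) - 1`.
#' @param exclude Optional character vector of flagged OG ids (TE-like or
#'   unspecific) to drop.
#' @return Character vector of OG ids.
#' @export
select_single_copy_ogs <- function(count_matrix,
                                   min_species_exact_one =
                                     ncol(count_matrix) - 1L,
                                   exclude = character()) {
  stopifnot(ncol(count_matrix) >= 2L)
  n_one <- rowSums(count_matrix == 1L)
  ids <- rownames(count_matrix)[n_one >= min_species_exact_one]
  setdiff(ids, exclude)
}

#' Estimate gene copy numbers from read depth on orthogroup consensuses
#'
#' Per read, only a unique best hit is retained (score ties are discarded
#' as ambiguous). Raw depth per OG is total aligned bases over unmasked
#' consensus positions divided by the unmasked length. The normalisation
#' factor is the pooled depth over the single-copy set (after discarding
#' single-copy OGs whose raw depth deviates more than `outlier_mad` MADs
#' from the set median); copy number is raw depth over that factor.
#'
#' @param hits data.frame `read_id`, `og_id`, `start`, `end` (1-based on
#'   the consensus), `score`.
#' @param consensus_lengths Named integer vector of consensus lengths.
#' @param single_copy_set OG ids used for normalisation.
#' @param masks Optional named list of [IRanges::IRanges] masked intervals.
#' @param outlier_mad MAD threshold for the single-copy outlier discard.
#' @return List `estimates` (data.frame `og_id`, `raw_depth`,
#'   `copy_number`), `norm_factor`, `single_copy_used`.
#' @export
estimate_copy_numbers <- function(hits, consensus_lengths, single_copy_set,
                                  masks = NULL, outlier_mad = 3) {
  stopifnot(length(single_copy_set) >= 1L)
  # unique best hit per read; ties dropped
  o <- order(hits$read_id, -hits$score)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$read_id)
  idx <- which(first)
  nxt <- c(idx[-1L] - 1L, nrow(h))
  tie <- nxt > idx & h$score[pmin(idx + 1L, nrow(h))] == h$score[idx]
  h <- h[idx[!tie], , drop = FALSE]

  ogs <- names(consensus_lengths)
  unmasked_len <- setNames(as.numeric(consensus_lengths), ogs)
  masked_bases <- function(og, s, e) {
    if (is.null(masks) || is.null(masks[[og]]) ||
        !length(masks[[og]])) return(rep(0L, length(s)))
    q <- IRanges::IRanges(s, e)
    ov <- IRanges::findOverlaps(q, masks[[og]])
    w <- IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(ov)], masks[[og]][S4Vectors::subjectHits(ov)]))
    out <- rep(0L, length(s))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
    out
  }
  if (!is.null(masks)) {
    for (og in names(masks))
      if (og %in% ogs && length(masks[[og]]))
        unmasked_len[og] <- unmasked_len[og] -
          sum(IRanges::width(IRanges::restrict(
            masks[[og]], 1L, consensus_lengths[[og]])))
  }
  if (any(unmasked_len <= 0))
    unmasked_len[unmasked_len <= 0] <- NA_real_
  aligned <- numeric(length(ogs)); names(aligned) <- ogs
  if (nrow(h)) {
    h <- h[h$og_id %in% ogs, , drop = FALSE]
    mb <- numeric(nrow(h))
    for (og in unique(h$og_id)) {
      i <- which(h$og_id == og)
      mb[i] <- masked_bases(og, h$start[i], h$end[i])
    }
    bases <- (h$end - h$start + 1L) - mb
    agg <- tapply(bases, h$og_id, sum)
    aligned[names(agg)] <- agg
  }
  raw_depth <- aligned / unmasked_len
  sc <- intersect(single_copy_set, ogs)
  if (!length(sc)) stop("single-copy set is empty")
  sc_depth <- raw_depth[sc]
  med <- median(sc_depth, na.rm = TRUE)
  madv <- mad(sc_depth, na.rm = TRUE)
  keep_sc <- if (madv > 0)
    sc[abs(sc_depth - med) <= outlier_mad * madv] else sc
  if (!length(keep_sc))
    stop("single-copy set empty after outlier removal")
  norm <- sum(aligned[keep_sc]) / sum(unmasked_len[keep_sc], na.rm = TRUE)
  if (!is.finite(norm) || norm <= 0)
    stop("non-positive normalisation depth on the single-copy set")
  list(estimates = data.frame(og_id = ogs, raw_depth = as.numeric(raw_depth),
                              copy_number = as.numeric(raw_depth / norm),
                              stringsAsFactors = FALSE),
       norm_factor = norm, single_copy_used = keep_sc)
}

#' Two-sided binomial p-value
#'
#' Exact binomial test of `x` successes in `n` trials against probability
#' `p0`. `method = "minlike"` sums the probabilities of all outcomes no
#' more likely than the observed one (the classical two-sided exact test);
#' `"central"` doubles the smaller tail (capped at 1).
#'
#' @param x,n,p0 Test inputs (vectorised over `x`, `n`).
#' @param method `"minlike"` or `"central"`.
#' @return Numeric p-values.
#' @export
binom_pvalue <- function(x, n, p0, method = c("minlike", "central")) {
  method <- match.arg(method)
  one <- function(x, n) {
    if (n == 0L) return(1)
    if (method == "central") {
      lo <- pbinom(x, n, p0)
      hi <- pbinom(x - 1L, n, p0, lower.tail = FALSE)
      return(min(1, 2 * min(lo, hi)))
    }
    d <- dbinom(0:n, n, p0)
    # relative tolerance guards ties against floating-point noise
    min(1, sum(d[d <= d[x + 1L] * (1 + 1e-7)]))
  }
  # evaluate each distinct (x, n) once; large screens repeat few values
  key <- paste(x, n)
  u <- which(!duplicated(key))
  pv <- mapply(one, rep_len(x, length(key))[u], rep_len(n, length(key))[u])
  unname(pv[match(key, key[u])])
}

#' Binomial gene-family amplification screen
#'
#' For each orthogroup, the summed gene count in group A is tested against
#' a binomial null in which every species contributes equally, i.e.
#' `p0 = |groupA| / (|groupA| + |groupB|)` (the published screen's 11/14
#' group ratio). P-values are Benjamini-Hochberg adjusted across tested
#' orthogroups; calls require adjusted p below `alpha`.
#'
#' @param count_matrix Integer matrix (OG x species).
#' @param groupA,groupB Disjoint species-name vectors.
#' @param alpha Adjusted-p threshold (default 0.001).
#' @param method Two-sided p-value method (see [binom_pvalue()]).
#' @param exclude OG ids (TE-like/unspecific) excluded from testing.
#' @return data.frame `og_id`, `count_groupA`, `count_groupB`,
#'   `expected_ratio`, `p_value`, `p_adjusted`, `call` (one of
#'   `amplified_A`, `amplified_B`, `none`).
#' @export
amplification_screen <- function(count_matrix, groupA, groupB,
                                 alpha = 0.001,
                                 method = c("minlike", "central"),
                                 exclude = character()) {
  method <- match.arg(method)
  if (length(intersect(groupA, groupB)))
    stop("species groups overlap")
  stopifnot(length(groupA) >= 1L, length(groupB) >= 1L,
            all(c(groupA, groupB) %in% colnames(count_matrix)))
  cm <- count_matrix[!rownames(count_matrix) %in% exclude, , drop = FALSE]
  xa <- rowSums(cm[, groupA, drop = FALSE])
  xb <- rowSums(cm[, groupB, drop = FALSE])
  n <- xa + xb
  tested <- n > 0
  p0 <- length(groupA) / (length(groupA) + length(groupB))
  p <- rep(NA_real_, length(n))
  p[tested] <- binom_pvalue(xa[tested], n[tested], p0, method = method)
  padj <- rep(NA_real_, length(n))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  call <- rep("none", length(n))
  sig <- tested & !is.na(padj) & padj < alpha
  call[sig & xa / n > p0] <- "amplified_A"
  call[sig & xa / n < p0] <- "amplified_B"
  data.frame(og_id = rownames(cm), count_groupA = as.integer(xa),
             count_groupB = as.integer(xb), expected_ratio = p0,
             p_value = p, p_adjusted = padj, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify orthogroups by protein-domain prevalence
#'
#' An orthogroup receives every label whose listed domains are carried by
#' at least the rule's prevalence fraction of its member genes (e.g.
#' TIR-domain receptors at 20%, NACHT at 5%, lectin-like at 50%).
#'
#' @param og_members Named list: OG id -> character vector of gene ids.
#' @param gene_domains data.frame `gene_id`, `domain_id`.
#' @param rules data.frame `label`, `domains` (comma-separated ids),
#'   `min_prevalence`.
#' @return data.frame `og_id`, `label`, `prevalence` (one row per
#'   assigned label).
#' @export
classify_og_by_domain <- function(og_members, gene_domains, rules) {
  known <- unique(unlist(og_members))
  unknown <- setdiff(unique(gene_domains$gene_id), known)
  if (length(unknown))
    warning(length(unknown), " gene id(s) in the domain table are not in ",
            "any orthogroup")
  dom_by_gene <- split(gene_domains$domain_id, gene_domains$gene_id)
  out <- list()
  for (og in names(og_members)) {
    genes <- og_members[[og]]
    if (!length(genes)) next
    for (r in seq_len(nrow(rules))) {
      doms <- trimws(strsplit(rules$domains[r], ",")[[1]])
      hit <- vapply(genes, function(g)
        any(dom_by_gene[[g]] %in% doms), TRUE)
      prev <- mean(hit)
      if (prev >= rules$min_prevalence[r])
        out[[length(out) + 1L]] <- data.frame(
          og_id = og, label = rules$label[r], prevalence = prev,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(og_id = character(), label = character(),
                      prevalence = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
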