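# Telomeric repeat detection: window scan for (TTAGGG)n arrays on both
# strands, merging of nearby hits into interstitial telomeric sequence
# (ITS) records, and terminal-vs-interstitial classification.

#' Scan a genome for telomeric repeat windows
#'
#' The query is `units` copies of the motif (24 nt for (TTAGGG)4). A
#' window is a hit when it matches the query with at most `max_mismatch`
#' mismatches over the full window (which implies identity above
#' `min_identity` and coverage of at least `min_coverage` for the default
#' thresholds). Both strands are scanned; overlapping or adjacent hits on
#' the same strand are merged into maximal runs before ITS merging.
#'
#' @param genome Named character vector of contig sequences.
#' @param motif Repeat unit (default TTAGGG).
#' @param units Motif copies per query window (default 4).
#' @param max_mismatch Maximum mismatches per window (default 2).
#' @param min_identity,min_coverage Acceptance thresholds; windows below
#'   either are rejected (the defaults are implied by `max_mismatch` for
#'   full-length windows and kept as explicit guards).
#' @return data.frame `contig`, `start`, `end` (1-based inclusive),
#'   `strand`, `n_windows`, `mean_identity`.
#' @export
scan_telomeric_windows <- function(genome, motif = "TTAGGG", units = 4L,
                                   max_mismatch = 2L, min_identity = 0.75,
                                   min_coverage = 0.75) {
  stopifnot(nzchar(motif), units >= 1L)
  query <- paste(rep(motif, units), collapse = "")
  w <- nchar(query)
  out <- list()
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") query else revcomp(query)
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
      if (!length(m)) next
      mm <- Biostrings::neditAt(Biostrings::DNAString(pat), subj,
                                at = Biostrings::start(m))
      ident <- (w - mm) / w
      keep <- ident > min_identity & 1 >= min_coverage
      if (!any(keep)) next
      r <- IRanges::IRanges(Biostrings::start(m)[keep],
                            Biostrings::end(m)[keep])
      runs <- IRanges::reduce(r, min.gapwidth = 1L)
      ov <- IRanges::findOverlaps(r, runs)
      mean_id <- tapply(ident[keep][S4Vectors::queryHits(ov)],
                        S4Vectors::subjectHits(ov), mean)
      n_win <- tapply(S4Vectors::queryHits(ov),
                      S4Vectors::subjectHits(ov), length)
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = IRanges::start(runs),
        end = IRanges::end(runs), strand = strand,
        n_windows = as.integer(n_win),
        mean_identity = as.numeric(mean_id), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_windows = integer(), mean_identity = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge telomeric hits into ITS records
#'
#' Strand-agnostic chaining per contig: consecutive hits separated by a
#' gap of fewer than `max_gap` base pairs are gathered into a single
#' record spanning from the first to the last hit.
#'
#' @param raw_hits data.frame from [scan_telomeric_windows()].
#' @param max_gap Strict gap bound in bp (default 400: gaps of 399 bp
#'   merge, gaps of 400 bp or more do not).
#' @return data.frame `contig`, `start`, `end`, `n_windows_merged`,
#'   `mean_identity`.
#' @export
merge_into_its <- function(raw_hits, max_gap = 400L) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), n_windows_merged = integer(),
                      mean_identity = numeric(), stringsAsFactors = FALSE)
  if (!nrow(raw_hits)) return(empty)
  out <- list()
  for (ctg in unique(raw_hits$contig)) {
    h <- raw_hits[raw_hits$contig == ctg, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    acc_n <- h$n_windows[1]; acc_id <- h$mean_identity[1] * h$n_windows[1]
    flush <- function()
      out[[length(out) + 1L]] <<- data.frame(
        contig = ctg, start = cur$start, end = cur$end,
        n_windows_merged = acc_n, mean_identity = acc_id / acc_n,
        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(h))[-1L]) {
      gap <- h$start[i] - cur$end - 1L
      if (gap < max_gap) {
        cur$end <- max(cur$end, h$end[i])
        acc_n <- acc_n + h$n_windows[i]
        acc_id <- acc_id + h$mean_identity[i] * h$n_windows[i]
      } else {
        flush()
        cur <- h[i, , drop = FALSE]
        acc_n <- h$n_windows[i]; acc_id <- h$mean_identity[i] * h$n_windows[i]
      }
    }
    flush()
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify ITS records as terminal or interstitial
#'
#' A record is terminal when it starts within `end_window` bp of a contig
#' end (on either side); otherwise it is interstitial.
#'
#' @param its_records data.frame from [merge_into_its()].
#' @param contig_lengths Named integer vector.
#' @param end_window Terminal window in bp (default 1000).
#' @return The records with a `classification` column.
#' @export
classify_terminal <- function(its_records, contig_lengths,
                              end_window = 1000L) {
  stopifnot(end_window >= 0L)
  if (!nrow(its_records)) {
    its_records$classification <- character()
    return(its_records)
  }
  clen <- contig_lengths[its_records$contig]
  if (anyNA(clen)) stop("ITS record on contig without a known length")
  if (any(its_records$end > clen | its_records$start < 1L))
    stop("ITS record beyond contig bounds")
  terminal <- its_records$start <= end_window |
    its_records$end > clen - end_window
  its_records$classification <- ifelse(terminal, "terminal", "interstitial")
  its_records
}

#' Full telomere scan: windows, ITS merging, classification
#'
#' @param genome Named character vector of contig sequences.
#' @param config Configuration list (see [default_config()]).
#' @return data.frame of classified ITS records.
#' @export
scan_telomeres <- function(genome, config = default_config()) {
  config <- validate_config(config)
  hits <- scan_telomeric_windows(
    genome, motif = config$telomere_motif, units = config$telomere_units,
    max_mismatch = config$telomere_max_mismatch,
    min_identity = config$telomere_min_identity,
    min_coverage = config$telomere_min_coverage)
  its <- merge_into_its(hits, max_gap = config$its_merge_gap)
  classify_terminal(its, setNames(nchar(genome), names(genome)),
                    end_window = config$terminal_window)
}
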