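#' @importFrom utils read.table write.table modifyList head tail
#' @importFrom stats median mad p.adjust cor dbinom pbinom rpois runif setNames
NULL

# Internal coordinate convention: 1-based inclusive intervals everywhere
# (the IRanges/GFF3 convention). PAF input (0-based half-open) is converted
# at the parse boundary and back on write.

#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/exon/CDS features and builds one gene model per gene,
#' using the representative transcript with the longest total CDS (ties
#' broken by transcript id). Per-contig ranks are assigned by start
#' position, ties broken by gene id.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with one row per gene: `gene_id`, `contig`,
#'   `start`, `end` (1-based inclusive), `strand`, `rank` (0-based, per
#'   contig, ordered by start), `n_exons`, `cds_length`, `utr_length`, and
#'   a list column `exons` of two-column matrices (`start`, `end`).
#' @export
parse_gene_models <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body)) return(empty_gene_models())
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield != 9L]
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], ": expected 9 tab-separated fields")
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  gff$seqid <- as.character(gff$seqid)
  gff$type <- as.character(gff$type)

  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  cdss  <- gff[gff$type == "CDS",  , drop = FALSE]
  if (!nrow(genes)) return(empty_gene_models())

  cds_by_tx <- tapply(cdss$end - cdss$start + 1L, cdss$Parent, sum)
  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == g$ID, , drop = FALSE]
    if (!nrow(tx)) stop("gene without mRNA feature: ", g$ID)
    lens <- cds_by_tx[tx$ID]
    lens[is.na(lens)] <- 0L
    rep_tx <- tx$ID[order(-lens, tx$ID)][1]
    ex <- exons[!is.na(exons$Parent) & exons$Parent == rep_tx, , drop = FALSE]
    if (!nrow(ex)) stop("transcript without exons: ", rep_tx)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start < g$start | ex$end > g$end))
      stop("exon outside gene bounds for gene ", g$ID)
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons for gene ", g$ID)
    cds_len <- cds_by_tx[rep_tx]
    if (is.na(cds_len)) cds_len <- 0L
    exon_len <- sum(ex$end - ex$start + 1L)
    models[[i]] <- list(
      gene_id = g$ID, contig = g$seqid, start = g$start, end = g$end,
      strand = as.character(g$strand),
      exons = cbind(start = ex$start, end = ex$end),
      cds_length = as.integer(cds_len),
      utr_length = as.integer(max(0L, exon_len - cds_len)))
  }
  out <- data.frame(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    contig = vapply(models, `[[`, "", "contig"),
    start = vapply(models, `[[`, 0L, "start"),
    end = vapply(models, `[[`, 0L, "end"),
    strand = vapply(models, `[[`, "", "strand"),
    cds_length = vapply(models, `[[`, 0L, "cds_length"),
    utr_length = vapply(models, `[[`, 0L, "utr_length"),
    stringsAsFactors = FALSE)
  out$n_exons <- vapply(models, function(m) nrow(m$exons), 0L)
  out$exons <- lapply(models, `[[`, "exons")
  assign_ranks(out)
}

empty_gene_models <- function() {
  out <- data.frame(gene_id = character(), contig = character(),
                    start = integer(), end = integer(), strand = character(),
                    cds_length = integer(), utr_length = integer(),
                    n_exons = integer(), rank = integer(),
                    stringsAsFactors = FALSE)
  out$exons <- list()
  out
}

#' Assign per-contig gene ranks
#'
#' Ranks are 0-based per contig, ordered by start position; equal starts are
#' broken lexicographically by gene id. Duplicate gene ids are an error.
#'
#' @param models Gene model data.frame.
#' @return The data.frame, ordered by (contig, rank), with a `rank` column.
#' @export
assign_ranks <- function(models) {
  if (anyDuplicated(models$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(models$gene_id[duplicated(models$gene_id)]),
               collapse = ", "))
  ord <- order(models$contig, models$start, models$gene_id)
  models <- models[ord, , drop = FALSE]
  models$rank <- stats::ave(seq_len(nrow(models)), models$contig,
                            FUN = seq_along) - 1L
  rownames(models) <- NULL
  models
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features (one transcript per gene; exons are
#' written as both exon and CDS records, UTRs are not modelled on output).
#'
#' @param models Gene model data.frame as from [parse_gene_models()].
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models))) {
    g <- models[i, ]
    tx_id <- paste0(g$gene_id, ".t1")
    row9 <- function(type, s, e, attr)
      paste(g$contig, "tandemdup", type, s, e, ".", g$strand, ".", attr,
            sep = "\t")
    lines <- c(row9("gene", g$start, g$end, paste0("ID=", g$gene_id)),
               row9("mRNA", g$start, g$end,
                    paste0("ID=", tx_id, ";Parent=", g$gene_id)))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
                 row9("exon", ex[j, "start"], ex[j, "end"],
                      paste0("ID=", tx_id, ".e", j, ";Parent=", tx_id)),
                 row9("CDS", ex[j, "start"], ex[j, "end"],
                      paste0("ID=", tx_id, ".c", j, ";Parent=", tx_id)))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Parse a 12-column tabular similarity table (BLAST outfmt 6 dialect)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. Alignment spans are computed as
#' `|qend - qstart| + 1` and `|send - sstart| + 1`.
#'
#' @param path Path to the tabular file (or a connection).
#' @return data.frame of hits with columns `query_id`, `subject_id`,
#'   `identity_pct`, `aln_length`, `q_aln_span`, `s_aln_span`, `evalue`,
#'   `bitscore`, `self` (logical).
#' @export
parse_similarity_table <- function(path) {
  cols <- c("query_id", "subject_id", "identity_pct", "aln_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  empty <- function() {
    d <- data.frame(query_id = character(), subject_id = character(),
                    identity_pct = numeric(), aln_length = integer(),
                    q_aln_span = integer(), s_aln_span = integer(),
                    evalue = numeric(), bitscore = numeric(),
                    self = logical(), stringsAsFactors = FALSE)
    d
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("similarity table row ", bad[1], " has ", lengths(fields)[bad[1]],
         " columns, expected 12")
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  if (anyNA(num[, 9]))
    stop("non-numeric e-value at row ", which(is.na(num[, 9]))[1])
  if (anyNA(num))
    stop("non-numeric field at row ", which(rowSums(is.na(num)) > 0)[1])
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    identity_pct = num[, 1],
                    aln_length = as.integer(num[, 2]),
                    q_aln_span = as.integer(abs(num[, 6] - num[, 5]) + 1),
                    s_aln_span = as.integer(abs(num[, 8] - num[, 7]) + 1),
                    evalue = num[, 9], bitscore = num[, 10],
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$evalue)))
    stop("non-finite e-value at row ", which(!is.finite(out$evalue))[1])
  out$self <- out$query_id == out$subject_id
  out
}

#' Parse long-read alignment spans (PAF or 4-column TSV)
#'
#' PAF coordinates are 0-based half-open on the reference and converted to
#' the package's 1-based inclusive convention. The 4-column TSV dialect
#' (`read_id contig start end`) is taken as already 1-based inclusive and
#' all rows are treated as primary alignments.
#'
#' @param path Path to a PAF or TSV file.
#' @param drop_secondary Drop PAF rows without a `tp:A:P` tag?
#' @return data.frame with `read_id`, `contig`, `start`, `end`,
#'   `is_primary`.
#' @export
parse_read_spans <- function(path, drop_secondary = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(read_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      is_primary = logical(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 4L)) {
    m <- do.call(rbind, fields)
    out <- data.frame(read_id = m[, 1], contig = m[, 2],
                      start = as.integer(m[, 3]), end = as.integer(m[, 4]),
                      is_primary = TRUE, stringsAsFactors = FALSE)
  } else if (all(nf >= 12L)) {
    out <- data.frame(
      read_id = vapply(fields, `[`, "", 1L),
      contig = vapply(fields, `[`, "", 6L),
      start = as.integer(vapply(fields, `[`, "", 8L)) + 1L,  # 0-based in PAF
      end = as.integer(vapply(fields, `[`, "", 9L)),
      stringsAsFactors = FALSE)
    tags <- vapply(fields, function(f)
      paste(f[-seq_len(12L)], collapse = " "), "")
    out$is_primary <- !grepl("tp:A:[SI]", tags)
    if (drop_secondary) out <- out[out$is_primary, , drop = FALSE]
  } else {
    stop("read span file is neither PAF (>=12 columns) nor 4-column TSV")
  }
  bad <- which(out$start > out$end)
  if (length(bad)) stop("alignment with start > end at row ", bad[1])
  rownames(out) <- NULL
  out
}

#' Write read spans as PAF
#'
#' Minimal PAF: query name/length/start/end, strand, target
#' name/length/start/end, matches, block length, mapq, and a `tp:A:` tag.
#' Reference coordinates are converted back to 0-based half-open.
#'
#' @param spans data.frame with `read_id`, `read_length`, `contig`,
#'   `contig_length`, `start`, `end` (1-based inclusive), `is_primary`.
#' @param path Output path.
#' @export
write_paf <- function(spans, path) {
  tp <- ifelse(spans$is_primary, "tp:A:P", "tp:A:S")
  lines <- paste(spans$read_id, spans$read_length, 0L, spans$read_length,
                 "+", spans$contig, spans$contig_length,
                 spans$start - 1L, spans$end, spans$end - spans$start + 1L,
                 spans$end - spans$start + 1L, 60L, tp, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write plain TSV report tables
#'
#' All report tables are written with headers, tab-separated, no quoting,
#' so that writing then re-reading reproduces identical records.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  x <- x[, setdiff(names(x), "exons"), drop = FALSE]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
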