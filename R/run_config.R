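#' Default run configuration
#'
#' All tunables of the pipeline in one flat named list. Defaults are the
#' published thresholds of the analysis: similarity filter (e-value <=
#' 1e-20, >= 80% of the smaller protein aligned), gene rank distance <= 10,
#' intron split trigger > 5 kb, intronless-alignment proteome fraction 40%,
#' unique-intron exon cover 10, single-exon CDS minimum 100 aa, CDS/UTR
#' ratio 0.75, MSA outlier threshold 1.5 SD, consensus length excess 15%,
#' unspecific window 30 aa at >= 85% identity, single-copy rule "exactly 1
#' copy in at least S-1 species", amplification screen alpha 0.001 with a
#' group-ratio binomial null, synteny chaining (>= 5 ortholog genes per
#' contig, < 15 ortholog-gene gap, >= 5 pairs per cluster), telomere scan
#' ((TTAGGG)4, identity > 75%, coverage >= 75%, <= 2 mismatches, < 400 bp
#' ITS merge gap).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed                  = 1L,
    # tdg
    max_evalue            = 1e-20,
    min_coverage          = 0.8,
    max_gene_distance     = 10L,
    min_bitscore          = 50,     # score-equivalent filter when no e-value
    # annot_refine
    max_intron            = 5000L,
    split_min_rel_gain    = 0.05,
    intronless_max_fraction = 0.40,
    unique_intron_min_exons = 10L,
    min_cds_aa            = 100L,
    min_cds_utr_ratio     = 0.75,
    # og_families
    outlier_sd            = 1.5,
    consensus_excess_frac = 0.15,
    consensus_max_gap_frac = 0.50,
    mask_window           = 30L,
    mask_min_identity     = 0.85,
    unspecific_flag_fraction = 0.5,
    single_copy_slack     = 1L,     # "at least S-1 species" rule
    depth_outlier_mad     = 3,
    screen_alpha          = 0.001,
    screen_method         = "minlike",
    # synteny
    min_ortholog_genes    = 5L,
    synteny_max_gap       = 15L,
    synteny_min_size      = 5L,
    synteny_both_genomes  = TRUE,
    # telomere
    telomere_motif        = "TTAGGG",
    telomere_units        = 4L,
    telomere_max_mismatch = 2L,
    telomere_min_identity = 0.75,
    telomere_min_coverage = 0.75,
    its_merge_gap         = 400L,
    terminal_window       = 1000L
  )
}

.config_ranges <- list(
  min_coverage = c(0, 1), intronless_max_fraction = c(0, 1),
  min_cds_utr_ratio = c(0, Inf), outlier_sd = c(0, Inf),
  consensus_excess_frac = c(0, 1), consensus_max_gap_frac = c(0, 1),
  mask_min_identity = c(0, 1), unspecific_flag_fraction = c(0, 1),
  screen_alpha = c(0, 1), telomere_min_identity = c(0, 1),
  telomere_min_coverage = c(0, 1), split_min_rel_gain = c(0, Inf)
)

#' Validate a run configuration
#'
#' @param config Named list as from [default_config()]; unknown keys are an
#'   error, missing keys are filled with defaults.
#' @return The completed, validated configuration list.
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, config)
  for (key in names(.config_ranges)) {
    rng <- .config_ranges[[key]]
    v <- out[[key]]
    if (!is.numeric(v) || v < rng[1] || v > rng[2])
      stop("config value out of range for '", key, "'")
  }
  if (!out$screen_method %in% c("minlike", "central"))
    stop("screen_method must be 'minlike' or 'central'")
  out
}

#' Write / read a configuration as a flat key = value text file
#'
#' Serialisation round-trips losslessly: types are restored from the
#' defaults' types.
#'
#' @param config Configuration list.
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  fmt <- function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) as.character(v)
    else format(v, digits = 17, scientific = TRUE)
  }
  writeLines(paste0(names(config), " = ", vapply(config, fmt, "")), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^[ \t]*([^=[:space:]]+)[ \t]*=(.*)$",
                                  lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed config line ", bad[1])
  kv <- lapply(kv, trimws)
  def <- default_config()
  out <- list()
  for (m in kv) {
    key <- m[2]; val <- m[3]
    if (!key %in% names(def)) stop("unknown config key: ", key)
    proto <- def[[key]]
    out[[key]] <-
      if (is.character(proto)) val
      else if (is.logical(proto)) as.logical(val)
      else if (is.integer(proto)) as.integer(round(as.numeric(val)))
      else as.numeric(val)
  }
  validate_config(out)
}
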