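# Synthetic genome generator with planted tandem arrays and full ground
# truth. Tandem arrays grow by a birth process: each duplication copies a
# gene (or a contiguous 2-3-gene unit) next to its source, after which
# every member of the cluster accumulates codon-aware divergence, so that
# older pairs are both more diverged and, through later insertions, tend to
# sit at larger rank distances.

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sense_codons <- function() {
  tab <- ng86_tables()
  tab$codons[tab$aa != "*"]
}

random_cds <- function(n_aa) {
  paste(sample(sense_codons(), n_aa, replace = TRUE), collapse = "")
}

codon_change_options <- function() {
  if (!is.null(.pkg_cache$codon_changes)) return(.pkg_cache$codon_changes)
  tab <- ng86_tables()
  bases <- c("A", "C", "G", "T")
  syn <- nonsyn <- vector("list", 64)
  for (i in seq_len(64)) {
    if (tab$aa[i] == "*") { syn[[i]] <- character(); nonsyn[[i]] <- character(); next }
    s <- character(); n <- character()
    for (pos in 1:3) for (b in setdiff(bases, substr(tab$codons[i], pos, pos))) {
      alt <- tab$codons[i]; substr(alt, pos, pos) <- b
      j <- codon_index(alt)
      if (tab$aa[j] == "*") next
      if (tab$aa[j] == tab$aa[i]) s <- c(s, alt) else n <- c(n, alt)
    }
    syn[[i]] <- s; nonsyn[[i]] <- n
  }
  .pkg_cache$codon_changes <- list(syn = syn, nonsyn = nonsyn)
  .pkg_cache$codon_changes
}

#' Add a target amount of synonymous divergence to a CDS
#'
#' Applies single-base codon-aware substitutions until the expected added
#' synonymous proportion matches `delta_ds` (after Jukes-Cantor inversion),
#' with nonsynonymous changes added at a fixed dN/dS ratio `omega`. Stop
#' codons are never created.
#'
#' @param cds Coding sequence (multiple of 3, no internal stops).
#' @param delta_ds Target dS increment.
#' @param omega dN/dS ratio for the accompanying nonsynonymous changes.
#' @return The mutated CDS.
#' @export
mutate_cds <- function(cds, delta_ds, omega = 0.2) {
  if (delta_ds <= 0) return(cds)
  tab <- ng86_tables(); opts <- codon_change_options()
  cod <- split_codons(toupper(cds))
  idx <- codon_index(cod)
  S <- sum(tab$syn_sites[idx]); N <- 3 * length(idx) - S
  ps_inc <- 3 / 4 * (1 - exp(-4 * delta_ds / 3))
  pn_inc <- 3 / 4 * (1 - exp(-4 * delta_ds * omega / 3))
  # slightly undershoot, then top up against the measured dS
  n_syn <- floor(0.85 * ps_inc * S); n_non <- round(pn_inc * N)
  apply_changes <- function(n_changes, pool) {
    tries <- 0L
    while (n_changes > 0L && tries < 50L * (n_changes + 1L)) {
      k <- sample.int(length(cod), 1L)
      choices <- pool[[codon_index(cod[k])]]
      tries <- tries + 1L
      if (!length(choices)) next
      cod[k] <<- if (length(choices) == 1L) choices else sample(choices, 1L)
      n_changes <- n_changes - 1L
    }
  }
  apply_changes(n_syn, opts$syn)
  apply_changes(n_non, opts$nonsyn)
  # top up: repeated hits at one site register as fewer observed
  # differences, so add synonymous changes until the measured dS reaches
  # the target (within 2%)
  ref <- paste(split_codons(toupper(cds)), collapse = "")
  est <- ng86_ds(ref, paste(cod, collapse = ""))$dS
  guard <- 0L
  while (!is.na(est) && est < 0.98 * delta_ds && guard < 10L * length(cod)) {
    apply_changes(1L, opts$syn)
    guard <- guard + 1L
    est <- ng86_ds(ref, paste(cod, collapse = ""))$dS
  }
  paste(cod, collapse = "")
}

# Split a protein length into exon lengths (in bp, multiples that sum to
# the CDS length) and draw intron lengths.
draw_gene_structure <- function(n_aa, params) {
  n_ex <- sample(params$exon_count_range[1]:params$exon_count_range[2], 1L)
  n_ex <- min(n_ex, n_aa %/% 15L)  # keep exons >= ~15 codons
  n_ex <- max(n_ex, 1L)
  cds_len <- 3L * n_aa
  if (n_ex == 1L) {
    exon_lens <- cds_len
  } else {
    cuts <- sort(sample(seq_len(n_aa - 1L), n_ex - 1L))
    exon_lens <- diff(c(0L, cuts, n_aa)) * 3L
  }
  intron_lens <- if (n_ex > 1L) {
    pmin(pmax(round(stats::rlnorm(n_ex - 1L, params$intron_len_meanlog,
                                  params$intron_len_sdlog)), 60L),
         params$intron_len_max)
  } else integer()
  list(exon_lens = as.integer(exon_lens), intron_lens = as.integer(intron_lens))
}

# Grow one tandem cluster; returns members in genomic order plus the
# divergence matrix accumulated along the birth process.
grow_cluster <- function(size, params) {
  n_aa <- sample(params$protein_len_range[1]:params$protein_len_range[2], 1L)
  founder <- list(cds = random_cds(n_aa),
                  structure = draw_gene_structure(n_aa, params),
                  birth_order = 0L)
  members <- list(founder)
  D <- matrix(0, 1, 1)
  birth <- 0L
  while (length(members) < size) {
    unit <- 1L
    if (params$growth == "random" &&
        stats::runif(1) < params$p_multi_gene_unit && length(members) >= 2L)
      unit <- sample(2:3, 1L)
    unit <- min(unit, length(members), size - length(members))
    # "ordered" growth always copies the youngest member to the array end,
    # so birth order, rank distance and divergence increase together
    src <- if (params$growth == "ordered") length(members)
    else sample.int(length(members) - unit + 1L, 1L)
    block <- members[src:(src + unit - 1L)]
    new_members <- lapply(block, function(m) {
      birth <<- birth + 1L
      st <- m$structure
      if (length(st$intron_lens))  # introns drift on duplication
        st$intron_lens <- pmax(60L, as.integer(round(
          st$intron_lens * stats::runif(length(st$intron_lens), 0.85, 1.15))))
      list(cds = m$cds, structure = st, birth_order = birth)
    })
    ins <- src + unit - 1L
    members <- append(members, new_members, after = ins)
    old_idx <- seq_len(nrow(D))
    map <- append(old_idx, src:(src + unit - 1L), after = ins)
    n2 <- length(map)
    D2 <- matrix(0, n2, n2)
    D2[] <- D[cbind(rep(map, n2), rep(map, each = n2))]
    for (k in seq_len(unit)) D2[ins + k, src + k - 1L] <-
      D2[src + k - 1L, ins + k] <- 0
    D <- D2
    if (params$growth == "ordered") {
      # divergence ladder: only the newborn copy mutates, so dS between
      # members grows linearly with their rank separation
      for (k in ins + seq_len(unit)) {
        members[[k]]$cds <- mutate_cds(members[[k]]$cds, params$delta_ds,
                                       params$omega)
        D[k, -k] <- D[k, -k] + params$delta_ds
        D[-k, k] <- D[-k, k] + params$delta_ds
      }
    } else {
      # every member diverges a little after each event
      members <- lapply(members, function(m) {
        m$cds <- mutate_cds(m$cds, params$delta_ds, params$omega); m
      })
      D <- D + 2 * params$delta_ds
      diag(D) <- 0
    }
  }
  list(members = members, D = D)
}

#' Default genome simulation parameters
#'
#' The defaults reproduce the study conditions used throughout: ~500 genes
#' over ~2 Mb of sequence in 4 contigs, 40 planted tandem clusters of 2-10
#' genes, within-cluster divergence kept below ~10% at the protein level
#' (per-event dS increment 0.03 with dN/dS = 0.2), occasional duplication
#' of 2-3-gene units, and lognormal intron/intergenic lengths.
#'
#' @param ... Overrides for individual parameters.
#' @return Named parameter list.
#' @export
genome_params <- function(...) {
  p <- list(
    seed = 1L, n_contigs = 4L, genes_per_contig = 125L,
    n_clusters = 40L, cluster_size_range = c(2L, 10L),
    p_multi_gene_unit = 0.10,
    protein_len_range = c(120L, 320L),
    exon_count_range = c(1L, 5L),
    intron_len_meanlog = log(350), intron_len_sdlog = 0.5,
    intron_len_max = 3000L,
    intergenic_meanlog = log(1800), intergenic_sdlog = 0.5,
    delta_ds = 0.03, omega = 0.2,
    growth = "random",
    random_strand = TRUE)
  modifyList(p, list(...))
}

#' Simulate a genome with planted tandem gene arrays
#'
#' @param params Parameter list from [genome_params()].
#' @return List with `genome` (named character vector of contig
#'   sequences), `models` (gene model data.frame as from
#'   [parse_gene_models()]), `cds` and `proteins` (named character
#'   vectors), and `truth`: `clusters` (cluster_id, gene_id, birth_order,
#'   contig), `pair_ds` (gene_a, gene_b, true_ds for all within-cluster
#'   pairs), and `params`.
#' @export
simulate_genome <- function(params = genome_params()) {
  with_seed(derive_seed(params$seed, "genome"), {
    sizes <- if (params$n_clusters > 0L)
      sample(params$cluster_size_range[1]:params$cluster_size_range[2],
             params$n_clusters, replace = TRUE) else integer()
    clusters <- lapply(sizes, grow_cluster, params = params)
    contig_of_cluster <- if (params$n_clusters > 0L)
      rep_len(seq_len(params$n_contigs), params$n_clusters) else integer()

    genome <- character(params$n_contigs)
    names(genome) <- sprintf("ctg%02d", seq_len(params$n_contigs))
    rows <- list(); cds_all <- character(); truth_cl <- list(); pair_ds <- list()
    gid <- 0L
    for (ci in seq_len(params$n_contigs)) {
      cl_here <- which(contig_of_cluster == ci)
      n_cluster_genes <- sum(vapply(cl_here, function(k)
        length(clusters[[k]]$members), 0L))
      n_single <- params$genes_per_contig - n_cluster_genes
      if (n_single < 0L)
        stop("contig ", ci, " too short for requested genes: ",
             n_cluster_genes, " cluster genes > ", params$genes_per_contig)
      # entity list: clusters kept contiguous, singletons interleaved
      entities <- list()
      for (k in cl_here)
        entities[[length(entities) + 1L]] <- list(type = "cluster", idx = k)
      for (k in seq_len(n_single))
        entities[[length(entities) + 1L]] <- list(type = "single")
      entities <- entities[sample.int(length(entities))]

      seq_parts <- character(); pos <- 0L
      emit_gene <- function(cds, structure, cluster_id, birth_order) {
        gid <<- gid + 1L
        gene_id <- sprintf("g%04d", gid)
        spacer <- as.integer(max(150, round(
          stats::rlnorm(1, params$intergenic_meanlog,
                        params$intergenic_sdlog))))
        seq_parts[[length(seq_parts) + 1L]] <<- random_dna(spacer)
        pos <<- pos + spacer
        strand <- if (params$random_strand) sample(c("+", "-"), 1L) else "+"
        exl <- structure$exon_lens; inl <- structure$intron_lens
        tx_parts <- character(2L * length(exl) - 1L)
        cds_off <- 0L
        rel <- matrix(0L, length(exl), 2L)  # transcription-order coords
        cur <- 0L
        for (j in seq_along(exl)) {
          tx_parts[2L * j - 1L] <- substr(cds, cds_off + 1L, cds_off + exl[j])
          cds_off <- cds_off + exl[j]
          rel[j, ] <- c(cur + 1L, cur + exl[j])
          cur <- cur + exl[j]
          if (j < length(exl)) {
            tx_parts[2L * j] <- random_dna(inl[j])
            cur <- cur + inl[j]
          }
        }
        gseq <- paste(tx_parts, collapse = "")
        L <- nchar(gseq)
        if (strand == "-") {
          gseq <- revcomp(gseq)
          rel <- cbind(L + 1L - rel[, 2L], L + 1L - rel[, 1L])
          rel <- rel[rev(seq_len(nrow(rel))), , drop = FALSE]
        }
        gstart <- pos + 1L
        seq_parts[[length(seq_parts) + 1L]] <<- gseq
        pos <<- pos + L
        ex_abs <- cbind(start = as.integer(gstart + rel[, 1L] - 1L),
                        end = as.integer(gstart + rel[, 2L] - 1L))
        rows[[length(rows) + 1L]] <<- list(
          gene_id = gene_id, contig = names(genome)[ci],
          start = gstart, end = gstart + L - 1L, strand = strand,
          cds_length = nchar(cds), utr_length = 0L, exons = ex_abs)
        cds_all[[gene_id]] <<- cds
        if (!is.na(cluster_id))
          truth_cl[[length(truth_cl) + 1L]] <<- data.frame(
            cluster_id = cluster_id, gene_id = gene_id,
            birth_order = birth_order, contig = names(genome)[ci],
            stringsAsFactors = FALSE)
        gene_id
      }
      for (ent in entities) {
        if (ent$type == "single") {
          n_aa <- sample(params$protein_len_range[1]:
                           params$protein_len_range[2], 1L)
          emit_gene(random_cds(n_aa), draw_gene_structure(n_aa, params),
                    NA_character_, NA_integer_)
        } else {
          cl <- clusters[[ent$idx]]
          cl_name <- sprintf("cl%03d", ent$idx)
          ids <- vapply(seq_along(cl$members), function(j)
            emit_gene(cl$members[[j]]$cds, cl$members[[j]]$structure,
                      cl_name, cl$members[[j]]$birth_order), "")
          n <- length(ids)
          if (n >= 2L) {
            ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
            pair_ds[[length(pair_ds) + 1L]] <- data.frame(
              cluster_id = cl_name, gene_a = ids[ij[, 1L]],
              gene_b = ids[ij[, 2L]], true_ds = cl$D[ij],
              stringsAsFactors = FALSE)
          }
        }
      }
      seq_parts[[length(seq_parts) + 1L]] <- random_dna(200L)
      genome[ci] <- paste(seq_parts, collapse = "")
    }
    models <- data.frame(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      contig = vapply(rows, `[[`, "", "contig"),
      start = as.integer(vapply(rows, `[[`, 0, "start")),
      end = as.integer(vapply(rows, `[[`, 0, "end")),
      strand = vapply(rows, `[[`, "", "strand"),
      cds_length = as.integer(vapply(rows, `[[`, 0, "cds_length")),
      utr_length = as.integer(vapply(rows, `[[`, 0, "utr_length")),
      stringsAsFactors = FALSE)
    models$n_exons <- vapply(rows, function(r) nrow(r$exons), 0L)
    models$exons <- lapply(rows, `[[`, "exons")
    models <- assign_ranks(models)
    proteins <- vapply(cds_all, translate_chr, "")
    truth <- list(
      clusters = if (length(truth_cl)) do.call(rbind, truth_cl) else
        data.frame(cluster_id = character(), gene_id = character(),
                   birth_order = integer(), contig = character()),
      pair_ds = if (length(pair_ds)) do.call(rbind, pair_ds) else
        data.frame(cluster_id = character(), gene_a = character(),
                   gene_b = character(), true_ds = numeric()),
      params = params)
    list(genome = genome, models = models, cds = cds_all,
         proteins = proteins, truth = truth)
  })
}

#' Plant telomeric repeat arrays into a genome
#'
#' Injects arrays of TTAGGG units (with a configurable number of single-base
#' unit mismatches) at the requested or randomly drawn positions and
#' records exact truth intervals.
#'
#' @param genome Named character vector of contig sequences.
#' @param placements Optional data.frame `contig`, `start`, `n_units`,
#'   `n_mismatches`; drawn randomly when NULL.
#' @param n_arrays,unit_range,mismatch_range Random placement controls.
#' @param motif Repeat unit.
#' @param end_window Window (bp) used to mark planted arrays as terminal in
#'   the truth table.
#' @param seed Seed for random placement.
#' @return List `genome` (modified) and `truth` data.frame with `contig`,
#'   `start`, `end`, `n_units`, `n_mismatches`, `terminal`.
#' @export
plant_telomeric_arrays <- function(genome, placements = NULL, n_arrays = 6L,
                                   unit_range = c(8L, 40L),
                                   mismatch_range = c(0L, 2L),
                                   motif = "TTAGGG", end_window = 1000L,
                                   seed = 1L) {
  u <- nchar(motif)
  with_seed(derive_seed(seed, "telomere_plant"), {
    if (is.null(placements)) {
      rows <- list()
      for (i in seq_len(n_arrays)) {
        n_units <- sample(unit_range[1]:unit_range[2], 1L)
        len <- n_units * u
        # rejection-sample a slot clear of earlier arrays (with a margin
        # larger than the ITS merge distance)
        for (try in 1:100) {
          ctg <- sample(names(genome), 1L)
          start <- sample.int(nchar(genome[[ctg]]) - len, 1L)
          clash <- any(vapply(rows, function(r)
            r$contig == ctg && start <= r$end + 500L &&
              start + len - 1L >= r$start - 500L, TRUE))
          if (!clash) break
        }
        if (clash) stop("could not place ", n_arrays,
                        " non-overlapping arrays")
        rows[[i]] <- data.frame(
          contig = ctg, start = start, end = start + len - 1L,
          n_units = n_units,
          n_mismatches = sample(mismatch_range[1]:mismatch_range[2], 1L),
          stringsAsFactors = FALSE)
      }
      placements <- do.call(rbind, rows)[, c("contig", "start", "n_units",
                                             "n_mismatches")]
    }
    placements$end <- placements$start + placements$n_units * u - 1L
    for (ctg in unique(placements$contig)) {
      p <- placements[placements$contig == ctg, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      if (nrow(p) > 1L && any(p$start[-1] <= p$end[-nrow(p)]))
        stop("overlapping telomeric array placements on ", ctg)
      if (any(p$end > nchar(genome[[ctg]])))
        stop("telomeric array placement outside contig ", ctg)
    }
    bases <- c("A", "C", "G", "T")
    truth <- placements
    for (i in seq_len(nrow(placements))) {
      p <- placements[i, ]
      arr <- strsplit(paste(rep(motif, p$n_units), collapse = ""), "")[[1]]
      if (p$n_mismatches > 0L) {
        units <- sample.int(p$n_units, min(p$n_mismatches, p$n_units))
        for (k in units) {
          off <- (k - 1L) * u + sample.int(u, 1L)
          arr[off] <- sample(setdiff(bases, arr[off]), 1L)
        }
      }
      s <- genome[[p$contig]]
      genome[[p$contig]] <- paste0(substr(s, 1L, p$start - 1L),
                                   paste(arr, collapse = ""),
                                   substr(s, p$end + 1L, nchar(s)))
    }
    clen <- nchar(genome)[truth$contig]
    truth$terminal <- truth$start <= end_window | truth$end > clen - end_window
    list(genome = genome, truth = truth)
  })
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA path.
#' @param type `"DNA"` or `"AA"`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
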