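# Independent brute-force oracles and shared fixtures for the test suite.

# -- naive Smith-Waterman (Gotoh affine-gap) local alignment score ---------
# A gap of length L costs gap_open + L * gap_extend, matching the scoring
# contract of align_local().
sw_score_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0, M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# -- brute-force Nei-Gojobori site/path enumerator -------------------------
# Direct string-based enumeration, independent of the package's lookup
# tables; same stated conventions (stop-creating changes are
# nonsynonymous for site counting; pathways through stops are discarded,
# all-blocked pairs fall back to all pathways).
ng86_oracle <- function(cds_a, cds_b) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons_of <- function(x) substring(x, seq(1, nchar(x), 3),
                                     seq(3, nchar(x), 3))
  syn_sites_codon <- function(cod) {
    aa <- code[[cod]]
    s <- 0
    for (p in 1:3) for (bb in setdiff(bases, substr(cod, p, p))) {
      alt <- cod; substr(alt, p, p) <- bb
      if (code[[alt]] == aa) s <- s + 1 / 3
    }
    s
  }
  path_counts <- function(c1, c2) {
    dif <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dif)) return(c(0, 0))
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      out
    }
    res <- list()
    for (ord in perms(dif)) {
      cur <- c1; syn <- 0; non <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[nxt]] == "*") blocked <- TRUE
        if (code[[cur]] == code[[nxt]]) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      res[[length(res) + 1]] <- c(syn, non, blocked)
    }
    res <- do.call(rbind, res)
    use <- res[, 3] == 0
    if (!any(use)) use <- rep(TRUE, nrow(res))
    c(mean(res[use, 1]), mean(res[use, 2]))
  }
  ca <- codons_of(cds_a); cb <- codons_of(cds_b)
  S <- (sum(vapply(ca, syn_sites_codon, 0)) +
          sum(vapply(cb, syn_sites_codon, 0))) / 2
  N <- 3 * length(ca) - S
  sd_nd <- rowSums(vapply(seq_along(ca),
                          function(i) path_counts(ca[i], cb[i]),
                          numeric(2)))
  list(S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2])
}

# -- brute-force connected components (transitive closure) ------------------
components_oracle <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(nodes, comp[nodes]))
}

canonical_sets <- function(sets)
  sort(unname(vapply(sets, function(s)
    paste(sort(unlist(s)), collapse = ","), "")))

# -- shared fixtures (built once per test run) ------------------------------
.fixtures <- new.env()

fixture_genome <- function() {
  if (is.null(.fixtures$genome))
    .fixtures$genome <- simulate_genome(genome_params(
      n_contigs = 2L, genes_per_contig = 40L, n_clusters = 6L, seed = 3L))
  .fixtures$genome
}

fixture_detection <- function() {
  if (is.null(.fixtures$detection)) {
    g <- fixture_genome()
    .fixtures$detection <- detect_tdg(g$proteins, g$models)
  }
  .fixtures$detection
}

random_aa <- function(n)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")

random_cds_pair <- function(n_aa, target_ds) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  a <- paste(sample(sense, n_aa, replace = TRUE), collapse = "")
  list(a = a, b = mutate_cds(a, target_ds))
}
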