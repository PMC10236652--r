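#' Derive a labelled child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own RNG stream from the
#' master seed through a stable string label, so that re-running one stage
#' (or reordering stages) never perturbs another stage's stream.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the substream (e.g. `"genome"`,
#'   `"long_reads"`).
#' @return An integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label),
            length(label) == 1L)
  mod <- 2147480009   # large prime < 2^31, keeps arithmetic exact in doubles
  h <- as.numeric(master) %% mod
  for (k in utf8ToInt(label)) {
    h <- (h * 131 + k) %% mod
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
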