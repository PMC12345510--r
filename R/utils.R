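#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero (the convention of printed mitogenome tables;
# base round() is round-half-even). Small epsilon guards against binary
# representation of values like 2.675.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Reverse complement preserving IUPAC ambiguity codes; input and output are
# plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and convert RNA to DNA alphabet.
as_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

dna_to_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

`%not in%` <- function(x, table) !(x %in% table)
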