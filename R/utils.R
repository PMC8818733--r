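# shared internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL runs on the ambient stream (used by internal calls so a single
# top-level seed governs a whole simulation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# canonical (chrom, pos, ref, alt) key used for blacklists and joins
variant_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp_chars <- function(chars) rev(chartr("ACGT", "TGCA", chars))

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
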