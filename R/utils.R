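# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# i.i.d. nucleotides at a target GC fraction; returns a single string.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Random CDS: ATG start, non-stop internal codons, TAA terminator.
# `n_codons` includes the start and stop codons.
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  all_codons <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  mid <- sample(sense, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(mid, collapse = ""), "TAA")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a nucleotide string (trimmed to codon multiple), returning the
# amino-acid string with "*" for stops.
translate_nt <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n < 3) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1, n)), if.fuzzy.codon = "solve")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Distribute `filler` bp among `k` slots as evenly as possible (deterministic).
split_filler <- function(filler, k) {
  if (k <= 0) return(integer(0))
  base <- filler %/% k
  extra <- filler %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

# Path to a file shipped under inst/extdata.
mipt_extdata <- function(file) {
  system.file("extdata", file, package = "miptkit", mustWork = TRUE)
}
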