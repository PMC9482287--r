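# Independent brute-force oracles used to freeze expected values.

# Direct translator oracle for gene-status calls: reads frame 1 (fixture
# genes are framed), finds stops and lengths directly, and measures
# identity by position-wise comparison at offset 0.
oracle_classify <- function(observed, reference, type,
                            tau_len = 0.5, tau_id = 0.6) {
  if (is.null(observed) || is.na(observed) || !nzchar(observed)) {
    return("lost")
  }
  n <- min(nchar(observed), nchar(reference))
  obs_chars <- strsplit(observed, "")[[1]]
  ref_chars <- strsplit(reference, "")[[1]]
  ident <- mean(obs_chars[seq_len(n)] == ref_chars[seq_len(n)])
  if (type == "protein") {
    codons <- substring(observed, seq(1, nchar(observed) - 2, 3),
                        seq(3, nchar(observed), 3))
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    ref_codons <- nchar(reference) / 3
    if (length(stops) && stops[1] < ref_codons) return("pseudogene")
    aa_len <- if (length(stops)) stops[1] - 1 else length(codons)
    if (aa_len < tau_len * (ref_codons - 1)) return("pseudogene")
  } else if (nchar(observed) < tau_len * nchar(reference)) {
    return("pseudogene")
  }
  if (ident < tau_id) return("pseudogene")
  "intact"
}

# Quadratic dynamic-programming oracle: all maximal common substrings
# between a linear sequence and its reverse complement, mapped back to
# disjoint inverted-repeat interval pairs; returns the longest.
oracle_longest_ir <- function(seq, min_len) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  rc <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))), "")[[1]]
  best <- NULL
  prev <- integer(n + 1L)
  for (i in seq_len(n)) {
    cur <- integer(n + 1L)
    for (j in seq_len(n)) {
      if (s[i] == rc[j]) {
        cur[j + 1L] <- prev[j] + 1L
        L <- cur[j + 1L]
        if (L >= min_len) {
          a1 <- i - L + 1L; a2 <- i               # interval in seq
          b1 <- n - j + 1L; b2 <- n - (j - L)     # mapped rc interval
          if (a2 < b1 || b2 < a1) {               # disjoint
            if (is.null(best) || L > best$len) {
              best <- list(len = L, a = c(a1, a2), b = sort(c(b1, b2)))
            }
          }
        }
      }
    }
    prev <- cur
  }
  best
}

# Exhaustive monophyly oracle: compare the tip set against the descendant
# set of every internal node, computed independently via ape utilities.
oracle_monophyletic <- function(phy, tips) {
  n_tip <- length(phy$tip.label)
  for (node in (n_tip + 1L):(n_tip + phy$Nnode)) {
    desc <- ape::extract.clade(phy, node)$tip.label
    if (setequal(desc, tips)) return(TRUE)
  }
  FALSE
}

random_rooted_tree <- function(n_tip) {
  ape::rtree(n_tip, rooted = TRUE, br = NULL)
}
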