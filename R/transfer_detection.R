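# Seeded homology scanning of mitochondrial chromosomes against a plastid
# reference gene set, and ORF-completeness assessment of the hits.

# Karlin-Altschul-style significance for an ungapped +1/-2 nucleotide score.
ka_evalue <- function(score, m, n, lambda = 1.28, K = 0.46) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

# Exact greedy extension of a seed on one diagonal, then X-drop extension
# through mismatches keeping the best-scoring endpoint.
extend_seed <- function(s_chars, r_chars, i1, i2, j1, xdrop = 12L) {
  # left
  best <- 0L; score <- 0L; step <- 0L; best_step <- 0L
  while (i1 - step - 1L >= 1L && j1 - step - 1L >= 1L) {
    step <- step + 1L
    score <- score + if (s_chars[i1 - step] == r_chars[j1 - step]) 1L else -2L
    if (score > best) { best <- score; best_step <- step }
    if (best - score > xdrop) break
  }
  left <- best_step
  # right
  j2 <- j1 + (i2 - i1)
  best <- 0L; score <- 0L; step <- 0L; best_step <- 0L
  n_s <- length(s_chars); n_r <- length(r_chars)
  while (i2 + step + 1L <= n_s && j2 + step + 1L <= n_r) {
    step <- step + 1L
    score <- score + if (s_chars[i2 + step] == r_chars[j2 + step]) 1L else -2L
    if (score > best) { best <- score; best_step <- step }
    if (best - score > xdrop) break
  }
  c(i1 - left, i2 + best_step)
}

#' Scan replicons for segments homologous to a reference gene set
#'
#' A seeded ungapped scanner: exact k-mer anchors between each subject
#' replicon (both strands) and every reference gene are chained along their
#' diagonal when separated by at most `join_gap` bp, extended greedily with
#' an X-drop criterion, and scored with a Karlin-Altschul-style significance
#' approximation (match +1, mismatch -2). Only hits with significance below
#' `cutoff` are reported, ordered by (replicon, start).
#'
#' @param subjects Named character vector or `DNAStringSet` of replicon
#'   sequences (e.g. mitochondrial chromosomes).
#' @param reference Reference gene set: data frame with `gene` and
#'   `sequence` columns, or a named character vector.
#' @param cutoff Significance cutoff (default `1e-10`).
#' @param k Seed length (default 13).
#' @param join_gap Maximum gap for chaining same-diagonal anchors and for
#'   merging nearby same-gene hits (default 50 bp).
#' @return A data frame of homology hits: `gene`, `seqid`, `sstart`, `send`,
#'   `qstart`, `qend` (reference coordinates), `strand`, `length`,
#'   `identity`, `mismatches`, `score`, `evalue`.
#' @export
scan_homology <- function(subjects, reference, cutoff = 1e-10, k = 13L,
                          join_gap = 50L) {
  if (methods::is(subjects, "DNAStringSet")) {
    subjects <- stats::setNames(as.character(subjects), names(subjects))
  }
  if (is.data.frame(reference)) {
    ref <- stats::setNames(reference$sequence, reference$gene)
  } else ref <- reference
  if (!length(ref)) stop("reference gene set is empty")
  m_total <- sum(nchar(ref))

  # reference k-mer index over both strands
  idx_list <- lapply(names(ref), function(g) {
    r <- ref[[g]]
    n <- nchar(r)
    if (n < k) return(NULL)
    fwd <- substring(r, 1:(n - k + 1L), k:n)
    rc <- revcomp(r)
    rcs <- substring(rc, 1:(n - k + 1L), k:n)
    data.frame(kmer = c(fwd, rcs), gene = g,
               pos = c(seq_along(fwd), seq_along(rcs)),
               strand = rep(c("+", "-"), times = c(length(fwd), length(rcs))),
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, idx_list)
  kmap <- split(seq_len(nrow(idx)), idx$kmer)

  hits <- list()
  for (sid in names(subjects)) {
    s <- subjects[[sid]]
    n <- nchar(s)
    if (n < k) next
    s_chars <- strsplit(s, "")[[1]]
    skmers <- substring(s, 1:(n - k + 1L), k:n)
    hit_pos <- match(skmers, names(kmap))
    seeds_i <- which(!is.na(hit_pos))
    if (!length(seeds_i)) next
    rows_list <- kmap[hit_pos[seeds_i]]
    pairs <- data.frame(
      i = rep(seeds_i, lengths(rows_list)),
      gene = idx$gene[unlist(rows_list)],
      j = idx$pos[unlist(rows_list)],
      strand = idx$strand[unlist(rows_list)],
      stringsAsFactors = FALSE)
    pairs$diag <- pairs$i - pairs$j
    key <- paste(pairs$gene, pairs$strand, pairs$diag)
    for (grp_rows in split(seq_len(nrow(pairs)), key)) {
      p <- pairs[grp_rows, ]
      p <- p[order(p$i), ]
      g <- p$gene[1]; strand <- p$strand[1]
      r_seq <- if (strand == "+") ref[[g]] else revcomp(ref[[g]])
      r_chars <- strsplit(r_seq, "")[[1]]
      # chain anchors separated by <= join_gap
      brk <- c(TRUE, p$i[-1] > p$i[-nrow(p)] + k - 1L + join_gap)
      seg_id <- cumsum(brk)
      for (sg in unique(seg_id)) {
        q <- p[seg_id == sg, ]
        i1 <- q$i[1]; i2 <- q$i[nrow(q)] + k - 1L
        j1 <- q$j[1]
        ext <- extend_seed(s_chars, r_chars, i1, i2, j1)
        a <- ext[1]; b <- ext[2]
        jj1 <- j1 - (i1 - a); jj2 <- jj1 + (b - a)
        len <- b - a + 1L
        matches <- sum(s_chars[a:b] == r_chars[jj1:jj2])
        mm <- len - matches
        sc <- matches - 2L * mm
        ev <- ka_evalue(sc, m_total, n)
        if (ev < cutoff) {
          # map minus-strand reference coords back to forward gene coords
          if (strand == "+") { qs <- jj1; qe <- jj2 }
          else {
            mlen <- nchar(ref[[g]])
            qs <- mlen - jj2 + 1L; qe <- mlen - jj1 + 1L
          }
          hits[[length(hits) + 1L]] <- data.frame(
            gene = g, seqid = sid, sstart = a, send = b,
            qstart = qs, qend = qe, strand = strand, length = len,
            identity = matches / len, mismatches = mm, score = sc,
            evalue = ev, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(gene = character(0), seqid = character(0),
                      sstart = integer(0), send = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), mismatches = integer(0),
                      score = numeric(0), evalue = numeric(0)))
  }
  out <- do.call(rbind, hits)
  # merge nearby same-gene same-strand hits on a replicon (split anchors of
  # one insertion), then order deterministically
  out <- merge_hits(out, subjects, ref, m_total, join_gap)
  out <- out[order(match(out$seqid, names(subjects)), out$sstart, out$gene), ]
  rownames(out) <- NULL
  out
}

merge_hits <- function(hits, subjects, ref, m_total, join_gap) {
  key <- paste(hits$gene, hits$seqid, hits$strand)
  merged <- lapply(unique(key), function(kk) {
    h <- hits[key == kk, ]
    h <- h[order(h$sstart), ]
    brk <- c(TRUE, h$sstart[-1] > h$send[-nrow(h)] + join_gap)
    grp <- cumsum(brk)
    do.call(rbind, lapply(unique(grp), function(g) {
      hh <- h[grp == g, ]
      if (nrow(hh) == 1L) return(hh)
      a <- min(hh$sstart); b <- max(hh$send)
      s_chars <- strsplit(substr(subjects[[hh$seqid[1]]], a, b), "")[[1]]
      gene <- hh$gene[1]
      qs <- min(hh$qstart); qe <- max(hh$qend)
      r_span <- substr(ref[[gene]], qs, qe)
      if (hh$strand[1] == "-") r_span <- revcomp(r_span)
      r_chars <- strsplit(r_span, "")[[1]]
      len <- b - a + 1L
      cmp_len <- min(len, length(r_chars))
      matches <- sum(s_chars[seq_len(cmp_len)] == r_chars[seq_len(cmp_len)])
      mm <- cmp_len - matches
      sc <- matches - 2L * mm
      data.frame(gene = gene, seqid = hh$seqid[1], sstart = a, send = b,
                 qstart = qs, qend = qe, strand = hh$strand[1], length = len,
                 identity = matches / cmp_len, mismatches = mm, score = sc,
                 evalue = ka_evalue(sc, m_total, nchar(subjects[[hh$seqid[1]]])),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, merged)
}

#' Assess whether a fragment carries a complete ORF of its reference CDS
#'
#' A fragment is complete only if it contains the reference's full CDS span
#' with an intact ATG start, a terminal stop codon, and no frame-breaking
#' internal stop.
#'
#' @param fragment Nucleotide sequence of the fragment.
#' @param reference Reference CDS sequence.
#' @param type `"protein"` for a coding reference; anything else returns a
#'   not-applicable flag.
#' @return List with `complete` (logical, `NA` for non-coding references)
#'   and `reason` (`complete`, `too_short`, `missing_start`,
#'   `missing_stop`, `internal_stop`, `not_applicable`).
#' @export
check_orf_completeness <- function(fragment, reference, type = "protein") {
  if (type != "protein") {
    return(list(complete = NA, reason = "not_applicable"))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(fragment), Biostrings::DNAString(reference),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  if (BiocGenerics::start(Biostrings::subject(aln)) > 1L ||
      BiocGenerics::end(Biostrings::subject(aln)) < nchar(reference)) {
    return(list(complete = FALSE, reason = "too_short"))
  }
  cds <- substr(fragment, BiocGenerics::start(Biostrings::pattern(aln)),
                BiocGenerics::end(Biostrings::pattern(aln)))
  if (substr(cds, 1, 3) != "ATG") {
    return(list(complete = FALSE, reason = "missing_start"))
  }
  aa <- translate_nt(cds)
  if (!endsWith(aa, "*")) {
    return(list(complete = FALSE, reason = "missing_stop"))
  }
  if (grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE)) {
    return(list(complete = FALSE, reason = "internal_stop"))
  }
  list(complete = TRUE, reason = "complete")
}

#' Collect homology hits into transfer fragments with ORF assessment
#'
#' Copy indices distinguish multiple fragments of the same gene and are
#' assigned in subject-coordinate order.
#'
#' @param hits Hit data frame from [scan_homology()] (already chained).
#' @param subjects The scanned replicon sequences.
#' @param reference Reference gene catalog data frame (`gene`, `type`,
#'   `sequence`).
#' @return Data frame of transfer fragments: `gene`, `copy`, `seqid`,
#'   `sstart`, `send`, `length`, `identity`, `orf_complete`, `orf_reason`.
#' @export
transfer_fragments <- function(hits, subjects, reference) {
  if (methods::is(subjects, "DNAStringSet")) {
    subjects <- stats::setNames(as.character(subjects), names(subjects))
  }
  if (!nrow(hits)) {
    return(data.frame(gene = character(0), copy = integer(0),
                      seqid = character(0), sstart = integer(0),
                      send = integer(0), length = integer(0),
                      identity = numeric(0), orf_complete = logical(0),
                      orf_reason = character(0)))
  }
  hits <- hits[order(match(hits$seqid, names(subjects)), hits$sstart), ]
  hits$copy <- stats::ave(seq_len(nrow(hits)), hits$gene, FUN = seq_along)
  orf <- lapply(seq_len(nrow(hits)), function(i) {
    frag <- substr(subjects[[hits$seqid[i]]], hits$sstart[i], hits$send[i])
    if (hits$strand[i] == "-") frag <- revcomp(frag)
    ri <- match(hits$gene[i], reference$gene)
    check_orf_completeness(frag, reference$sequence[ri],
                           type = reference$type[ri])
  })
  out <- data.frame(
    gene = hits$gene, copy = as.integer(hits$copy), seqid = hits$seqid,
    sstart = hits$sstart, send = hits$send, length = hits$length,
    identity = hits$identity,
    orf_complete = vapply(orf, function(x) isTRUE(x$complete), logical(1)),
    orf_reason = vapply(orf, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read / write homology hits in 12-column BLAST tabular format
#'
#' The standard `outfmt 6` columns (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore). Both
#' paths produce and consume the same hit data frame as [scan_homology()];
#' minus-strand hits are encoded with reversed subject coordinates, as
#' BLAST does.
#'
#' @param path File path.
#' @param hits Hit data frame (for writing).
#' @return A hit data frame ([read_blast6()]) or `path` invisibly
#'   ([write_blast6()]).
#' @export
read_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  strand <- ifelse(df$sstart <= df$send, "+", "-")
  data.frame(
    gene = df$qseqid, seqid = df$sseqid,
    sstart = pmin(df$sstart, df$send), send = pmax(df$sstart, df$send),
    qstart = df$qstart, qend = df$qend, strand = strand,
    length = df$length, identity = df$pident / 100,
    mismatches = df$mismatch, score = df$bitscore, evalue = df$evalue,
    stringsAsFactors = FALSE)
}

#' @rdname read_blast6
#' @export
write_blast6 <- function(hits, path) {
  sstart <- ifelse(hits$strand == "-", hits$send, hits$sstart)
  send <- ifelse(hits$strand == "-", hits$sstart, hits$send)
  df <- data.frame(hits$gene, hits$seqid, round(hits$identity * 100, 3),
                   hits$length, hits$mismatches, 0L, hits$qstart, hits$qend,
                   sstart, send, format(hits$evalue, digits = 3),
                   hits$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
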