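# Quadripartite plastome architecture: inverted-repeat detection and
# region-size comparisons.

#' Construct a plastome partition
#'
#' Intervals are 0-based half-open on the circle linearized at the LSC
#' start. The two inverted repeats must have equal length, the four regions
#' tile the circle, and LSC is by convention the longer single-copy arc.
#'
#' @param lsc,ssc,ir Region lengths in bp (`ir` is the length of each
#'   repeat copy).
#' @param origin Position (0-based) of the LSC start on the input sequence.
#' @return An object of class `plastome_partition` with elements
#'   `total_len`, `origin`, and the four intervals `lsc`, `ira`, `ssc`,
#'   `irb` (each `c(start, end)`, half-open).
#' @export
plastome_partition <- function(lsc, ssc, ir, origin = 0L) {
  stopifnot(lsc >= 0, ssc >= 0, ir >= 0, lsc >= ssc)
  total <- lsc + ssc + 2L * ir
  p <- list(total_len = as.integer(total), origin = as.integer(origin),
            lsc = c(0L, as.integer(lsc)),
            ira = c(as.integer(lsc), as.integer(lsc + ir)),
            ssc = c(as.integer(lsc + ir), as.integer(lsc + ir + ssc)),
            irb = c(as.integer(lsc + ir + ssc), as.integer(total)))
  class(p) <- "plastome_partition"
  p
}

#' Region lengths of a partition
#'
#' @param partition A `plastome_partition`.
#' @return Named integer vector `lsc`, `ssc`, `ira`, `irb`.
#' @export
region_lengths <- function(partition) {
  c(lsc = diff(partition$lsc), ssc = diff(partition$ssc),
    ira = diff(partition$ira), irb = diff(partition$irb))
}

#' @export
print.plastome_partition <- function(x, ...) {
  rl <- region_lengths(x)
  cat("Quadripartite plastome partition (", x$total_len, " bp):\n",
      "  LSC ", rl["lsc"], " bp | SSC ", rl["ssc"], " bp | IR ",
      rl["ira"], " bp x 2 | origin at ", x$origin, "\n", sep = "")
  invisible(x)
}

#' Detect the quadripartite architecture of a circular plastome
#'
#' Finds the maximal pair of disjoint segments on the circle where one is
#' the (near-)reverse complement of the other: exact k-mer anchors between
#' the doubled sequence and its reverse complement are grouped by diagonal,
#' the longest run is extended greedily (X-drop through mismatches when
#' `min_identity < 1`, exact otherwise), and the two remaining arcs become
#' LSC (the longer) and SSC. When no repeat of at least `min_len` exists,
#' the partition degenerates to a single LSC spanning the whole molecule.
#'
#' @param seq Circular nucleotide sequence (character).
#' @param min_len Minimum repeat length to accept (default 1,000 bp).
#' @param min_identity Minimum identity of the repeat pair (default 0.99).
#' @param k Anchor length (default 21).
#' @return A [plastome_partition()]; region lengths always sum to the
#'   sequence length, and are invariant to rotation and reverse
#'   complementation of the input.
#' @export
find_inverted_repeats <- function(seq, min_len = 1000L, min_identity = 0.99,
                                  k = 21L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  degenerate <- plastome_partition(lsc = n, ssc = 0L, ir = 0L, origin = 0L)
  if (n < 2L * k) return(degenerate)
  half <- n %/% 2L

  s2 <- paste0(seq, seq)
  rc2 <- revcomp(s2)
  n2 <- nchar(s2)
  fwd <- substring(s2, 1:(n2 - k + 1L), k:n2)
  rck <- substring(rc2, 1:(n2 - k + 1L), k:n2)
  kmap <- split(seq_along(rck), rck)
  hit <- match(fwd, names(kmap))
  seeds_i <- which(!is.na(hit))
  if (!length(seeds_i)) return(degenerate)
  rows_list <- kmap[hit[seeds_i]]
  pairs <- cbind(i = rep(seeds_i, lengths(rows_list)),
                 j = unlist(rows_list, use.names = FALSE))
  # map rc2 anchor j back to forward coordinates of s2: the k-mer at rc2
  # position j covers s2 positions (n2 - j - k + 2) .. (n2 - j + 1)

  s_chars <- strsplit(s2, "")[[1]]
  r_chars <- strsplit(rc2, "")[[1]]

  diag <- pairs[, "i"] - pairs[, "j"]
  best <- NULL
  for (d in unique(diag)) {
    ii <- sort(pairs[diag == d, "i"])
    brk <- c(TRUE, diff(ii) > 1L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      run <- ii[grp == g]
      i1 <- run[1]; i2 <- run[length(run)] + k - 1L
      j1 <- i1 - d
      if (min_identity < 1) {
        ext <- extend_seed(s_chars, r_chars, i1, i2, j1, xdrop = 20L)
        i1 <- ext[1]; i2 <- ext[2]; j1 <- i1 - d
      }
      L <- i2 - i1 + 1L
      if (L > n) { i2 <- i1 + n - 1L; L <- n }
      j2 <- j1 + L - 1L
      # forward coordinates (on s2) of the partner segment
      p1 <- n2 - j2 - k + 1L + k      # = n2 - j2 + 1
      # circle coordinates, 1-based starts
      a_start <- ((i1 - 1L) %% n) + 1L
      b_start <- ((p1 - 1L) %% n) + 1L
      matches <- sum(s_chars[i1:i2] == r_chars[j1:j2])
      ident <- matches / L
      if (L >= min_len && ident >= min_identity && L <= half) {
        # disjointness on the circle
        occ_a <- (seq.int(a_start - 1L, length.out = L)) %% n
        occ_b <- (seq.int(b_start - 1L, length.out = L)) %% n
        if (!length(intersect(occ_a, occ_b))) {
          cand <- list(len = L, a = a_start, b = b_start, identity = ident)
          if (is.null(best) || cand$len > best$len ||
              (cand$len == best$len && cand$a < best$a)) {
            best <- cand
          }
        }
      }
    }
  }
  if (is.null(best)) return(degenerate)

  # arcs between the two repeat copies (0-based circle positions)
  a0 <- best$a - 1L; b0 <- best$b - 1L; L <- best$len
  first <- min(a0, b0); second <- max(a0, b0)
  arc1 <- (second - (first + L)) %% n          # between copy1 end and copy2
  arc2 <- (n - 2L * L - arc1)                  # remaining arc
  if (arc1 >= arc2) {
    lsc_len <- arc1; ssc_len <- arc2
    lsc_start <- (first + L) %% n
  } else {
    lsc_len <- arc2; ssc_len <- arc1
    lsc_start <- (second + L) %% n
  }
  plastome_partition(lsc = lsc_len, ssc = ssc_len, ir = L,
                     origin = lsc_start)
}

#' Signed percent change of a region between two partitions
#'
#' @param a Baseline partition.
#' @param b Target partition.
#' @param region One of `"LSC"`, `"SSC"`, `"IR"`, `"total"`.
#' @return Signed percent change `100 * (|b| - |a|) / |a|`, rounded to one
#'   decimal; `NA` (flagged by a warning) when the baseline region has zero
#'   length.
#' @export
region_change_pct <- function(a, b, region = c("LSC", "SSC", "IR", "total")) {
  region <- match.arg(region)
  pick <- function(p) {
    rl <- region_lengths(p)
    switch(region, LSC = rl[["lsc"]], SSC = rl[["ssc"]], IR = rl[["ira"]],
           total = p$total_len)
  }
  base <- pick(a); target <- pick(b)
  if (base == 0) {
    warning("zero-length baseline region; change undefined")
    return(NA_real_)
  }
  round(100 * (target - base) / base, 1)
}
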