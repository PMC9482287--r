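#' Fixture specifications for synthetic organelle genomes
#'
#' A fixture spec bundles everything the generators need: the random seed,
#' the quadripartite region lengths, the per-gene status map, placement of
#' genes into regions, the planted plastid-to-mitochondrion transfers, and
#' the per-site mutation rate applied to planted material.
#'
#' @param seed Integer random seed.
#' @param regions Named numeric vector with elements `lsc`, `ssc`, `ir`
#'   (both inverted repeats share the `ir` length).
#' @param gene_statuses Named character vector over the reference roster,
#'   values in `intact`, `pseudogene`, `lost`.
#' @param ir_genes,ssc_genes Gene symbols placed in the inverted repeats /
#'   the small single copy; everything else present goes to the LSC.
#' @param irb_genes Gene symbols for the second IR copy; defaults to
#'   `ir_genes` and must equal it (a gene placed across the two copies
#'   inconsistently is rejected).
#' @param chromosomes Named integer vector of mitochondrial chromosome
#'   lengths (mitogenome specs).
#' @param local_genes Named list: chromosome -> character vector of local
#'   mitochondrial gene symbols (mitogenome specs).
#' @param transfers Data frame of planted transfers with columns `gene`,
#'   `donor`, `ref_start`, `length`, `chrom` (mitogenome specs).
#' @param mutation_rate Per-site substitution rate applied to planted genes
#'   and fragments (default 0).
#' @return An object of class `fixture_spec`.
#' @seealso [ck_plastome_spec()], [ck_mitogenome_spec()],
#'   [make_plastome_fixture()], [make_mitogenome_fixture()]
#' @export
fixture_spec <- function(seed = 1L, regions = NULL, gene_statuses = NULL,
                         ir_genes = character(0), ssc_genes = character(0),
                         irb_genes = NULL, chromosomes = NULL,
                         local_genes = NULL, transfers = NULL,
                         mutation_rate = 0) {
  spec <- list(seed = as.integer(seed), regions = regions,
               gene_statuses = gene_statuses, ir_genes = ir_genes,
               ssc_genes = ssc_genes, irb_genes = irb_genes %||% ir_genes,
               chromosomes = chromosomes, local_genes = local_genes,
               transfers = transfers, mutation_rate = mutation_rate)
  class(spec) <- "fixture_spec"
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  if (!is.null(spec$regions)) {
    if (any(spec$regions < 0)) stop("region lengths must be positive")
  }
  if (!is.null(spec$gene_statuses)) {
    bad <- setdiff(unique(spec$gene_statuses),
                   c("intact", "pseudogene", "lost"))
    if (length(bad)) stop("unknown gene status: ", paste(bad, collapse = ", "))
  }
  if (!setequal(spec$ir_genes, spec$irb_genes)) {
    stop("genes placed inconsistently across the two inverted-repeat copies: ",
         paste(union(setdiff(spec$ir_genes, spec$irb_genes),
                     setdiff(spec$irb_genes, spec$ir_genes)), collapse = ", "))
  }
  if (!is.null(spec$transfers) && !is.null(spec$chromosomes)) {
    too_long <- spec$transfers$length >
      spec$chromosomes[spec$transfers$chrom]
    if (any(too_long)) {
      stop("planted fragment longer than its chromosome: ",
           paste(spec$transfers$gene[too_long], collapse = ", "))
    }
  }
  if (spec$mutation_rate < 0 || spec$mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  invisible(spec)
}

# C. kwangtungensis-like study conditions ----------------------------------

ck_gene_statuses <- function() {
  roster <- plastid_roster()
  status <- stats::setNames(rep("intact", length(roster)), roster)
  pseudo <- c("rps16", "psbI", "rpoB", "psbD", "atpE", "petB", "rpoA",
              "rpl23", "ycf15", "ndhB", "rps15")
  lost <- c(paste0("psa", c("A", "B", "C", "I", "J")),
            paste0("psb", c("B", "C", "E", "F", "H", "J", "K", "L", "M",
                            "N", "T", "Z")),
            paste0("pet", c("A", "D", "G", "L", "N")),
            paste0("ndh", c("A", "C", "D", "E", "F", "G", "H", "I", "J", "K")),
            "rpoC1", "rpoC2", "rbcL", "ycf3", "ycf4", "ccsA", "cemA", "trnV")
  status[pseudo] <- "pseudogene"
  status[lost] <- "lost"
  status
}

#' Plastome fixture spec with the study's region lengths and gene statuses
#'
#' Encodes a degraded holoparasite plastome: LSC 30,072 bp, SSC 480 bp, two
#' 32,761 bp inverted repeats (total 96,074 bp); 68 intact gene copies and
#' the 11 named pseudogenes; 40 reference genes absent.
#'
#' @param seed Integer random seed.
#' @param mutation_rate Per-site substitution rate for planted genes.
#' @return A [fixture_spec()].
#' @export
ck_plastome_spec <- function(seed = 1L, mutation_rate = 0) {
  fixture_spec(
    seed = seed,
    regions = c(lsc = 30072L, ssc = 480L, ir = 32761L),
    gene_statuses = ck_gene_statuses(),
    ir_genes = c("trnI", "trnA", "trnN", "trnR",
                 "rrn16", "rrn23", "rrn4.5", "rrn5"),
    ssc_genes = "rpl32",
    mutation_rate = mutation_rate)
}

ck_transfers <- function() {
  data.frame(
    gene = c("rpl20", "rpoB", "ndhB", "ycf2", "ycf15",
             "petB", "rpl14", "rpl16", "ycf2"),
    donor = c("Lamiales", "Lamiales", "Lamiales", "Orchidaceae", "unknown",
              "Lamiales", "Gentianaceae", "Gentianaceae", "unknown"),
    ref_start = c(31L, 31L, 101L, 101L, 46L, 61L, 16L, 25L, 1501L),
    length = c(300L, 600L, 550L, 700L, 90L, 500L, 340L, 360L, 80L),
    chrom = c("mt1", "mt2", "mt2", "mt2", "mt2",
              "mt3", "mt3", "mt3", "mt3"),
    stringsAsFactors = FALSE)
}

ck_local_genes <- function() {
  ref <- reference_mito_catalog()
  pc_present <- setdiff(ref$gene[ref$type == "protein"],
                        c("rps2", "rps11", "rps19"))
  trn <- ref$gene[ref$class == "trn"]
  list(
    mt1 = c(pc_present[1:4], trn[1:3], "rrn5", "rrn18"),
    mt2 = c(pc_present[5:20], trn[4:10],
            "rrn5", "rrn18", "rrn26", "rrn5", "rrn18"),
    mt3 = c(pc_present[21:39], trn[11:26], "rrn5", "rrn18", "rrn26"))
}

#' Mitogenome fixture spec with three chromosomes and nine planted transfers
#'
#' Three circular chromosomes of 87,933, 303,254 and 241,909 bp carrying 75
#' local genes (39 protein-coding, 26 tRNA, 10 rRNA, split 9/28/38) and nine
#' planted plastid-derived fragments of eight genes (ycf2 twice), all with
#' incomplete ORFs.
#'
#' @inheritParams ck_plastome_spec
#' @return A [fixture_spec()].
#' @export
ck_mitogenome_spec <- function(seed = 1L, mutation_rate = 0) {
  fixture_spec(
    seed = seed,
    chromosomes = c(mt1 = 87933L, mt2 = 303254L, mt3 = 241909L),
    local_genes = ck_local_genes(),
    transfers = ck_transfers(),
    mutation_rate = mutation_rate)
}

# Sequence assembly helpers -------------------------------------------------

mutate_seq <- function(s, rate) {
  if (rate <= 0 || !nchar(s)) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1)
  paste(v, collapse = "")
}

# Apply a planted pseudogene defect. Returns list(seq, gene_len, defect):
# the allocated span always keeps the reference length (the truncated tail
# becomes intergenic filler) so region budgets stay exact.
plant_defect <- function(ref_seq, type, gc) {
  n <- nchar(ref_seq)
  if (type == "protein" && stats::runif(1) < 0.5) {
    n_cod <- n %/% 3L
    at <- sample(seq(max(2L, floor(0.1 * n_cod)), floor(0.6 * n_cod)), 1)
    s <- ref_seq
    substr(s, (at - 1L) * 3L + 1L, at * 3L) <- "TAA"
    list(seq = s, gene_len = n, defect = "internal_stop")
  } else {
    keep <- max(3L, 3L * floor(0.4 * n / 3L))
    filler <- random_dna(n - keep, gc)
    list(seq = paste0(substr(ref_seq, 1, keep), filler),
         gene_len = keep, defect = "truncation")
  }
}

# Lay out genes in one region: returns list(seq, ann) where ann has
# region-local 1-based coordinates for the annotated portion of each gene.
layout_region <- function(genes, ref, length_bp, gc, mutation_rate,
                          statuses) {
  if (!length(genes)) {
    return(list(seq = random_dna(length_bp, gc),
                ann = data.frame(gene = character(0), start = integer(0),
                                 end = integer(0), strand = character(0),
                                 status = character(0), defect = character(0),
                                 stringsAsFactors = FALSE)))
  }
  idx <- match(genes, ref$gene)
  stopifnot(!anyNA(idx))
  alloc <- integer(length(genes))
  pieces <- character(length(genes))
  gene_len <- integer(length(genes))
  defect <- character(length(genes))
  strand <- sample(c("+", "-"), length(genes), replace = TRUE)
  for (i in seq_along(genes)) {
    rs <- ref$sequence[idx[i]]
    if (statuses[genes[i]] == "pseudogene") {
      d <- plant_defect(rs, ref$type[idx[i]], gc)
      pieces[i] <- d$seq; gene_len[i] <- d$gene_len; defect[i] <- d$defect
    } else {
      pieces[i] <- rs; gene_len[i] <- nchar(rs); defect[i] <- "none"
    }
    pieces[i] <- mutate_seq(pieces[i], mutation_rate)
    alloc[i] <- nchar(pieces[i])
  }
  filler_total <- length_bp - sum(alloc)
  if (filler_total < length(genes) + 1L) {
    stop("region of ", length_bp, " bp cannot hold ", sum(alloc),
         " bp of genes plus spacers")
  }
  spacers <- split_filler(filler_total, length(genes) + 1L)
  seq_parts <- character(2L * length(genes) + 1L)
  ann <- data.frame(gene = genes, start = NA_integer_, end = NA_integer_,
                    strand = strand, status = unname(statuses[genes]),
                    defect = defect, stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_along(genes)) {
    seq_parts[2L * i - 1L] <- random_dna(spacers[i], gc)
    pos <- pos + spacers[i]
    placed <- if (strand[i] == "-") revcomp(pieces[i]) else pieces[i]
    seq_parts[2L * i] <- placed
    # annotate only the genic prefix (suffix of the span on minus strand)
    if (strand[i] == "+") {
      ann$start[i] <- pos + 1L
      ann$end[i] <- pos + gene_len[i]
    } else {
      ann$end[i] <- pos + alloc[i]
      ann$start[i] <- pos + alloc[i] - gene_len[i] + 1L
    }
    pos <- pos + alloc[i]
  }
  seq_parts[2L * length(genes) + 1L] <- random_dna(spacers[length(genes) + 1L], gc)
  list(seq = paste(seq_parts, collapse = ""), ann = ann)
}

#' Generate a circular quadripartite plastome fixture
#'
#' Builds a circular sequence of length `lsc + ssc + 2 * ir`, linearized in
#' LSC, IRa, SSC, IRb order, in which IRb is the exact reverse complement of
#' IRa. Genes marked `pseudogene` in the spec carry a planted defect (an
#' internal stop codon at a seeded position in 10-60% of the CDS, or
#' truncation to 40% of the reference length); genes marked `lost` have no
#' homologous segment anywhere. The bases flanking the IR boundaries are
#' adjusted so the repeat pair cannot be extended by chance, keeping the
#' planted region lengths exactly recoverable.
#'
#' @param spec A [fixture_spec()] with `regions` and `gene_statuses`.
#' @return A list with elements `sequence` (character), `catalog` (gene
#'   catalog data frame with planted truth in `status`/`defect`), `regions`
#'   (named lengths) and `spec`.
#' @export
make_plastome_fixture <- function(spec) {
  validate_fixture_spec(spec)
  stopifnot(!is.null(spec$regions), !is.null(spec$gene_statuses))
  ref <- reference_plastid_catalog()
  statuses <- spec$gene_statuses
  present <- names(statuses)[statuses != "lost"]
  ir_genes <- intersect(spec$ir_genes, present)
  ssc_genes <- intersect(spec$ssc_genes, present)
  lsc_genes <- setdiff(present, c(ir_genes, ssc_genes))
  gc <- 0.35
  with_seed(spec$seed, {
    lsc <- layout_region(lsc_genes, ref, spec$regions[["lsc"]], gc,
                         spec$mutation_rate, statuses)
    ira <- layout_region(ir_genes, ref, spec$regions[["ir"]], gc,
                         spec$mutation_rate, statuses)
    ssc <- layout_region(ssc_genes, ref, spec$regions[["ssc"]], gc,
                         spec$mutation_rate, statuses)
    n_lsc <- spec$regions[["lsc"]]; n_ir <- spec$regions[["ir"]]
    n_ssc <- spec$regions[["ssc"]]
    irb_seq <- revcomp(ira$seq)
    seqs <- c(lsc$seq, ira$seq, ssc$seq, irb_seq)
    genome <- paste(seqs, collapse = "")
    # break complementarity in a window just outside the repeat pair so
    # greedy X-drop extension is guaranteed to stop exactly at the planted
    # boundaries (enough consecutive mismatches to exceed any drop budget)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    fix_pair <- function(g, outer_pos, inner_pos) {
      if (substr(g, outer_pos, outer_pos) ==
          comp[[substr(g, inner_pos, inner_pos)]]) {
        substr(g, outer_pos, outer_pos) <- substr(g, inner_pos, inner_pos)
      }
      g
    }
    n <- nchar(genome)
    w <- 12L
    # wrap side: base 1+t of the LSC pairs with base n_lsc-t during
    # outward extension of the repeat pair
    for (t in 0:min(w - 1L, n_lsc %/% 2L - 1L)) {
      genome <- fix_pair(genome, 1L + t, n_lsc - t)
    }
    # inner side: the SSC flanks pair with each other
    for (t in 0:min(w - 1L, (n_ssc - 2L) %/% 2L)) {
      genome <- fix_pair(genome, n_lsc + n_ir + n_ssc - t,
                         n_lsc + n_ir + 1L + t)
    }
    # global coordinates
    glob <- function(ann, offset, seqid, region, copy = 1L) {
      if (!nrow(ann)) return(NULL)
      data.frame(seqid = seqid, start = ann$start + offset,
                 end = ann$end + offset, strand = ann$strand,
                 gene = ann$gene, region = region, copy = copy,
                 status = ann$status, defect = ann$defect,
                 stringsAsFactors = FALSE)
    }
    ann_lsc <- glob(lsc$ann, 0L, "plastome", "LSC")
    ann_ira <- glob(ira$ann, n_lsc, "plastome", "IRa")
    ann_ssc <- glob(ssc$ann, n_lsc + n_ir, "plastome", "SSC")
    # IRb annotations mirror IRa
    ann_irb <- NULL
    if (nrow(ira$ann)) {
      off <- n_lsc + n_ir + n_ssc
      ann_irb <- data.frame(
        seqid = "plastome",
        start = off + n_ir - ira$ann$end + 1L,
        end = off + n_ir - ira$ann$start + 1L,
        strand = ifelse(ira$ann$strand == "+", "-", "+"),
        gene = ira$ann$gene, region = "IRb", copy = 2L,
        status = ira$ann$status, defect = ira$ann$defect,
        stringsAsFactors = FALSE)
    }
    catalog <- rbind(ann_lsc, ann_ira, ann_ssc, ann_irb)
    catalog <- catalog[order(catalog$start), ]
    rownames(catalog) <- NULL
    catalog$category <- gene_category(catalog$gene)
    catalog$type <- ifelse(catalog$category %in% c("trn", "rrn"),
                           "rna", "protein")
    catalog <- extract_gene_sequences(catalog, c(plastome = genome))
    list(sequence = genome, catalog = catalog,
         regions = c(lsc = n_lsc, ssc = n_ssc, ira = n_ir, irb = n_ir),
         spec = spec)
  })
}

#' Generate a multi-chromosome mitogenome fixture with planted transfers
#'
#' Each chromosome carries its local mitochondrial genes (sequences from the
#' mitochondrial reference catalog) and the planted plastid-derived
#' fragments listed in the spec, embedded verbatim (optionally mutated at
#' the spec's per-site rate) at recorded coordinates, separated by random
#' filler at mitochondrial GC content.
#'
#' @param spec A [fixture_spec()] with `chromosomes`, `local_genes` and
#'   `transfers`.
#' @return A list with elements `sequences` (named character vector),
#'   `catalog` (local genes, `feature == "gene"`), `transfers` (planted
#'   fragments with coordinates, `feature == "mipt"`), and `spec`.
#' @export
make_mitogenome_fixture <- function(spec) {
  validate_fixture_spec(spec)
  stopifnot(!is.null(spec$chromosomes), !is.null(spec$local_genes))
  mref <- reference_mito_catalog()
  pref <- reference_plastid_catalog()
  transfers <- spec$transfers
  gc <- 0.44
  with_seed(spec$seed, {
    seqs <- character(0)
    cat_rows <- list()
    mipt_rows <- list()
    copy_counter <- new.env(parent = emptyenv())
    next_copy <- function(key) {
      k <- get0(key, envir = copy_counter, ifnotfound = 0L) + 1L
      assign(key, k, envir = copy_counter)
      k
    }
    for (chrom in names(spec$chromosomes)) {
      genes <- spec$local_genes[[chrom]]
      tr <- if (!is.null(transfers)) transfers[transfers$chrom == chrom, ]
            else transfers
      items <- data.frame(
        name = c(genes, if (!is.null(tr)) tr$gene),
        feature = c(rep("gene", length(genes)),
                    rep("mipt", if (is.null(tr)) 0 else nrow(tr))),
        idx = c(seq_along(genes), if (is.null(tr)) integer(0)
                else seq_len(nrow(tr))),
        stringsAsFactors = FALSE)
      items <- items[sample.int(nrow(items)), ]
      pieces <- character(nrow(items))
      for (i in seq_len(nrow(items))) {
        if (items$feature[i] == "gene") {
          pieces[i] <- mref$sequence[match(items$name[i], mref$gene)]
        } else {
          r <- tr[items$idx[i], ]
          full <- pref$sequence[match(r$gene, pref$gene)]
          pieces[i] <- substr(full, r$ref_start, r$ref_start + r$length - 1L)
        }
        pieces[i] <- mutate_seq(pieces[i], spec$mutation_rate)
      }
      alloc <- nchar(pieces)
      total <- spec$chromosomes[[chrom]]
      if (total - sum(alloc) < nrow(items) + 1L) {
        stop("chromosome ", chrom, " too short for its genes")
      }
      spacers <- split_filler(total - sum(alloc), nrow(items) + 1L)
      strand <- sample(c("+", "-"), nrow(items), replace = TRUE)
      parts <- character(2L * nrow(items) + 1L)
      pos <- 0L
      for (i in seq_len(nrow(items))) {
        parts[2L * i - 1L] <- random_dna(spacers[i], gc)
        pos <- pos + spacers[i]
        placed <- if (strand[i] == "-") revcomp(pieces[i]) else pieces[i]
        parts[2L * i] <- placed
        row <- data.frame(seqid = chrom, start = pos + 1L,
                          end = pos + alloc[i], strand = strand[i],
                          gene = items$name[i],
                          copy = next_copy(paste0(items$feature[i], ":",
                                                  items$name[i])),
                          feature = items$feature[i],
                          stringsAsFactors = FALSE)
        if (items$feature[i] == "gene") {
          cat_rows[[length(cat_rows) + 1L]] <- row
        } else {
          r <- tr[items$idx[i], ]
          row$donor <- r$donor
          row$ref_start <- r$ref_start
          row$length <- r$length
          mipt_rows[[length(mipt_rows) + 1L]] <- row
        }
        pos <- pos + alloc[i]
      }
      parts[2L * nrow(items) + 1L] <- random_dna(spacers[nrow(items) + 1L], gc)
      chrom_seq <- paste(parts, collapse = "")
      # break chance homology in an 8 bp window at planted-fragment flanks
      # so an X-drop scan at mutation rate 0 recovers the planted
      # coordinates exactly (the mismatch run exhausts the drop budget)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      fix_flank <- function(s, pos, forbidden) {
        if (is.na(forbidden) || pos < 1L || pos > nchar(s)) return(s)
        if (substr(s, pos, pos) == forbidden) {
          substr(s, pos, pos) <- comp[[forbidden]]
        }
        s
      }
      w <- 8L
      for (row in mipt_rows) {
        if (row$seqid != chrom) next
        r <- tr[tr$gene == row$gene & tr$ref_start == row$ref_start, ][1, ]
        full <- pref$sequence[match(r$gene, pref$gene)]
        m_len <- nchar(full)
        re <- min(r$ref_start + r$length - 1L, m_len)
        for (t in 1:w) {
          # continuation bases of the reference beyond the planted slice,
          # as they would appear next to the (possibly revcomped) insert
          before <- if (row$strand == "+") {
            if (r$ref_start - t >= 1L) substr(full, r$ref_start - t,
                                              r$ref_start - t) else NA
          } else {
            if (re + t <= m_len) comp[[substr(full, re + t, re + t)]] else NA
          }
          after <- if (row$strand == "+") {
            if (re + t <= m_len) substr(full, re + t, re + t) else NA
          } else {
            if (r$ref_start - t >= 1L) comp[[substr(full, r$ref_start - t,
                                                    r$ref_start - t)]] else NA
          }
          chrom_seq <- fix_flank(chrom_seq, row$start - t, before)
          chrom_seq <- fix_flank(chrom_seq, row$end + t, after)
        }
      }
      seqs[chrom] <- chrom_seq
    }
    catalog <- do.call(rbind, cat_rows)
    catalog <- catalog[order(match(catalog$seqid, names(spec$chromosomes)),
                             catalog$start), ]
    rownames(catalog) <- NULL
    catalog$category <- gene_category(catalog$gene)
    catalog$class <- mref$class[match(catalog$gene, mref$gene)]
    catalog$type <- ifelse(catalog$class %in% c("trn", "rrn"),
                           "rna", "protein")
    catalog <- extract_gene_sequences(catalog, seqs)
    planted <- if (length(mipt_rows)) {
      p <- do.call(rbind, mipt_rows)
      p <- p[order(match(p$seqid, names(spec$chromosomes)), p$start), ]
      rownames(p) <- NULL
      # copy indices in subject-coordinate order, per gene
      p$copy <- stats::ave(seq_len(nrow(p)), p$gene, FUN = seq_along)
      p
    } else NULL
    list(sequences = seqs, catalog = catalog, transfers = planted,
         spec = spec)
  })
}
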