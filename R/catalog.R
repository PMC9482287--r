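#' Gene catalogs and reference rosters
#'
#' A gene catalog is a data frame with one row per annotated gene copy,
#' carrying the columns `seqid`, `start`, `end` (1-based inclusive), `strand`,
#' `gene`, `category`, `type` (`protein` or `rna`), `copy` (copy index,
#' distinguishing inverted-repeat duplicates), and optionally `sequence`.
#'
#' @name gene_catalog
NULL

#' Functional category of a plastid or mitochondrial gene symbol
#'
#' Categories follow the field's controlled vocabulary: `psa`, `psb`, `pet`,
#' `ndh`, `rpo`, `atp`, `rbcL`, `rps`, `rpl`, `trn`, `rrn`, `ycf`, and
#' `other`; mitochondrial symbols additionally use `ccm`, `cob`, `cox`,
#' `nad`, `matR`, `mttB`, and `sdh`.
#'
#' @param gene Character vector of gene symbols.
#' @return Character vector of categories, same length as `gene`.
#' @examples
#' gene_category(c("psbA", "rpl32", "trnH", "nad4L"))
#' @export
gene_category <- function(gene) {
  pre <- function(p) startsWith(gene, p)
  out <- rep("other", length(gene))
  prefixes <- c("psa", "psb", "pet", "ndh", "rpo", "atp", "rps", "rpl",
                "trn", "rrn", "ycf", "ccm", "cob", "cox", "nad", "sdh")
  for (p in rev(prefixes)) out[pre(p)] <- p
  out[gene == "rbcL"] <- "rbcL"
  out[gene == "matR"] <- "matR"
  out[gene == "mttB"] <- "mttB"
  out
}

#' The 24 mitochondrial core genes
#'
#' The `atp`, `ccm`, `cob`, `cox` and `nad` genes plus `matR` and `mttB`,
#' which are nearly universal in angiosperm mitogenomes and whose retention
#' is checked by [check_core_retention()].
#'
#' @return Character vector of 24 gene symbols.
#' @export
mito_core_genes <- function() {
  c("atp1", "atp4", "atp6", "atp8", "atp9",
    "ccmB", "ccmC", "ccmFc", "ccmFn",
    "cob", "cox1", "cox2", "cox3",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad7", "nad9",
    "matR", "mttB")
}

# Gene symbol rosters ------------------------------------------------------

plastid_roster <- function() {
  genes <- c(
    paste0("psa", c("A", "B", "C", "I", "J")),
    paste0("psb", c("A", "B", "C", "D", "E", "F", "H", "I", "J", "K", "L",
                    "M", "N", "T", "Z")),
    paste0("pet", c("A", "B", "D", "G", "L", "N")),
    paste0("ndh", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K")),
    paste0("rpo", c("A", "B", "C1", "C2")),
    paste0("atp", c("A", "B", "E", "F", "H", "I")),
    "rbcL",
    paste0("rps", c("2", "3", "4", "7", "8", "11", "12", "14", "15", "16",
                    "18", "19")),
    paste0("rpl", c("2", "14", "16", "20", "22", "23", "32", "33")),
    paste0("ycf", c("1", "2", "3", "4", "15")),
    c("accD", "matK", "infA", "clpP", "ccsA", "cemA"),
    paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                    "fM", "L2", "S2", "S3", "G2", "R2", "I2", "M2")),
    paste0("rrn", c("16", "23", "4.5", "5"))
  )
  genes
}

# Reference CDS/gene lengths in bp; 300 bp unless overridden (real lengths
# are irrelevant to the classification logic; transferred genes get longer
# references so that sub-fragments of realistic sizes can be planted).
plastid_ref_lengths <- function() {
  len <- stats::setNames(rep(300L, length(plastid_roster())), plastid_roster())
  len[c("rpoB", "ndhB", "petB", "ycf2", "rpl20", "rpl14", "rpl16", "ycf15")] <-
    c(900L, 900L, 648L, 2100L, 360L, 369L, 408L, 180L)
  len
}

#' Reference plastid gene catalog (synthetic)
#'
#' A non-parasite-like reference roster of 111 plastid genes with seeded
#' synthetic sequences: protein-coding genes are clean ORFs (ATG start, no
#' internal stop, TAA terminator), tRNA/rRNA genes are plain nucleotide
#' strings. The same fixed internal seed is always used, so the reference is
#' identical across calls and shared by the plastome and mitogenome fixture
#' generators.
#'
#' @return A data frame with columns `gene`, `category`, `type`, `length`,
#'   `sequence`.
#' @export
reference_plastid_catalog <- function() {
  genes <- plastid_roster()
  lens <- plastid_ref_lengths()[genes]
  category <- gene_category(genes)
  type <- ifelse(category %in% c("trn", "rrn"), "rna", "protein")
  seqs <- with_seed(20220917, {
    vapply(seq_along(genes), function(i) {
      if (type[i] == "protein") random_cds(lens[i] / 3L)
      else random_dna(lens[i], gc = 0.5)
    }, character(1))
  })
  data.frame(gene = genes, category = category, type = type,
             length = as.integer(lens), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Reference mitochondrial gene catalog (synthetic)
#'
#' The 24 core genes plus the standard variable genes (ribosomal protein and
#' succinate dehydrogenase subunits), tRNAs and rRNAs, with seeded synthetic
#' sequences that are unrelated to the plastid reference so homology scans
#' cannot cross-hit.
#'
#' @return A data frame with columns `gene`, `category`, `class`
#'   (`core`/`variable`/`trn`/`rrn`), `type`, `length`, `sequence`.
#' @export
reference_mito_catalog <- function() {
  core <- mito_core_genes()
  variable <- c(paste0("rps", c("1", "2", "3", "4", "7", "10", "11", "12",
                                "13", "14", "19")),
                paste0("rpl", c("2", "5", "6", "10", "16")),
                "sdh3", "sdh4")
  trn <- paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                         "fM", "S2", "M2", "G2", "E2", "N2"))
  rrn <- c("rrn5", "rrn18", "rrn26")
  genes <- c(core, variable, trn, rrn)
  cls <- c(rep("core", length(core)), rep("variable", length(variable)),
           rep("trn", length(trn)), rep("rrn", length(rrn)))
  category <- gene_category(genes)
  type <- ifelse(cls %in% c("trn", "rrn"), "rna", "protein")
  seqs <- with_seed(20220918, {
    vapply(seq_along(genes), function(i) {
      if (type[i] == "protein") random_cds(100L) else random_dna(300L, gc = 0.44)
    }, character(1))
  })
  data.frame(gene = genes, category = category, class = cls, type = type,
             length = nchar(seqs), sequence = seqs, stringsAsFactors = FALSE)
}

# GFF3 / FASTA round-trip ---------------------------------------------------

#' Write a gene catalog as GFF3
#'
#' Coordinates are written 1-based inclusive; the gene symbol, category,
#' type and copy index travel in the attribute column so that
#' [read_gene_catalog()] recovers the catalog exactly.
#'
#' @param catalog Gene catalog data frame (see [gene_catalog]).
#' @param path Output file path.
#' @param seqlens Named integer vector of replicon lengths (optional,
#'   recorded as `##sequence-region` pragmas via the GRanges seqinfo).
#' @return `path`, invisibly.
#' @export
write_gene_catalog <- function(catalog, path, seqlens = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = catalog$seqid,
    ranges = IRanges::IRanges(start = catalog$start, end = catalog$end),
    strand = catalog$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- paste0(catalog$gene, "-", catalog$copy)
  S4Vectors::mcols(gr)$Name <- catalog$gene
  S4Vectors::mcols(gr)$gene_category <- catalog$category
  S4Vectors::mcols(gr)$gene_type <- catalog$type
  S4Vectors::mcols(gr)$copy_index <- as.character(catalog$copy)
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene catalog from GFF3
#'
#' @param path GFF3 file written by [write_gene_catalog()] (or any GFF3 whose
#'   gene features carry `Name` attributes).
#' @return A gene catalog data frame.
#' @export
read_gene_catalog <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  m <- S4Vectors::mcols(gr)
  name <- as.character(m$Name)
  category <- if (!is.null(m$gene_category)) as.character(m$gene_category)
              else gene_category(name)
  type <- if (!is.null(m$gene_type)) as.character(m$gene_type)
          else ifelse(category %in% c("trn", "rrn"), "rna", "protein")
  copy <- if (!is.null(m$copy_index)) as.integer(as.character(m$copy_index))
          else 1L
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene = name, category = category, type = type, copy = copy,
    stringsAsFactors = FALSE)
}

#' Extract annotated gene sequences from replicon sequences
#'
#' @param catalog Gene catalog data frame.
#' @param seqs Named character vector (or `DNAStringSet`) of replicon
#'   sequences keyed by `seqid`.
#' @return The catalog with a `sequence` column added; minus-strand genes are
#'   reverse-complemented.
#' @export
extract_gene_sequences <- function(catalog, seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  catalog$sequence <- vapply(seq_len(nrow(catalog)), function(i) {
    s <- substr(seqs[[catalog$seqid[i]]], catalog$start[i], catalog$end[i])
    if (catalog$strand[i] == "-") revcomp(s) else s
  }, character(1))
  catalog
}
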