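test_that("the fixture scan recovers all nine planted fragments exactly", {
  fr <- ck_fragments()
  expect_equal(nrow(fr), 9L)
  expect_equal(length(unique(fr$gene)), 8L)
  expect_true(all(!fr$orf_complete))
  truth <- ck_mito()$transfers
  merged <- merge(fr, truth, by = c("gene", "copy"))
  expect_equal(nrow(merged), 9L)
  expect_equal(merged$sstart, merged$start)
  expect_equal(merged$send, merged$end)
  expect_true(all(merged$identity == 1))
})

test_that("hits are sound: re-aligned identity matches the report", {
  hits <- ck_scan()
  mito <- ck_mito()$sequences
  ref <- reference_plastid_catalog()
  for (i in seq_len(nrow(hits))) {
    frag <- substr(mito[[hits$seqid[i]]], hits$sstart[i], hits$send[i])
    if (hits$strand[i] == "-") {
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    }
    rseq <- substr(ref$sequence[match(hits$gene[i], ref$gene)],
                   hits$qstart[i], hits$qend[i])
    ident <- mean(strsplit(frag, "")[[1]] == strsplit(rseq, "")[[1]])
    expect_gte(ident, hits$identity[i] - 1e-9)
  }
})

test_that("relaxing the cutoff never removes hits", {
  strict <- ck_scan()
  relaxed <- scan_homology(ck_mito()$sequences, reference_plastid_catalog(),
                           cutoff = 1e-3)
  key <- function(h) paste(h$gene, h$seqid, h$sstart, h$send)
  expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("a mutated planted fragment is still found within the gap margin", {
  spec <- fixture_spec(
    seed = 8L, chromosomes = c(mt1 = 15000L),
    local_genes = list(mt1 = c("cox1", "nad1")),
    transfers = data.frame(gene = "rpoB", donor = "Lamiales",
                           ref_start = 101L, length = 600L, chrom = "mt1"),
    mutation_rate = 0.01)
  mf <- make_mitogenome_fixture(spec)
  hits <- scan_homology(mf$sequences, reference_plastid_catalog())
  hits <- hits[hits$gene == "rpoB", ]
  expect_equal(nrow(hits), 1L)
  truth <- mf$transfers
  expect_lte(abs(hits$sstart - truth$start), 50L)
  expect_lte(abs(hits$send - truth$end), 50L)
  expect_gte(hits$identity, 0.95)
})

test_that("scan agrees with exhaustive local alignment on a toy input", {
  spec <- fixture_spec(
    seed = 12L, chromosomes = c(mt1 = 8000L),
    local_genes = list(mt1 = "cox1"),
    transfers = data.frame(gene = "petB", donor = "Lamiales",
                           ref_start = 31L, length = 400L, chrom = "mt1"))
  mf <- make_mitogenome_fixture(spec)
  hits <- scan_homology(mf$sequences, reference_plastid_catalog())
  hits <- hits[hits$gene == "petB", ]
  expect_equal(nrow(hits), 1L)
  ref <- reference_plastid_catalog()
  target <- ref$sequence[ref$gene == "petB"]
  chrom <- mf$sequences[["mt1"]]
  subject <- if (hits$strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
  } else chrom
  sw <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(subject), Biostrings::DNAString(target),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  sw_start <- BiocGenerics::start(Biostrings::pattern(sw))
  sw_end <- BiocGenerics::end(Biostrings::pattern(sw))
  if (hits$strand == "-") {
    n <- nchar(chrom)
    tmp <- c(n - sw_end + 1L, n - sw_start + 1L)
    sw_start <- tmp[1]; sw_end <- tmp[2]
  }
  expect_equal(c(hits$sstart, hits$send), c(sw_start, sw_end))
})

test_that("ORF completeness distinguishes complete and broken frames", {
  ref <- reference_plastid_catalog()
  petB <- ref$sequence[ref$gene == "petB"]
  # fragment carrying the full CDS plus flanks
  set.seed(4)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  full <- paste0(flank(25), petB, flank(30))
  expect_true(check_orf_completeness(full, petB)$complete)
  # truncated at 70%
  trunc <- substr(petB, 1, floor(nchar(petB) * 0.7))
  res <- check_orf_completeness(trunc, petB)
  expect_false(res$complete)
  expect_equal(res$reason, "too_short")
  # internal stop breaks the frame
  broken <- petB
  substr(broken, 301, 303) <- "TAA"
  res2 <- check_orf_completeness(paste0(flank(10), broken, flank(10)), petB)
  expect_false(res2$complete)
  expect_equal(res2$reason, "internal_stop")
  # non-coding reference is flagged not applicable
  res3 <- check_orf_completeness("ACGTACGT", "ACGTACGT", type = "rna")
  expect_true(is.na(res3$complete))
  expect_equal(res3$reason, "not_applicable")
})

test_that("hits round-trip through BLAST outfmt-6 TSV", {
  hits <- ck_scan()
  path <- tempfile(fileext = ".tsv")
  write_blast6(hits, path)
  back <- read_blast6(path)
  expect_equal(back$gene, hits$gene)
  expect_equal(back$seqid, hits$seqid)
  expect_equal(back$sstart, hits$sstart)
  expect_equal(back$send, hits$send)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$identity, hits$identity, tolerance = 1e-4)
})
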