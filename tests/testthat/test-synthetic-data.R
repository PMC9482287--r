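test_that("plastome fixture reproduces the planted quadripartite layout", {
  pf <- ck_plastome()
  expect_equal(nchar(pf$sequence), 96074L)
  expect_equal(unname(pf$regions),
               c(30072L, 480L, 32761L, 32761L))
  # IRb is the exact reverse complement of IRa
  ira <- substr(pf$sequence, 30073L, 30072L + 32761L)
  irb <- substr(pf$sequence, 96074L - 32761L + 1L, 96074L)
  expect_identical(irb, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ira))))
})

test_that("a tiny all-intact spec builds a revcomp-consistent circle", {
  spec <- fixture_spec(
    seed = 3L, regions = c(lsc = 700L, ssc = 500L, ir = 400L),
    gene_statuses = c(psbA = "intact", rpl32 = "intact"),
    ssc_genes = "rpl32")
  pf <- make_plastome_fixture(spec)
  expect_equal(nchar(pf$sequence), 700L + 500L + 2L * 400L)
  ira <- substr(pf$sequence, 701L, 1100L)
  irb <- substr(pf$sequence, 1601L, 2000L)
  expect_identical(irb, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ira))))
})

test_that("exactly the 11 listed pseudogenes carry planted defects", {
  pf <- ck_plastome()
  defective <- unique(pf$catalog$gene[pf$catalog$defect != "none"])
  expect_setequal(defective,
                  c("rps16", "psbI", "rpoB", "psbD", "atpE", "petB", "rpoA",
                    "rpl23", "ycf15", "ndhB", "rps15"))
  expect_equal(sum(pf$catalog$status == "pseudogene"), 11L)
})

test_that("lost genes leave no homologous segment in the plastome", {
  pf <- ck_plastome()
  ref <- reference_plastid_catalog()
  lost <- names(ck_plastome_spec(1)$gene_statuses)[
    ck_plastome_spec(1)$gene_statuses == "lost"]
  hits <- scan_homology(c(plastome = pf$sequence),
                        ref[ref$gene %in% lost, ])
  expect_equal(nrow(hits), 0L)
})

test_that("mitogenome fixture has the stated chromosomes and gene layout", {
  mf <- ck_mito()
  expect_equal(unname(nchar(mf$sequences)),
               c(87933L, 303254L, 241909L))
  expect_equal(sum(nchar(mf$sequences)), 633096L)
  expect_equal(nrow(mf$catalog), 75L)
  expect_equal(as.vector(table(mf$catalog$seqid)[c("mt1", "mt2", "mt3")]),
               c(9L, 28L, 38L))
  by_type <- table(mf$catalog$type)
  expect_equal(sum(mf$catalog$type == "protein"), 39L)
  expect_equal(sum(mf$catalog$class == "trn"), 26L)
  expect_equal(sum(mf$catalog$class == "rrn"), 10L)
  expect_equal(nrow(mf$transfers), 9L)
  expect_equal(length(unique(mf$transfers$gene)), 8L)
  expect_equal(sum(mf$transfers$gene == "ycf2"), 2L)
})

test_that("a transfer-free mitogenome yields zero homology hits", {
  spec <- fixture_spec(
    seed = 5L, chromosomes = c(mt1 = 20000L),
    local_genes = list(mt1 = c("cox1", "nad1", "atp1")),
    transfers = NULL)
  mf <- make_mitogenome_fixture(spec)
  hits <- scan_homology(mf$sequences, reference_plastid_catalog())
  expect_equal(nrow(hits), 0L)
})

test_that("fixture generation is seed-deterministic and seed-sensitive", {
  a <- make_plastome_fixture(ck_plastome_spec(11))
  b <- make_plastome_fixture(ck_plastome_spec(11))
  c <- make_plastome_fixture(ck_plastome_spec(12))
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$catalog, b$catalog)
  expect_false(identical(a$sequence, c$sequence))
  m1 <- make_mitogenome_fixture(ck_mitogenome_spec(11))
  m2 <- make_mitogenome_fixture(ck_mitogenome_spec(11))
  expect_identical(m1$sequences, m2$sequences)
})

test_that("invalid specs are rejected", {
  expect_error(fixture_spec(regions = c(lsc = -5, ssc = 1, ir = 1)),
               "positive")
  expect_error(fixture_spec(gene_statuses = c(psbA = "broken")),
               "unknown gene status")
  expect_error(
    fixture_spec(ir_genes = c("rrn16", "rrn23"), irb_genes = "rrn16"),
    "inconsistently")
  expect_error(
    fixture_spec(chromosomes = c(mt1 = 500L),
                 transfers = data.frame(gene = "ycf2", donor = "x",
                                        ref_start = 1L, length = 900L,
                                        chrom = "mt1")),
    "longer than its chromosome")
})

test_that("annotations round-trip through GFF3 unchanged", {
  pf <- ck_plastome()
  path <- tempfile(fileext = ".gff3")
  cols <- c("seqid", "start", "end", "strand", "gene", "category",
            "type", "copy")
  write_gene_catalog(pf$catalog, path,
                     seqlens = c(plastome = nchar(pf$sequence)))
  back <- read_gene_catalog(path)
  orig <- pf$catalog[order(pf$catalog$start, pf$catalog$gene), cols]
  back <- back[order(back$start, back$gene), cols]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back, orig)
})

test_that("tree fixtures validate their scenarios", {
  scen <- ck_tree_scenarios()
  for (sc in scen) {
    nwk <- make_tree_fixture(sc)
    phy <- ape::read.tree(text = nwk)
    expect_true(sc$query %in% phy$tip.label)
    expect_equal(sum(phy$tip.label == sc$query), 1L)
  }
  bad <- scen$rpoB
  bad$newick <- "(Oryza_outgroup,(Salvia_sp,CK_query)120);"
  expect_error(make_tree_fixture(bad), "support")
  dup <- scen$rpoB
  dup$newick <- "(Oryza_outgroup,(CK_query,CK_query)90);"
  expect_error(make_tree_fixture(dup), "duplicate|exactly once")
})
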