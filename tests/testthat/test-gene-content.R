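test_that("classify_gene follows the pseudogene decision rules", {
  ref <- paste0("ATG", strrep("GCT", 98), "TAA")   # clean 100-codon CDS
  # identity case
  expect_equal(classify_gene(ref, ref),
               list(status = "intact", reason = "ok"))
  # stop codon substituted at codon 40 of 100
  obs <- ref
  substr(obs, 118, 120) <- "TAA"
  expect_equal(classify_gene(obs, ref),
               list(status = "pseudogene", reason = "premature_stop"))
  # absent observation
  expect_equal(classify_gene(NA, ref),
               list(status = "lost", reason = "no_hit"))
  # truncation below half the reference translated length
  expect_equal(classify_gene(substr(ref, 1, 120), ref),
               list(status = "pseudogene", reason = "too_short"))
  # unrelated sequence: no homologous segment at the cutoff
  set.seed(9)
  junk <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  expect_equal(classify_gene(junk, ref)$status, "lost")
  # structural RNAs skip the stop-codon test
  rna <- paste0(strrep("TAA", 60))
  expect_equal(classify_gene(rna, rna, type = "rna")$status, "intact")
  # input validation
  expect_error(classify_gene("ATG", ""), "empty reference")
  expect_error(classify_gene("AXG", "ATGTAA"), "non-nucleotide")
})

test_that("classification agrees with the brute-force translator oracle", {
  ref <- reference_plastid_catalog()
  set.seed(21)
  sub <- ref[sample(nrow(ref), 20), ]
  for (i in seq_len(nrow(sub))) {
    r <- sub[i, ]
    cases <- list(intact = r$sequence,
                  absent = NA_character_,
                  trunc = substr(r$sequence, 1, floor(nchar(r$sequence) * 0.3)))
    if (r$type == "protein") {
      stopped <- r$sequence
      at <- max(2L, floor(nchar(r$sequence) / 6) * 3 + 1)
      substr(stopped, at, at + 2) <- "TAA"
      cases$stopped <- stopped
    }
    for (obs in cases) {
      got <- classify_gene(obs, r$sequence, type = r$type)$status
      expect_equal(got, oracle_classify(obs, r$sequence, r$type),
                   info = paste(r$gene, nchar(obs)))
    }
  }
})

test_that("every catalog gene gets exactly one status and counts partition", {
  cls <- ck_plastome_classified()
  cb <- count_by_status(cls, unit = "row")
  expect_equal(unname(cb$counts["intact"]), 68L)
  expect_equal(unname(cb$counts["pseudogene"]), 11L)
  expect_equal(unname(cb$counts["lost"]), 40L)
  expect_equal(sum(cb$counts), nrow(cls$rows))
  # per-category breakdown of the intact genes, non-ribosomal collapsed
  cb2 <- count_by_status(cls, unit = "row", collapse = TRUE)
  intact_by_cat <- cb2$by_category["intact", ]
  expect_equal(unname(intact_by_cat[c("trn", "rrn", "rps", "rpl", "other")]),
               c(31L, 8L, 10L, 7L, 12L))
  expect_equal(sum(cb2$by_category["intact", ]), 68L)
  # classification of the synthetic catalog recovers the planted status map
  pf <- ck_plastome()
  planted <- pf$catalog$status
  names(planted) <- paste(pf$catalog$gene, pf$catalog$copy)
  got <- cls$rows$status[match(names(planted),
                               paste(cls$rows$gene, cls$rows$copy))]
  expect_equal(unname(got), unname(planted))
})

test_that("empty catalogs count to zero", {
  cb <- count_by_status(data.frame(gene = character(0),
                                   category = character(0),
                                   status = character(0)))
  expect_equal(sum(cb$counts), 0L)
})

test_that("mitochondrial core genes are retained, variable losses reported", {
  mcls <- ck_mito_classified()
  cb <- count_by_status(mcls, unit = "row")
  expect_equal(unname(cb$counts["intact"]), 75L)
  core <- check_core_retention(mcls)
  expect_equal(core$present, 24L)
  expect_equal(core$missing, character(0))
  expect_true(all(c("rps2", "rps11") %in% core$variable_missing))
  expect_equal(length(mito_core_genes()), 24L)
  # deleting one core gene is noticed
  dropped <- mcls$symbols
  dropped$status[dropped$gene == "nad5"] <- "lost"
  core2 <- check_core_retention(dropped)
  expect_equal(core2$present, 23L)
  expect_equal(core2$missing, "nad5")
  expect_error(check_core_retention(mcls, core = character(0)), "empty")
})

test_that("stage assignment reproduces the documented placements", {
  all_intact <- data.frame(
    category = c("psa", "psb", "pet", "ndh", "rpo", "atp", "rps", "rpl"),
    n_intact = c(5L, 15L, 6L, 11L, 4L, 6L, 12L, 8L),
    n_total = c(5L, 15L, 6L, 11L, 4L, 6L, 12L, 8L))
  expect_equal(as.character(assign_stage(all_intact)), "Photosynthetic")
  # ndh-only loss stays photosynthetic
  ndh_only <- all_intact
  ndh_only$n_intact[ndh_only$category == "ndh"] <- 0L
  expect_equal(as.character(assign_stage(ndh_only)), "Photosynthetic")
  # partial photosystem loss with rpo pseudogenized, atp untouched
  deg1 <- all_intact
  deg1$n_intact <- c(3L, 7L, 6L, 0L, 0L, 6L, 12L, 8L)
  expect_equal(as.character(assign_stage(deg1)), "DegradationI")
  # the classified plastome fixture profile sits in the stationary stage
  expect_equal(as.character(assign_stage(content_profile(
    ck_plastome_classified()))), "Stationary")
  # ribosomal collapse marks the late degradation stage
  deg2 <- all_intact
  deg2$n_intact <- c(0L, 1L, 0L, 0L, 0L, 2L, 3L, 2L)
  expect_equal(as.character(assign_stage(deg2)), "DegradationII")
  expect_equal(as.character(assign_stage(
    data.frame(category = character(0), n_intact = integer(0),
               n_total = integer(0)))), "Absent")
  expect_error(assign_stage(data.frame(category = "atp", n_intact = 7L,
                                       n_total = 6L)), "outside")
})

test_that("stage assignment is monotone under further degradation", {
  lv <- c("Photosynthetic", "DegradationI", "Stationary", "DegradationII",
          "Absent")
  set.seed(33)
  for (rep in 1:60) {
    totals <- c(psa = 5L, psb = 15L, pet = 6L, ndh = 11L, rpo = 4L,
                atp = 6L, rps = 12L, rpl = 8L)
    intact <- vapply(totals, function(t) sample.int(t + 1L, 1L) - 1L,
                     integer(1))
    prof <- data.frame(category = names(totals), n_intact = unname(intact),
                       n_total = unname(totals))
    s0 <- assign_stage(prof)
    # degrade one more gene in a random category that still has intact genes
    candidates <- which(prof$n_intact > 0L)
    if (!length(candidates)) next
    j <- sample(candidates, 1L)
    prof$n_intact[j] <- prof$n_intact[j] - 1L
    s1 <- assign_stage(prof)
    expect_gte(match(as.character(s1), lv), match(as.character(s0), lv))
  }
})

test_that("species content comparison matches the recorded ratios", {
  m <- ck_content_matrix()
  cmp <- compare_content(m, "Melampyrum_koreanum", "Lathraea_squamaria")
  expect_equal(cmp$lost$n_a, 7L)
  expect_equal(cmp$lost$n_b, 5L)
  expect_equal(cmp$lost$pct_of_a, 71.4)
  expect_equal(cmp$pseudogene$n_a, 4L)
  expect_equal(cmp$pseudogene$n_b, 30L)
  expect_equal(cmp$pseudogene$pct_of_a, 750)   # 7.5x
  same <- compare_content(m, "Lathraea_squamaria", "Lathraea_squamaria")
  expect_equal(same$lost$pct_of_a, 100)
  zero <- compare_content(m, "Lindenbergia_philippensis",
                          "Lathraea_squamaria")
  expect_true(is.na(zero$lost$pct_of_a))
  expect_error(compare_content(m, "nope", "Lathraea_squamaria"),
               "unknown species")
})

test_that("the shipped content matrix TSV matches the generator", {
  shipped <- read_content_matrix(
    system.file("extdata", "plastome_gene_content.synthetic.tsv",
                package = "miptkit"))
  expect_equal(shipped, ck_content_matrix())
})
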