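test_that("monophyly matches direct clade checks on a caterpillar tree", {
  phy <- ape::read.tree(text = "(((A,B),C),D);")
  st <- support_tree(phy, groups = c(A = "g", B = "g", C = "h", D = "out"),
                     query = "A")
  expect_true(is_monophyletic(st, c("A", "B"))$monophyletic)
  expect_false(is_monophyletic(st, c("A", "C"))$monophyletic)
  expect_error(is_monophyletic(st, c("A", "Z")), "unknown tips")
  expect_error(is_monophyletic(st, character(0)), "empty")
})

test_that("monophyly agrees with the exhaustive oracle on random trees", {
  set.seed(77)
  n_cases <- 0L
  while (n_cases < 1000L) {
    n_tip <- sample(4:8, 1)
    phy <- random_rooted_tree(n_tip)
    tips <- phy$tip.label
    st <- support_tree(phy, groups = stats::setNames(rep("g", n_tip), tips),
                       query = tips[1])
    # all proper subsets of size >= 2 for small trees, a sample for larger
    subsets <- if (n_tip <= 6) {
      unlist(lapply(2:(n_tip - 1), function(k) {
        utils::combn(tips, k, simplify = FALSE)
      }), recursive = FALSE)
    } else {
      lapply(1:25, function(i) sample(tips, sample(2:(n_tip - 1), 1)))
    }
    for (ss in subsets) {
      expect_equal(is_monophyletic(st, ss)$monophyletic,
                   oracle_monophyletic(phy, ss))
      n_cases <- n_cases + 1L
    }
  }
  expect_gte(n_cases, 1000L)
})

test_that("fragments are classified IGT, HGT or undetermined as designed", {
  scen <- ck_tree_scenarios()
  classify <- function(id) {
    sc <- scen[[id]]
    tr <- support_tree(make_tree_fixture(sc), sc$groups, sc$query,
                       sc$outgroup)
    classify_transfer(tr, n_informative = sc$n_informative)
  }
  igt <- classify("rpoB")
  expect_equal(igt$verdict, "IGT")
  expect_equal(igt$support, 95)
  hgt <- classify("ycf2.1")
  expect_equal(hgt$verdict, "HGT")
  expect_equal(hgt$donor, "Orchidaceae")
  expect_equal(hgt$support, 85)
  for (id in c("rpl14", "rpl16")) {
    g <- classify(id)
    expect_equal(g$verdict, "HGT")
    expect_equal(g$donor, "Gentianaceae")
    expect_equal(g$support, 100)
  }
  for (id in c("ycf15", "ycf2.2")) {
    u <- classify(id)
    expect_equal(u$verdict, "undetermined")
    expect_equal(u$reason, "too_short")
  }
})

test_that("unsupported topologies stay undetermined", {
  groups <- c(Out = "outgroup", L1 = "Lamiales", L2 = "Lamiales",
              Q = "query")
  # all supports at 60: below the bootstrap gate
  tr <- support_tree("(Out,(L1,(L2,Q)60)60);", groups, "Q", "Out")
  low <- classify_transfer(tr, n_informative = 10)
  expect_equal(low$verdict, "undetermined")
  expect_equal(low$reason, "low_support")
  # query sister to the outgroup with all supports 50
  tr2 <- support_tree("((Out,Q)50,(L1,L2)50);", groups, "Q", "Out")
  expect_equal(classify_transfer(tr2, n_informative = 10)$verdict,
               "undetermined")
})

test_that("classification is invariant to tip order and rerooting", {
  sc <- ck_tree_scenarios()$rpoB
  base <- classify_transfer(
    support_tree(sc$newick, sc$groups, sc$query, sc$outgroup),
    n_informative = sc$n_informative)
  # same topology, children written in permuted order
  permuted <- c(
    "(Oryza_outgroup,(Salvia_sp,(CK_query,Sesamum_sp)84)95,(Gentiana_sp,Coffea_sp)88);",
    "(((Sesamum_sp,CK_query)84,Salvia_sp)95,(Coffea_sp,Gentiana_sp)88,Oryza_outgroup);")
  for (nwk in permuted) {
    got <- classify_transfer(
      support_tree(nwk, sc$groups, sc$query, sc$outgroup),
      n_informative = sc$n_informative)
    expect_equal(got$verdict, base$verdict)
    expect_equal(got$donor, base$donor)
    expect_equal(got$support, base$support)
  }
  # explicit rooting on the outgroup edge before classification
  phy <- ape::read.tree(text = sc$newick)
  rooted <- ape::root(phy, outgroup = "Oryza_outgroup", resolve.root = TRUE,
                      edgelabel = TRUE)
  got <- classify_transfer(
    support_tree(rooted, sc$groups, sc$query, sc$outgroup),
    n_informative = sc$n_informative)
  expect_equal(got$verdict, base$verdict)
  expect_equal(got$support, base$support)
})

test_that("raising the bootstrap gate never turns undetermined into a call", {
  scen <- ck_tree_scenarios()
  gates <- c(50, 60, 70, 80, 90, 99)
  for (sc in scen) {
    tr <- support_tree(make_tree_fixture(sc), sc$groups, sc$query,
                       sc$outgroup)
    determined <- vapply(gates, function(g) {
      classify_transfer(tr, min_support = g,
                        n_informative = sc$n_informative)$verdict !=
        "undetermined"
    }, logical(1))
    # once undetermined at some gate, stays undetermined at stricter gates
    expect_true(all(diff(as.integer(determined)) <= 0L))
  }
})

test_that("the pivotal-site audit flags the single-site attachment", {
  aln <- ck_rpl20_alignment()
  audit <- audit_sites(aln, "CK_query",
                       group_a = c("Salvia_sp", "Scutellaria_sp"),
                       group_b = c("Orobanche_sp", "Aeginetia_sp"))
  expect_true(audit$fragile)
  expect_equal(audit$support_a, 1L)
  expect_equal(audit$support_b, 0L)
  expect_equal(audit$pivotal$site, 187L)
  expect_setequal(c(audit$pivotal$from, audit$pivotal$to), c("A", "G"))
})

test_that("ten consistent sites are not fragile; zero sites support nobody", {
  aln <- consistent_alignment(10L)
  audit <- audit_sites(aln, "query", c("a1", "a2"), c("b1", "b2"))
  expect_equal(audit$support_a, 10L)
  expect_false(audit$fragile)
  # constant alignment: no informative columns at all
  flat <- stats::setNames(rep(strrep("ACGT", 25), 6),
                          c("query", "a1", "a2", "b1", "b2", "out"))
  audit0 <- audit_sites(flat, "query", c("a1", "a2"), c("b1", "b2"))
  expect_equal(audit0$support_a + audit0$support_b, 0L)
  expect_equal(audit0$winner, "tie")
  expect_equal(count_informative_sites(flat), 0L)
  expect_error(audit_sites(aln, "query", c("a1", "b1"), c("b1", "b2")),
               "overlap")
  ragged <- c(query = "ACGT", a1 = "ACG")
  expect_error(audit_sites(ragged, "query", "a1", "a1"), "ragged|overlap")
})

test_that("flip analysis agrees with recomputing the audit from scratch", {
  aln <- ck_rpl20_alignment()
  audit <- audit_sites(aln, "CK_query",
                       group_a = c("Salvia_sp", "Scutellaria_sp"),
                       group_b = c("Orobanche_sp", "Aeginetia_sp"))
  for (i in seq_len(nrow(audit$pivotal))) {
    mutated <- aln
    s <- strsplit(mutated[["CK_query"]], "")[[1]]
    s[audit$pivotal$site[i]] <- audit$pivotal$to[i]
    mutated[["CK_query"]] <- paste(s, collapse = "")
    re <- audit_sites(mutated, "CK_query",
                      group_a = c("Salvia_sp", "Scutellaria_sp"),
                      group_b = c("Orobanche_sp", "Aeginetia_sp"))
    expect_false(re$winner == audit$winner)
  }
})

test_that("NJ recovers an additive four-taxon topology", {
  # ((A,B),(C,D)) with long internal branch: diagnostic columns separate
  # the two cherries
  aln <- c(
    A = paste(c(rep("A", 40), rep("C", 5), rep("G", 55)), collapse = ""),
    B = paste(c(rep("A", 40), rep("T", 5), rep("G", 55)), collapse = ""),
    C = paste(c(rep("C", 40), rep("C", 5), rep("G", 55)), collapse = ""),
    D = paste(c(rep("C", 40), rep("T", 5), rep("G", 55)), collapse = ""))
  phy <- build_nj_tree(aln)
  # the split {A,B} | {C,D} must be present
  expect_true(oracle_monophyletic(ape::root(phy, "D", resolve.root = TRUE),
                                  c("A", "B")))
  expect_error(build_nj_tree(aln[1:3]), "at least 4")
})

test_that("bootstrap support is seeded and finds the strong clade", {
  set.seed(55)
  backbone <- function() paste(sample(c("A", "C", "G", "T"), 150, TRUE),
                               collapse = "")
  shared <- backbone()
  mutate_at <- function(s, pos, base) {
    v <- strsplit(s, "")[[1]]; v[pos] <- base; paste(v, collapse = "")
  }
  # 50 fixed diagnostic columns uniting A and B
  diag_cols <- 1:50
  aln <- c(A = shared, B = shared, C = backbone(), D = backbone(),
           E = backbone())
  for (j in diag_cols) {
    aln[["A"]] <- mutate_at(aln[["A"]], j, "T")
    aln[["B"]] <- mutate_at(aln[["B"]], j, "T")
  }
  t1 <- bootstrap_support(aln, replicates = 100, seed = 3)
  t2 <- bootstrap_support(aln, replicates = 100, seed = 3)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  st <- support_tree(t1, groups = stats::setNames(rep("g", 5), names(aln)),
                     query = "A", outgroup = "E")
  mono <- is_monophyletic(st, c("A", "B"))
  expect_true(mono$monophyletic)
  expect_gte(mono$support, 95)
})
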