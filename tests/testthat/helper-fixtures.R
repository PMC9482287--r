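# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

ck_plastome <- function() {
  cached("plastome", function() make_plastome_fixture(ck_plastome_spec(1)))
}

ck_mito <- function() {
  cached("mito", function() make_mitogenome_fixture(ck_mitogenome_spec(1)))
}

ck_plastome_classified <- function() {
  cached("plastome_cls", function() {
    classify_catalog(ck_plastome()$catalog, reference_plastid_catalog())
  })
}

ck_mito_classified <- function() {
  cached("mito_cls", function() {
    classify_catalog(ck_mito()$catalog, reference_mito_catalog())
  })
}

ck_scan <- function() {
  cached("scan", function() {
    scan_homology(ck_mito()$sequences, reference_plastid_catalog())
  })
}

ck_fragments <- function() {
  cached("fragments", function() {
    transfer_fragments(ck_scan(), ck_mito()$sequences,
                       reference_plastid_catalog())
  })
}

# species column of the shipped content matrix as a classified-symbols frame
species_profile <- function(species, matrix = ck_content_matrix()) {
  data.frame(gene = matrix$gene, category = gene_category(matrix$gene),
             status = matrix[[species]], stringsAsFactors = FALSE)
}

# a control alignment with `n` informative columns all supporting group A
consistent_alignment <- function(n = 10L, ncol = 120L, seed = 7L) {
  taxa <- c("query", "a1", "a2", "b1", "b2", "out")
  set.seed(seed)
  backbone <- sample(c("A", "C", "G", "T"), ncol, replace = TRUE)
  m <- matrix(rep(backbone, length(taxa)), nrow = length(taxa), byrow = TRUE,
              dimnames = list(taxa, NULL))
  cols <- seq(5L, by = 7L, length.out = n)
  for (j in cols) {
    derived <- setdiff(c("A", "C", "G", "T"), m["query", j])[1]
    m[c("query", "a1", "a2"), j] <- derived
  }
  apply(m, 1L, paste, collapse = "")
}
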