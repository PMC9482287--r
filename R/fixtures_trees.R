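# Tree, alignment and table fixtures for the transfer-classification and
# comparison stages.

#' Build a Newick tree fixture from a named clade scenario
#'
#' A scenario names the tips, their group memberships, the query tip, the
#' outgroup, the per-fragment count of parsimony-informative sites, and the
#' Newick string with internal-node bootstrap labels. The function validates
#' the scenario (supports within \[0, 100\], unique tips, query present
#' exactly once, outgroup present) and returns the Newick text.
#'
#' @param scenario A list with elements `name`, `newick`, `groups` (named
#'   character vector tip -> group), `query`, `outgroup`, `n_informative`.
#' @return The validated Newick string (with class attribute dropped).
#' @seealso [ck_tree_scenarios()], [classify_transfer()]
#' @export
make_tree_fixture <- function(scenario) {
  phy <- ape::read.tree(text = scenario$newick)
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (sum(phy$tip.label == scenario$query) != 1L) {
    stop("query tip must be present exactly once")
  }
  if (!scenario$outgroup %in% phy$tip.label) stop("outgroup missing")
  sup <- suppressWarnings(as.numeric(phy$node.label))
  sup <- sup[!is.na(sup)]
  if (any(sup < 0 | sup > 100)) stop("support outside [0, 100]")
  missing_groups <- setdiff(phy$tip.label, names(scenario$groups))
  if (length(missing_groups)) {
    stop("tips without group mapping: ", paste(missing_groups, collapse = ", "))
  }
  scenario$newick
}

#' Donor-tree scenarios for the nine planted transfer fragments
#'
#' One bootstrap-annotated topology per fragment: four fragments nested
#' within Lamiales with supported clades (intracellular transfer), one
#' nested in Orchidaceae (85% support, sister to Bletilla at 64%), two
#' nested in Gentianaceae at 100%, and two fragments whose alignments carry
#' too few parsimony-informative sites to determine a donor.
#'
#' @return Named list of scenario lists keyed by fragment id
#'   (`gene` or `gene.copy` for the duplicated ycf2).
#' @export
ck_tree_scenarios <- function() {
  groups_igt <- c(Oryza_outgroup = "outgroup", Coffea_sp = "Rubiaceae",
                  Gentiana_sp = "Gentianaceae", Salvia_sp = "Lamiales",
                  Sesamum_sp = "Lamiales", CK_query = "query")
  igt <- function(name, sup_group, sup_inner) {
    list(name = name,
         newick = sprintf(
           "(Oryza_outgroup,(Coffea_sp,Gentiana_sp)88,(Salvia_sp,(Sesamum_sp,CK_query)%d)%d);",
           sup_inner, sup_group),
         groups = groups_igt, query = "CK_query",
         outgroup = "Oryza_outgroup", n_informative = 12L)
  }
  groups_orch <- c(Oryza_outgroup = "outgroup", Salvia_sp = "Lamiales",
                   Sesamum_sp = "Lamiales", Bletilla_sp = "Orchidaceae",
                   Dendrobium_sp = "Orchidaceae", Cymbidium_sp = "Orchidaceae",
                   CK_query = "query")
  groups_gent <- c(Oryza_outgroup = "outgroup", Salvia_sp = "Lamiales",
                   Sesamum_sp = "Lamiales", Gentiana_sp = "Gentianaceae",
                   Swertia_sp = "Gentianaceae", CK_query = "query")
  gent <- function(name, sup) {
    list(name = name,
         newick = sprintf(
           "(Oryza_outgroup,(Salvia_sp,Sesamum_sp)90,((Gentiana_sp,CK_query)%d,Swertia_sp)%d);",
           sup, sup),
         groups = groups_gent, query = "CK_query",
         outgroup = "Oryza_outgroup", n_informative = 15L)
  }
  short <- function(name, n_inf) {
    list(name = name,
         newick = "(Oryza_outgroup,(Salvia_sp,Sesamum_sp)55,(Gentiana_sp,CK_query)60);",
         groups = groups_gent[names(groups_gent) != "Swertia_sp"],
         query = "CK_query", outgroup = "Oryza_outgroup",
         n_informative = n_inf)
  }
  list(
    rpoB = igt("IGT-rpoB", 95L, 84L),
    ndhB = igt("IGT-ndhB", 92L, 80L),
    rpl20 = igt("IGT-rpl20", 83L, 74L),
    petB = igt("IGT-petB", 96L, 77L),
    ycf2.1 = list(
      name = "HGT-ycf2",
      newick = "(Oryza_outgroup,(Salvia_sp,Sesamum_sp)92,((Bletilla_sp,CK_query)64,(Dendrobium_sp,Cymbidium_sp)78)85);",
      groups = groups_orch, query = "CK_query",
      outgroup = "Oryza_outgroup", n_informative = 10L),
    rpl14 = gent("HGT-rpl14", 100L),
    rpl16 = gent("HGT-rpl16", 100L),
    ycf15 = short("short-ycf15", 2L),
    ycf2.2 = short("short-ycf2-2", 1L))
}

#' Alignment fixture with a single pivotal site at column 187
#'
#' A 360-column nucleotide alignment of the query, two Lamiaceae tips, two
#' Orobanchaceae tips, and an outgroup, in which exactly one
#' parsimony-informative column discriminates the two donor hypotheses: at
#' column 187 the query carries G together with the Lamiaceae tips while all
#' other taxa carry A. All remaining variation is outgroup-private and
#' therefore uninformative, so the Lamiaceae attachment of the query hinges
#' on that single A/G site.
#'
#' @param seed Integer seed for the otherwise-constant backbone sequence.
#' @return Named character vector of aligned sequences.
#' @export
ck_rpl20_alignment <- function(seed = 42L) {
  taxa <- c("CK_query", "Salvia_sp", "Scutellaria_sp",
            "Orobanche_sp", "Aeginetia_sp", "Oryza_outgroup")
  with_seed(seed, {
    ncol <- 360L
    backbone <- strsplit(random_dna(ncol, 0.4), "")[[1]]
    backbone[187L] <- "A"
    aln <- matrix(rep(backbone, length(taxa)), nrow = length(taxa),
                  byrow = TRUE, dimnames = list(taxa, NULL))
    aln[c("CK_query", "Salvia_sp", "Scutellaria_sp"), 187L] <- "G"
    singles <- sample(setdiff(seq_len(ncol), 187L), 12L)
    for (j in singles) {
      aln["Oryza_outgroup", j] <- sample(setdiff(DNA_BASES, aln[1, j]), 1)
    }
    apply(aln, 1L, paste, collapse = "")
  })
}

# Cross-species gene-content matrix ----------------------------------------

#' Synthetic plastome gene-content matrix for ten Orobanchaceae species
#'
#' Rows are the 111 reference gene symbols, columns are species, cells are
#' `intact`/`pseudogene`/`lost`. Counts for the species whose totals are
#' documented are encoded exactly (e.g. M. koreanum 7 lost / 4 pseudogenes;
#' L. squamaria 5 lost / 30 pseudogenes; C. kwangtungensis 40 lost / 11
#' pseudogenes; A. indica 46 lost / 15 pseudogenes; S. asiatica 1 lost / 5
#' pseudogenes); gene identities not individually documented are filled
#' arbitrarily but consistently.
#'
#' @return A data frame with a `gene` column plus one column per species.
#' @export
ck_content_matrix <- function() {
  roster <- plastid_roster()
  base <- function() stats::setNames(rep("intact", length(roster)), roster)
  set <- function(x, genes, status) { x[genes] <- status; x }
  ndh <- paste0("ndh", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K"))

  lind <- base()
  stri <- set(set(base(), "ndhF", "lost"),
              c("ndhA", "ndhB", "ndhD", "ndhG", "ndhK"), "pseudogene")
  mela <- set(set(base(), c("ndhA", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG",
                            "ndhH"), "lost"),
              c("ndhB", "ndhI", "ndhJ", "ndhK"), "pseudogene")
  euph <- set(set(base(), c("ndhA", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG"),
                  "lost"),
              c("ndhB", "ndhI", "ndhJ"), "pseudogene")
  lath <- set(set(base(), c("ndhA", "ndhC", "ndhD", "ndhE", "ndhF"), "lost"),
              c("ndhB", "ndhG", "ndhH", "ndhI", "ndhJ", "ndhK",
                "psaA", "psaC", "psaI",
                paste0("psb", c("B", "C", "D", "E", "F", "H", "I", "J", "K",
                                "L")),
                "petA", "petG", "petL", "rpoA", "rpoC1",
                "rps15", "rps16", "rpl22", "rpl23", "ccsA", "cemA"),
              "pseudogene")
  chri <- ck_gene_statuses()
  aegi <- set(set(base(),
                  c(paste0("psa", c("A", "B", "C", "I", "J")),
                    paste0("psb", c("B", "C", "D", "E", "F", "H", "I", "J",
                                    "K", "L", "M", "N", "T", "Z")),
                    ndh, paste0("pet", c("A", "D", "G", "L", "N")),
                    "rpoC1", "rpoC2", "rbcL", "ycf3", "ycf4", "ccsA", "cemA",
                    "trnA", "trnC", "trnD", "trnV"), "lost"),
              c("psbA", "petB", "rpoA", "rpoB", "rps15", "rps16", "rps18",
                "rpl22", "rpl23", "rpl33", "ycf15", "infA",
                "trnF", "trnG", "trnS3"), "pseudogene")
  orob <- set(aegi, c("rps18", "rpl33"), "lost")
  cist <- set(aegi, "trnF", "lost")
  phel <- set(aegi, c("infA", "trnS3"), "lost")

  out <- data.frame(
    gene = roster,
    Lindenbergia_philippensis = unname(lind),
    Striga_asiatica = unname(stri),
    Melampyrum_koreanum = unname(mela),
    Euphrasia_regelii = unname(euph),
    Lathraea_squamaria = unname(lath),
    Christisonia_kwangtungensis = unname(chri[roster]),
    Aeginetia_indica = unname(aegi),
    Orobanche_crenata = unname(orob),
    Cistanche_deserticola = unname(cist),
    Phelipanche_ramosa = unname(phel),
    stringsAsFactors = FALSE)
  out
}

#' Read / write a species-by-gene content matrix
#'
#' Plain TSV with a `gene` column and one status column per species.
#'
#' @param path File path.
#' @param matrix Content matrix data frame (for writing).
#' @return The content matrix data frame ([read_content_matrix()]) or
#'   `path` invisibly ([write_content_matrix()]).
#' @export
read_content_matrix <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_content_matrix
#' @export
write_content_matrix <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a complete fixture set to a directory
#'
#' Emits FASTA sequences, GFF3 annotations, Newick donor trees, the pivotal
#' site alignment, the gene-content matrix TSV and the spec JSON, so every
#' downstream stage can run from files alone.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed passed to the fixture specs.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- make_plastome_fixture(ck_plastome_spec(seed))
  mf <- make_mitogenome_fixture(ck_mitogenome_spec(seed))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(plastome = pf$sequence)),
    file.path(dir, "plastome.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(mf$sequences),
    file.path(dir, "mitogenome.fasta"))
  write_gene_catalog(pf$catalog, file.path(dir, "plastome.gff3"),
                     seqlens = c(plastome = nchar(pf$sequence)))
  mcat <- rbind(
    mf$catalog[, c("seqid", "start", "end", "strand", "gene", "copy")],
    mf$transfers[, c("seqid", "start", "end", "strand", "gene", "copy")])
  mcat$category <- gene_category(mcat$gene)
  mcat$type <- ifelse(mcat$category %in% c("trn", "rrn"), "rna", "protein")
  write_gene_catalog(mcat, file.path(dir, "mitogenome.gff3"),
                     seqlens = nchar(mf$sequences))
  scen <- ck_tree_scenarios()
  tree_dir <- file.path(dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  for (id in names(scen)) {
    writeLines(make_tree_fixture(scen[[id]]),
               file.path(tree_dir, paste0(id, ".nwk")))
    grp <- scen[[id]]$groups
    utils::write.table(
      data.frame(tip = names(grp), group = unname(grp)),
      file.path(tree_dir, paste0(id, ".groups.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  aln <- ck_rpl20_alignment()
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln),
                              file.path(dir, "rpl20_alignment.fasta"))
  write_content_matrix(ck_content_matrix(),
                       file.path(dir, "gene_content_matrix.tsv"))
  jsonlite::write_json(
    list(seed = seed,
         plastome_regions = as.list(ck_plastome_spec(seed)$regions),
         mito_chromosomes = as.list(ck_mitogenome_spec(seed)$chromosomes),
         transfers = ck_transfers()),
    file.path(dir, "fixture_spec.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
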