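# Mapping expression evidence onto pathway definitions and locating chain
# breaks in linear biosynthetic pathways.

#' Read a pathway definition from JSON
#'
#' A pathway definition lists named components, each with a gene set split
#' by compartment (`plastid`/`nuclear`), plus an alias table resolving
#' subunit-style names (alpha, beta, ...) to gene symbols. Gene sets must be
#' disjoint across components.
#'
#' @param path JSON file; the package ships `ko00195_photosynthesis.json`
#'   under `extdata` (a frozen synthetic roster of 63 genes, 30 plastid +
#'   33 nuclear).
#' @return A list of class `pathway_definition`: `id`, `name`, `components`
#'   (named list of data frames with `gene`, `compartment`), `aliases`.
#' @export
read_pathway <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  comps <- lapply(raw$components, function(cc) {
    data.frame(gene = unlist(cc$genes$gene),
               compartment = unlist(cc$genes$compartment),
               stringsAsFactors = FALSE)
  })
  names(comps) <- vapply(raw$components, `[[`, character(1), "name")
  genes <- unlist(lapply(comps, `[[`, "gene"))
  if (anyDuplicated(genes)) {
    stop("gene sets must be disjoint across components: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  aliases <- unlist(raw$aliases %||% list())
  structure(list(id = raw$id, name = raw$name, components = comps,
                 aliases = aliases), class = "pathway_definition")
}

#' Read an ordered reaction chain from JSON
#'
#' Each step carries a name, an EC number, one or more catalysing gene
#' symbols, and the product it yields; steps are ordered along the chain
#' and `input` names the chain substrate.
#'
#' @param path JSON file; the package ships
#'   `ko00860_chlorophyll_chain.json` under `extdata`.
#' @return A list of class `pathway_chain`: `id`, `name`, `input`, `steps`
#'   (data frame with `step`, `ec`, `genes` (list column), `product`).
#' @export
read_chain <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  steps <- data.frame(
    step = vapply(raw$steps, `[[`, character(1), "step"),
    ec = vapply(raw$steps, `[[`, character(1), "ec"),
    product = vapply(raw$steps, `[[`, character(1), "product"),
    stringsAsFactors = FALSE)
  steps$genes <- lapply(raw$steps, function(s) unlist(s$genes))
  if (!nrow(steps)) stop("empty chain")
  structure(list(id = raw$id, name = raw$name, input = raw$input,
                 steps = steps), class = "pathway_chain")
}

#' Read expression evidence from TSV
#'
#' Two columns: `gene` and `detected` (0/1 or TRUE/FALSE).
#'
#' @param path TSV file. The package ships
#'   `expression_c_kwangtungensis.tsv` and `expression_a_indica.tsv` under
#'   `extdata`, encoding the transcriptome presence patterns of the two
#'   holoparasites.
#' @param species Optional species label attached to the result.
#' @return A list of class `expression_evidence`: `species`, `detected`
#'   (named logical vector).
#' @export
read_expression <- function(path, species = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate gene symbols in evidence")
  structure(list(species = species,
                 detected = stats::setNames(as.logical(df$detected),
                                            df$gene)),
            class = "expression_evidence")
}

#' @rdname read_expression
#' @param evidence An `expression_evidence` (for writing).
#' @export
write_expression <- function(evidence, path) {
  utils::write.table(
    data.frame(gene = names(evidence$detected),
               detected = as.integer(evidence$detected)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

resolve_aliases <- function(genes, aliases) {
  hit <- match(genes, names(aliases))
  ifelse(is.na(hit), genes, unname(aliases[hit]))
}

#' Map expression evidence onto a pathway definition
#'
#' Counts detected genes per pathway component; evidence genes not in the
#' pathway are reported separately, never silently dropped. Aliases in the
#' pathway definition are resolved before matching.
#'
#' @param pathway A [read_pathway()] definition.
#' @param evidence An [read_expression()] evidence object, or a character
#'   vector of detected gene symbols.
#' @return A list of class `pathway_report`: `per_component` (data frame
#'   with `component`, `n_genes`, `n_detected`), `total_detected`,
#'   `detected_genes` (named list per component), `unmapped` (detected
#'   genes outside the pathway), `pathway_size`, `by_compartment` (gene
#'   totals per compartment).
#' @export
map_expression <- function(pathway, evidence) {
  detected_symbols <- if (inherits(evidence, "expression_evidence")) {
    names(evidence$detected)[evidence$detected]
  } else as.character(evidence)
  detected_symbols <- unique(resolve_aliases(detected_symbols,
                                             pathway$aliases))
  comp_names <- names(pathway$components)
  per <- lapply(comp_names, function(nm) {
    genes <- pathway$components[[nm]]$gene
    hits <- intersect(detected_symbols, genes)
    list(n_genes = length(genes), n_detected = length(hits), hits = hits)
  })
  names(per) <- comp_names
  all_genes <- unlist(lapply(pathway$components, `[[`, "gene"),
                      use.names = FALSE)
  compart <- unlist(lapply(pathway$components, `[[`, "compartment"),
                    use.names = FALSE)
  unmapped <- setdiff(detected_symbols, all_genes)
  structure(list(
    per_component = data.frame(
      component = comp_names,
      n_genes = vapply(per, `[[`, integer(1), "n_genes"),
      n_detected = vapply(per, `[[`, integer(1), "n_detected"),
      stringsAsFactors = FALSE),
    total_detected = sum(vapply(per, `[[`, integer(1), "n_detected")),
    detected_genes = lapply(per, `[[`, "hits"),
    unmapped = unmapped,
    pathway_size = length(all_genes),
    by_compartment = table(compartment = compart)),
    class = "pathway_report")
}

#' Locate the first break in an ordered reaction chain
#'
#' Walks the chain in order and returns the earliest step none of whose
#' genes is detected, together with the product of the preceding step (the
#' last metabolite the organism can still reach); reports the chain as
#' complete when every step has a detected gene.
#'
#' @param chain A [read_chain()] definition.
#' @param evidence An [read_expression()] evidence object or character
#'   vector of detected gene symbols.
#' @return A list: `complete` (logical), `break_step`, `break_ec`,
#'   `last_product` (the chain input when step 1 is broken), and
#'   `detected_steps` (logical vector along the chain).
#' @export
find_chain_break <- function(chain, evidence) {
  detected_symbols <- if (inherits(evidence, "expression_evidence")) {
    names(evidence$detected)[evidence$detected]
  } else as.character(evidence)
  ok <- vapply(chain$steps$genes, function(g) {
    any(g %in% detected_symbols)
  }, logical(1))
  if (all(ok)) {
    return(list(complete = TRUE, break_step = NA_character_,
                break_ec = NA_character_,
                last_product = chain$steps$product[nrow(chain$steps)],
                detected_steps = ok))
  }
  first <- which(!ok)[1]
  list(complete = FALSE,
       break_step = chain$steps$step[first],
       break_ec = chain$steps$ec[first],
       last_product = if (first == 1L) chain$input
                      else chain$steps$product[first - 1L],
       detected_steps = ok)
}
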