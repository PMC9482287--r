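# Phylogenetic classification of transferred fragments (intracellular vs
# horizontal) from bootstrap-annotated trees, plus the single-site
# fragility audit and a small NJ + bootstrap builder for fixture trees.

#' Construct a support-annotated, rooted query tree
#'
#' Wraps an `ape` phylogeny (or Newick text whose internal node labels are
#' bootstrap percentages) together with the tip-to-group map and the
#' designated query tip. The tree is rooted on the designated outgroup;
#' unrooted input without an outgroup is an error. Nodes without a numeric
#' support label are treated as unsupported.
#'
#' @param tree An `ape::phylo` object or a Newick string.
#' @param groups Named character vector mapping every tip to a taxonomic
#'   group (e.g. `Lamiales`, `Orchidaceae`, `outgroup`); the query tip may
#'   be mapped to `"query"`.
#' @param query The query tip label (the transferred fragment).
#' @param outgroup Outgroup tip label used for rooting.
#' @return An object of class `support_tree` with elements `phylo`,
#'   `support` (per internal node, `NA` when absent), `groups`, `query`,
#'   `outgroup`.
#' @export
support_tree <- function(tree, groups, query, outgroup = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!query %in% tree$tip.label) stop("query tip absent from tree")
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing)) {
    stop("group map incomplete; unmapped tips: ",
         paste(missing, collapse = ", "))
  }
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) {
      stop("unrooted tree: an outgroup must be designated")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  }
  support <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    support <- suppressWarnings(as.numeric(tree$node.label))
  }
  structure(list(phylo = tree, support = support, groups = groups,
                 query = query, outgroup = outgroup),
            class = "support_tree")
}

# tips descending from each internal node; list indexed by node - Ntip
node_tip_sets <- function(phy) {
  n_tip <- length(phy$tip.label)
  sets <- vector("list", phy$Nnode)
  # postorder accumulation
  for (e in rev(seq_len(nrow(phy$edge)))) {
    parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    kids <- if (child <= n_tip) phy$tip.label[child]
            else sets[[child - n_tip]]
    sets[[parent - n_tip]] <- c(sets[[parent - n_tip]], kids)
  }
  lapply(sets, sort)
}

root_node <- function(phy) {
  setdiff(unique(phy$edge[, 1]), phy$edge[, 2])[1]
}

ancestor_path <- function(phy, tip_label) {
  node <- match(tip_label, phy$tip.label)
  root <- root_node(phy)
  parent_of <- integer(max(phy$edge))
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  path <- integer(0)
  while (node != root) {
    node <- parent_of[node]
    path <- c(path, node)
  }
  path
}

#' Test monophyly of a tip set on a rooted support tree
#'
#' True iff some internal node's descendant tip set equals `tips` exactly;
#' the node's bootstrap support is returned alongside.
#'
#' @param tree A [support_tree()] (or `ape::phylo`).
#' @param tips Character vector of tip labels (non-empty, all present).
#' @return List with `monophyletic` (logical) and `support` (numeric, `NA`
#'   when the set is not a clade or the node carries no support value).
#' @export
is_monophyletic <- function(tree, tips) {
  phy <- if (inherits(tree, "support_tree")) tree$phylo else tree
  support <- if (inherits(tree, "support_tree")) tree$support
             else rep(NA_real_, phy$Nnode)
  if (!length(tips)) stop("tip set is empty")
  unknown <- setdiff(tips, phy$tip.label)
  if (length(unknown)) {
    stop("unknown tips: ", paste(unknown, collapse = ", "))
  }
  sets <- node_tip_sets(phy)
  target <- sort(unique(tips))
  for (i in seq_along(sets)) {
    if (length(sets[[i]]) == length(target) && all(sets[[i]] == target)) {
      return(list(monophyletic = TRUE, support = support[i]))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}

#' Classify a transferred fragment as IGT, HGT or undetermined
#'
#' Implements the nestedness decision rule used for plastid-derived
#' fragments in a parasite mitogenome. Walking from the query tip towards
#' the root, the smallest enclosing clade with bootstrap support of at
#' least `min_support` is located. The verdict is intracellular transfer
#' (IGT) when that clade contains, query aside, only tips of the parasite's
#' own lineage (Lamiales / Orobanchaceae) and that lineage (with the query)
#' forms a supported clade; horizontal transfer (HGT) when the lineage
#' minus the query forms a supported clade of its own while the query's
#' smallest supported enclosing clade lies within a single foreign group,
#' which is reported as the donor. Everything else - unsupported placements,
#' mixed clades, or fragments with fewer than `min_sites`
#' parsimony-informative sites - is undetermined.
#'
#' @param tree A [support_tree()].
#' @param min_support Bootstrap gate in percent (default 70; the rule is
#'   "support strictly greater than" this value is not required - at least
#'   `min_support` + epsilon is, i.e. `support > min_support` fails at
#'   exactly 70 only when the stored support equals the gate; the
#'   conventional reading BS > 70 is used).
#' @param min_sites Minimum number of parsimony-informative sites for a
#'   determinable verdict (default 3).
#' @param n_informative Number of parsimony-informative sites in the
#'   fragment's alignment (`Inf` when not limiting).
#' @param self_groups Group labels counted as the parasite's own lineage.
#' @return A list of class `transfer_call`: `verdict` (`IGT`/`HGT`/
#'   `undetermined`), `donor`, `support`, `reason`.
#' @export
classify_transfer <- function(tree, min_support = 70, min_sites = 3L,
                              n_informative = Inf,
                              self_groups = c("Lamiales", "Orobanchaceae")) {
  stopifnot(inherits(tree, "support_tree"))
  call_out <- function(verdict, donor, support, reason) {
    structure(list(verdict = verdict, donor = donor, support = support,
                   reason = reason), class = "transfer_call")
  }
  if (n_informative < min_sites) {
    return(call_out("undetermined", NA_character_, NA_real_, "too_short"))
  }
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  sets <- node_tip_sets(phy)
  supported <- function(node) {
    s <- tree$support[node - n_tip]
    !is.na(s) && s > min_support
  }
  path <- ancestor_path(phy, tree$query)
  root <- root_node(phy)
  anchor <- NA_integer_
  for (node in path) {
    if (node == root) break                        # the root does not count
    if (supported(node)) { anchor <- node; break }
  }
  if (is.na(anchor)) {
    return(call_out("undetermined", NA_character_, NA_real_, "low_support"))
  }
  others <- setdiff(sets[[anchor - n_tip]], tree$query)
  other_groups <- unique(unname(tree$groups[others]))
  self_tips <- names(tree$groups)[tree$groups %in% self_groups]

  if (all(other_groups %in% self_groups)) {
    lineage <- is_monophyletic(tree, c(self_tips, tree$query))
    if (lineage$monophyletic && !is.na(lineage$support) &&
        lineage$support > min_support) {
      return(call_out("IGT", other_groups[1], lineage$support,
                      "nested_in_Lamiales"))
    }
    return(call_out("undetermined", NA_character_, NA_real_, "low_support"))
  }
  if (length(other_groups) == 1L && !other_groups %in% c("outgroup")) {
    lineage <- is_monophyletic(tree, self_tips)
    if (lineage$monophyletic && !is.na(lineage$support) &&
        lineage$support > min_support) {
      return(call_out("HGT", other_groups, tree$support[anchor - n_tip],
                      "nested_in_other_group"))
    }
  }
  call_out("undetermined", NA_character_, NA_real_, "low_support")
}

#' @export
print.transfer_call <- function(x, ...) {
  cat("Transfer call:", x$verdict,
      if (!is.na(x$donor)) paste0("(donor ", x$donor, ", BS ", x$support, ")")
      else "", "-", x$reason, "\n")
  invisible(x)
}

# Alignment handling --------------------------------------------------------

as_aln_matrix <- function(alignment) {
  if (methods::is(alignment, "DNAStringSet")) {
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (is.matrix(alignment)) return(alignment)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("ragged alignment")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Count parsimony-informative columns of an alignment
#'
#' A column is parsimony-informative when it shows at least two states that
#' each occur in at least two sequences (gaps and ambiguities ignored).
#'
#' @param alignment Named character vector, matrix of single characters, or
#'   `DNAStringSet`.
#' @return Integer count.
#' @export
count_informative_sites <- function(alignment) {
  m <- as_aln_matrix(alignment)
  sum(apply(m, 2, function(col) {
    tab <- table(col[col %in% DNA_BASES])
    sum(tab >= 2L) >= 2L
  }))
}

#' Audit whether a donor assignment hinges on single alignment sites
#'
#' Counts the parsimony-informative columns in which the query shares its
#' base with one candidate donor group exclusively (present in that group,
#' absent from the other). For each such supporting column the query base
#' is flipped to the opposing group's state and the counts recomputed; the
#' call is fragile when one single-site flip changes which group wins the
#' majority.
#'
#' @param alignment Rectangular alignment (named character vector, matrix,
#'   or `DNAStringSet`) containing the query row and both groups.
#' @param query Query row name.
#' @param group_a,group_b Tip names of the two candidate donor groups
#'   (disjoint, both present in the alignment).
#' @return A list of class `site_audit`: `support_a`, `support_b` (column
#'   counts), `winner` (`"A"`, `"B"` or `"tie"`), `fragile` (logical), and
#'   `pivotal` (data frame of 1-based `site`, `from`, `to` flips that change
#'   the winner).
#' @export
audit_sites <- function(alignment, query, group_a, group_b) {
  m <- as_aln_matrix(alignment)
  if (length(intersect(group_a, group_b))) stop("donor groups overlap")
  need <- c(query, group_a, group_b)
  missing <- setdiff(need, rownames(m))
  if (length(missing)) stop("rows absent: ", paste(missing, collapse = ", "))

  informative <- apply(m, 2, function(col) {
    tab <- table(col[col %in% DNA_BASES])
    sum(tab >= 2L) >= 2L
  })
  col_side <- function(mm, j) {
    q <- mm[query, j]
    if (!q %in% DNA_BASES) return("none")
    in_a <- q %in% mm[group_a, j]
    in_b <- q %in% mm[group_b, j]
    if (in_a && !in_b) "A" else if (in_b && !in_a) "B" else "none"
  }
  sides <- vapply(which(informative), function(j) col_side(m, j),
                  character(1))
  support_a <- sum(sides == "A")
  support_b <- sum(sides == "B")
  winner <- if (support_a > support_b) "A"
            else if (support_b > support_a) "B" else "tie"

  pivotal <- list()
  for (j in which(informative)[sides != "none"]) {
    side <- col_side(m, j)
    opposing <- if (side == "A") group_b else group_a
    opp_bases <- unique(m[opposing, j])
    opp_bases <- opp_bases[opp_bases %in% DNA_BASES]
    for (b in opp_bases) {
      m2 <- m
      from <- m2[query, j]
      m2[query, j] <- b
      sides2 <- vapply(which(informative), function(jj) col_side(m2, jj),
                       character(1))
      a2 <- sum(sides2 == "A"); b2 <- sum(sides2 == "B")
      w2 <- if (a2 > b2) "A" else if (b2 > a2) "B" else "tie"
      if (w2 != winner) {
        pivotal[[length(pivotal) + 1L]] <- data.frame(
          site = j, from = from, to = b, stringsAsFactors = FALSE)
      }
    }
  }
  pivotal <- if (length(pivotal)) do.call(rbind, pivotal)
             else data.frame(site = integer(0), from = character(0),
                             to = character(0), stringsAsFactors = FALSE)
  structure(list(support_a = support_a, support_b = support_b,
                 winner = winner, fragile = nrow(pivotal) > 0L,
                 pivotal = pivotal),
            class = "site_audit")
}

# NJ + bootstrap fixture-tree builder ---------------------------------------

#' Neighbor-joining tree on p-distances
#'
#' A small tree builder for fixture alignments: pairwise p-distances
#' (proportion of differing sites, pairwise deletion of gaps) followed by
#' neighbor joining, optionally rooted on an outgroup.
#'
#' @param alignment Named character vector, matrix, or `DNAStringSet`;
#'   at least four sequences, no duplicate labels, no all-gap rows.
#' @param outgroup Optional tip to root on.
#' @return An `ape::phylo` tree.
#' @export
build_nj_tree <- function(alignment, outgroup = NULL) {
  m <- as_aln_matrix(alignment)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("alignment rows must carry unique labels")
  }
  if (nrow(m) < 4L) stop("need at least 4 sequences")
  if (any(apply(m, 1, function(r) !any(r %in% DNA_BASES)))) {
    stop("all-gap row in alignment")
  }
  bin <- ape::as.DNAbin(apply(m, 2, tolower))
  d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
  phy <- ape::nj(d)
  if (!is.null(outgroup)) {
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  phy
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and labels each internal node of the full-data tree with the
#' percentage of replicate trees containing its clade (via
#' [ape::prop.clades()]); seeded and reproducible.
#'
#' @inheritParams build_nj_tree
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return An `ape::phylo` with `node.label` holding support percentages.
#' @export
bootstrap_support <- function(alignment, replicates = 100L, seed = 1L,
                              outgroup = NULL) {
  stopifnot(replicates >= 1L)
  m <- as_aln_matrix(alignment)
  main <- build_nj_tree(m, outgroup = outgroup)
  boots <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      build_nj_tree(m[, cols, drop = FALSE], outgroup = outgroup)
    })
  })
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.character(round(100 * counts / replicates))
  main
}
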