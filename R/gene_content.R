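#' Classification thresholds for gene-status calls
#'
#' @param tau_len Minimum translated length as a fraction of the reference
#'   translated length below which a gene is called pseudogene (`too_short`).
#' @param tau_id Minimum nucleotide identity over the aligned region below
#'   which a gene is called pseudogene (`excess_divergence`).
#' @param evalue Significance cutoff below which a local alignment counts as
#'   a homologous segment at all; with no significant segment the gene is
#'   `lost`.
#' @return A named list of thresholds.
#' @export
classify_params <- function(tau_len = 0.5, tau_id = 0.6, evalue = 1e-10) {
  stopifnot(tau_len > 0, tau_len <= 1, tau_id > 0, tau_id <= 1, evalue > 0)
  list(tau_len = tau_len, tau_id = tau_id, evalue = evalue)
}

#' Classify one gene as intact, pseudogene or lost
#'
#' A gene is `lost` when no homologous segment aligns to the reference at
#' the significance cutoff; `pseudogene` when homologous but its translation
#' is terminated in advance (an in-frame stop strictly before the final
#' codon of the aligned reference span), or its translated length falls
#' below `tau_len` of the reference translated length, or its nucleotide
#' identity over the aligned region falls below `tau_id`; otherwise
#' `intact`. Structural RNA genes (`type = "rna"`) skip the stop-codon and
#' translated-length tests and are judged on homology, identity and length
#' alone.
#'
#' @param observed Observed nucleotide sequence, or `NA`/`NULL` when the
#'   gene has no annotated copy.
#' @param reference Reference nucleotide sequence (a clean CDS for protein
#'   genes).
#' @param type `"protein"` or `"rna"`.
#' @param params Thresholds from [classify_params()].
#' @return A list with elements `status` (`intact`/`pseudogene`/`lost`) and
#'   `reason` (`ok`, `premature_stop`, `too_short`, `excess_divergence`,
#'   `no_hit`).
#' @export
classify_gene <- function(observed, reference, type = "protein",
                          params = classify_params()) {
  if (is.null(reference) || !nzchar(reference)) stop("empty reference")
  check_nt <- function(x, what) {
    if (grepl("[^ACGTNacgtn-]", x)) stop("non-nucleotide characters in ", what)
  }
  check_nt(reference, "reference")
  if (type == "protein" && nchar(reference) %% 3L != 0L) {
    stop("protein reference length must be divisible by 3")
  }
  if (is.null(observed) || length(observed) == 0L || is.na(observed) ||
      !nzchar(observed)) {
    return(list(status = "lost", reason = "no_hit"))
  }
  check_nt(observed, "observed")
  observed <- toupper(gsub("-", "", observed))
  reference <- toupper(reference)

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(observed), Biostrings::DNAString(reference),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  score <- Biostrings::score(aln)
  ev <- ka_evalue(score, nchar(observed), nchar(reference))
  if (ev >= params$evalue) return(list(status = "lost", reason = "no_hit"))

  identity <- Biostrings::pid(aln, type = "PID1") / 100
  if (type == "protein") {
    aa <- translate_nt(observed)
    ref_aa_len <- nchar(reference) / 3L - 1L        # excludes the terminator
    stop_at <- regexpr("*", aa, fixed = TRUE)
    # a stop is premature if it falls strictly before the final codon of the
    # aligned reference span
    ref_end_codon <- ceiling(
      BiocGenerics::end(Biostrings::subject(aln)) / 3L)
    if (stop_at > 0L && stop_at < min(ref_end_codon, nchar(aa))) {
      return(list(status = "pseudogene", reason = "premature_stop"))
    }
    translated_len <- if (stop_at > 0L) stop_at - 1L else nchar(aa)
    if (translated_len < params$tau_len * ref_aa_len) {
      return(list(status = "pseudogene", reason = "too_short"))
    }
  } else if (nchar(observed) < params$tau_len * nchar(reference)) {
    return(list(status = "pseudogene", reason = "too_short"))
  }
  if (identity < params$tau_id) {
    return(list(status = "pseudogene", reason = "excess_divergence"))
  }
  list(status = "intact", reason = "ok")
}

#' Classify every gene of a catalog against a reference roster
#'
#' Each annotated gene copy is classified with [classify_gene()]; reference
#' genes with no annotated copy are appended as `lost` rows, so the result
#' partitions the full reference roster. Symbol-level statuses collapse
#' inverted-repeat duplicates with the better status winning
#' (intact > pseudogene > lost).
#'
#' @param catalog Gene catalog with `gene`, `type`, `copy` and `sequence`
#'   columns (see [extract_gene_sequences()]).
#' @param reference Reference catalog data frame with `gene`, `type`,
#'   `sequence` (defaults to [reference_plastid_catalog()]).
#' @param params Thresholds from [classify_params()].
#' @return A list with `rows` (per annotated copy, plus synthesized rows for
#'   lost symbols) and `symbols` (one row per reference symbol).
#' @export
classify_catalog <- function(catalog, reference = reference_plastid_catalog(),
                             params = classify_params()) {
  ridx <- match(catalog$gene, reference$gene)
  if (anyNA(ridx)) {
    stop("genes absent from the reference roster: ",
         paste(unique(catalog$gene[is.na(ridx)]), collapse = ", "))
  }
  res <- lapply(seq_len(nrow(catalog)), function(i) {
    classify_gene(catalog$sequence[i], reference$sequence[ridx[i]],
                  type = reference$type[ridx[i]], params = params)
  })
  rows <- data.frame(
    gene = catalog$gene,
    category = gene_category(catalog$gene),
    copy = catalog$copy,
    status = vapply(res, `[[`, character(1), "status"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  absent <- setdiff(reference$gene, catalog$gene)
  if (length(absent)) {
    rows <- rbind(rows, data.frame(
      gene = absent, category = gene_category(absent), copy = NA_integer_,
      status = "lost", reason = "no_hit", stringsAsFactors = FALSE))
  }
  rank <- c(intact = 3L, pseudogene = 2L, lost = 1L)
  best <- tapply(rank[rows$status], rows$gene, max)
  symbols <- data.frame(
    gene = names(best),
    category = gene_category(names(best)),
    status = names(rank)[match(as.integer(best), rank)],
    stringsAsFactors = FALSE)
  symbols <- symbols[match(reference$gene, symbols$gene), ]
  rownames(symbols) <- NULL
  list(rows = rows, symbols = symbols)
}

#' Count classified genes by status and category
#'
#' @param classified Result of [classify_catalog()], or a data frame with
#'   `gene`, `category`, `status` columns.
#' @param unit `"row"` counts annotated copies (inverted-repeat duplicates
#'   twice, matching how annotation totals are usually reported);
#'   `"symbol"` counts distinct gene symbols with the better status winning.
#' @param collapse Collapse categories outside `trn`/`rrn`/`rps`/`rpl` into
#'   `other` for the per-category breakdown.
#' @return A list with `counts` (named totals per status, summing to the
#'   catalog size) and `by_category` (status x category table).
#' @export
count_by_status <- function(classified, unit = c("row", "symbol"),
                            collapse = FALSE) {
  unit <- match.arg(unit)
  df <- if (is.data.frame(classified)) classified
        else if (unit == "row") classified$rows else classified$symbols
  if (!nrow(df)) {
    z <- c(intact = 0L, pseudogene = 0L, lost = 0L)
    return(list(counts = z, by_category = table(character(0), character(0))))
  }
  cat_col <- df$category
  if (collapse) {
    cat_col <- ifelse(cat_col %in% c("trn", "rrn", "rps", "rpl"),
                      cat_col, "other")
  }
  status <- factor(df$status, levels = c("intact", "pseudogene", "lost"))
  counts <- table(status)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       by_category = table(status, category = cat_col))
}

#' Check retention of the mitochondrial core genes
#'
#' @param classified Result of [classify_catalog()] on a mitochondrial
#'   catalog (or its `symbols` data frame).
#' @param core Character vector of core gene symbols
#'   (default [mito_core_genes()]).
#' @param variable Character vector of variable gene symbols whose losses
#'   are reported separately; defaults to the `rps`/`rpl`/`sdh` genes of the
#'   mitochondrial reference roster.
#' @return A list with `present` (count of core genes not lost), `missing`
#'   (core symbols lost), and `variable_missing` (variable symbols lost).
#' @export
check_core_retention <- function(classified, core = mito_core_genes(),
                                 variable = NULL) {
  if (!length(core)) stop("core gene list is empty")
  df <- if (is.data.frame(classified)) classified else classified$symbols
  if (is.null(variable)) {
    ref <- reference_mito_catalog()
    variable <- ref$gene[ref$class == "variable"]
  }
  status_of <- function(genes) {
    s <- df$status[match(genes, df$gene)]
    s[is.na(s)] <- "lost"
    stats::setNames(s, genes)
  }
  core_status <- status_of(core)
  var_status <- status_of(variable)
  list(present = sum(core_status != "lost"),
       missing = names(core_status)[core_status == "lost"],
       variable_missing = names(var_status)[var_status == "lost"])
}

# Degradation staging -------------------------------------------------------

STAGE_LEVELS <- c("Photosynthetic", "DegradationI", "Stationary",
                  "DegradationII", "Absent")

#' Per-category functional profile of a classified plastome
#'
#' Counts intact genes per functional category over distinct gene symbols
#' (inverted-repeat duplicates collapsed, better status winning).
#'
#' @param classified Result of [classify_catalog()] (or its `symbols` data
#'   frame).
#' @return Data frame with columns `category`, `n_intact`, `n_total`,
#'   `fraction`.
#' @export
content_profile <- function(classified) {
  df <- if (is.data.frame(classified)) classified else classified$symbols
  cats <- sort(unique(df$category))
  n_total <- vapply(cats, function(cc) sum(df$category == cc), integer(1))
  n_intact <- vapply(cats, function(cc) {
    sum(df$category == cc & df$status == "intact")
  }, integer(1))
  data.frame(category = cats, n_intact = n_intact, n_total = n_total,
             fraction = n_intact / n_total, stringsAsFactors = FALSE)
}

#' Assign the five-stage plastome degradation stage
#'
#' Stages are ordered `Photosynthetic < DegradationI < Stationary <
#' DegradationII < Absent` and assigned by a rule table over per-category
#' intact fractions: `Absent` when no plastome (empty profile);
#' `DegradationII` when any of the `atp`, `rps`, `rpl` categories keeps
#' fewer than half of its genes intact; `Stationary` when (not
#' DegradationII and) `ndh` and `rpo` are fully degraded and the
#' photosynthesis categories `psa`/`psb`/`pet` jointly retain at most one
#' intact gene (the commonly retained psbA); `DegradationI` when any of
#' `psa`, `psb`, `pet`, `rpo` has lost genes beyond ndh-only loss;
#' `Photosynthetic` otherwise (loss confined to `ndh` is permitted). The
#' rule is monotone: degrading an additional gene never moves the stage
#' earlier.
#'
#' @param profile Data frame from [content_profile()] (columns `category`,
#'   `n_intact`, `n_total`), or a result of [classify_catalog()].
#' @return A factor of length 1 with the ordered stage levels.
#' @export
assign_stage <- function(profile) {
  if (!is.data.frame(profile)) profile <- content_profile(profile)
  if (!nrow(profile) || sum(profile$n_total) == 0L) {
    return(factor("Absent", levels = STAGE_LEVELS, ordered = TRUE))
  }
  if (any(profile$n_intact < 0 | profile$n_intact > profile$n_total)) {
    stop("intact counts outside [0, n_total]")
  }
  frac <- function(cc) {
    i <- match(cc, profile$category)
    if (is.na(i) || profile$n_total[i] == 0L) NA_real_
    else profile$n_intact[i] / profile$n_total[i]
  }
  n_int <- function(cc) {
    i <- match(cc, profile$category)
    if (is.na(i)) 0L else profile$n_intact[i]
  }
  stage <- "Photosynthetic"
  housekeeping <- c("atp", "rps", "rpl")
  hk <- vapply(housekeeping, frac, numeric(1))
  photo_intact <- n_int("psa") + n_int("psb") + n_int("pet")
  if (any(!is.na(hk) & hk < 0.5)) {
    stage <- "DegradationII"
  } else if (isTRUE(frac("ndh") == 0 || is.na(frac("ndh"))) &&
             isTRUE(frac("rpo") == 0 || is.na(frac("rpo"))) &&
             photo_intact <= 1L) {
    stage <- "Stationary"
  } else {
    early <- vapply(c("psa", "psb", "pet", "rpo"), frac, numeric(1))
    if (any(!is.na(early) & early < 1)) stage <- "DegradationI"
  }
  factor(stage, levels = STAGE_LEVELS, ordered = TRUE)
}

#' Compare gene loss and pseudogenization between two species
#'
#' @param matrix Content matrix data frame (see [ck_content_matrix()]): a
#'   `gene` column plus one status column per species.
#' @param a,b Species column names; `b` is expressed as a percentage of `a`.
#' @return A list with `lost` and `pseudogene` elements, each holding
#'   `(n_a, n_b, pct_of_a)`; a zero baseline yields `NA` (`undefined`), not
#'   an error.
#' @export
compare_content <- function(matrix, a, b) {
  for (sp in c(a, b)) {
    if (!sp %in% names(matrix)) stop("unknown species: ", sp)
  }
  one <- function(status) {
    n_a <- sum(matrix[[a]] == status)
    n_b <- sum(matrix[[b]] == status)
    pct <- if (n_a == 0L) NA_real_ else round(100 * n_b / n_a, 1)
    list(n_a = n_a, n_b = n_b, pct_of_a = pct)
  }
  list(lost = one("lost"), pseudogene = one("pseudogene"))
}
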