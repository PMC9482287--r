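---
title: "Methods: plastome degradation staging and plastid-to-mitochondrion transfer classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome degradation staging and plastid-to-mitochondrion transfer classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miptkit)
```

## The biological problem

Holoparasitic plants obtain all nutrients from a host and no longer
photosynthesize. Released from selection, their plastid genomes decay:
genes pseudogenize, then disappear, in a broadly conserved order —
NADH-dehydrogenase (*ndh*) genes first, then photosystem (*psa*/*psb*),
cytochrome b6/f (*pet*) and plastid RNA polymerase (*rpo*) genes, and only
late the ATP synthase and ribosomal-protein genes. The quadripartite
architecture (long and short single-copy regions flanked by two inverted
repeats) contracts alongside. At the same time the mitochondrial genome,
whose own gene content is barely affected by parasitism, accumulates
plastid-derived DNA fragments. Each such fragment has a history: it came
either from the plant's own plastid (intracellular transfer, IGT) or from
another species' plastid (horizontal transfer, HGT), the latter typically
via the haustorial bridge to a current or historical host. `miptkit`
implements the full analysis — classification, staging, structure,
detection, phylogenetic attribution, and pathway completeness — on genomes
and trees supplied by the user or built by its seeded generator.

## Gene-status classification

Each gene is compared with its reference-catalog counterpart
(`classify_gene()`):

* **lost** — no locally aligned segment reaches the homology gate
  (significance `evalue`, default `1e-10`, the same gate as the transfer
  scanner);
* **pseudogene** — homologous but defective: an in-frame stop strictly
  before the final codon of the aligned reference span
  (`premature_stop`), a translated length below `tau_len` (default 0.5) of
  the reference translated length (`too_short`), or nucleotide identity
  below `tau_id` (default 0.6) over the aligned region
  (`excess_divergence`);
* **intact** otherwise.

Structural RNAs (tRNA/rRNA) skip the translation tests and are judged on
homology, identity and length alone. The thresholds are deliberately
conservative and configurable (`classify_params()`); no canonical values
exist for them in the literature, and whether "significant difference from
the reference" is best read as a statistical test or as curation is an
open question — the identity threshold is our operationalization.

Counting conventions matter in plastomes because the inverted repeat
duplicates genes. `count_by_status(unit = "row")` counts annotated copies
(an IR-duplicated rRNA contributes two), which is how annotation totals
are conventionally reported; `unit = "symbol"` collapses duplicates with
the better status winning, which is the right unit for cross-species
content matrices and for category profiles used in staging.

## Degradation staging

`assign_stage()` maps a per-category intact profile to one of the five
ordered stages:

| Stage | Rule |
|---|---|
| Absent | empty profile (no plastome) |
| DegradationII | any of `atp`, `rps`, `rpl` below 50% intact |
| Stationary | `ndh` and `rpo` fully degraded **and** `psa`+`psb`+`pet` jointly retain at most one intact gene (the commonly persisting *psbA*) |
| DegradationI | any of `psa`, `psb`, `pet`, `rpo` has losses beyond *ndh*-only loss |
| Photosynthetic | otherwise; loss confined to `ndh` is permitted |

Two design points. First, the rule is monotone: degrading one more gene
can never move a genome to an earlier stage (verified by a property
test). Second, *rbcL* is deliberately **not** a DegradationII trigger:
genomes in the Stationary stage can have lost *rbcL* while retaining their
`atp`/`rps`/`rpl` complement, so treating its single-gene category as a
late-stage trigger would misclassify exactly the profile the stage is
meant to describe. Under these rules the bundled holoparasite profile
lands in Stationary, the *Lathraea*-like profile in Degradation I, and an
all-intact profile in Photosynthetic.

## Quadripartite structure detection

`find_inverted_repeats()` finds the maximal pair of disjoint segments on
the circle where one is the near-reverse-complement of the other: exact
k-mer anchors (k = 21) between the doubled sequence and its reverse
complement are grouped by diagonal, runs are extended greedily, and the
best pair partitions the circle into IRa/IRb plus a long and a short
single-copy arc. Defaults `min_len = 1000` bp and `min_identity = 0.99`
reflect that plastome IRs are long and near-identical; no method or
threshold is canonical for this step, so both are configurable. With
`min_identity < 1` extension uses an X-drop rule (match +1, mismatch −2,
drop 20) and trims back to the best-scoring endpoint; with
`min_identity = 1` extension is exact. Doubling the sequence makes
detection work when a repeat spans the linearization origin, which is what
makes the reported region lengths rotation-invariant. Ambiguous equal-arc
ties are broken deterministically by start coordinate, and output is
normalized to start at the LSC, the common plastome convention. A
quadratic dynamic-programming search over all substring pairs is the test
oracle at toy scale.

## Transfer detection

`scan_homology()` is a small seeded aligner: 13-mer anchors against both
strands of every reference gene, same-diagonal chaining across gaps of at
most `join_gap = 50` bp, X-drop extension (match +1, mismatch −2, drop
12), and a Karlin–Altschul-style significance `E = K·m·n·exp(−λS)` with
the ungapped nucleotide constants (λ = 1.28, K = 0.46). Only hits with
`E < 1e-10` are reported — at that gate a hit needs roughly 35 bp of
near-exact match, so chance 13-mer anchors in hundreds of kilobases of
mitochondrial sequence are never reported. Nearby same-gene hits are
merged (no standard convention exists for when split local alignments
count as one insertion; `join_gap` is ours).
The same `HomologyHit` table can be read from or written to 12-column
BLAST tabular files, so a precomputed BLASTN run can be substituted for
the built-in scanner without touching downstream code.

`check_orf_completeness()` declares a fragment translatable only if it
contains the reference's full CDS span with an intact start, terminal
stop, and no frame-breaking internal stop — fragments that are proper
substrings of their source CDS are incomplete by construction.

## IGT / HGT classification and the fragility audit

`classify_transfer()` operationalizes nestedness, which the decision rule
needs but the literature leaves informal: walking rootward from the query
tip, the *smallest enclosing clade with bootstrap support above
`min_support`* (default 70, strict inequality) is the query's attachment.
If its other tips all belong to the parasite's own lineage (Lamiales /
Orobanchaceae) and that lineage plus the query forms a supported clade,
the fragment is intracellular (IGT). If the lineage minus the query is
itself a supported clade while the query attaches inside a single foreign
group, the fragment is horizontal (HGT) and that group is the donor — we
require the lineage clade to be *supported*, not merely observed, the
stricter of the two readings of the rule. Everything else is
undetermined, including fragments whose alignments carry fewer than
`min_sites` (default 3) parsimony-informative sites ("too short").
Missing support labels are treated as unsupported, matching the
convention of hiding bootstrap values at or below 50%. The verdict is
invariant to tip-order permutation and to rerooting along the outgroup
edge, and raising the gate can only move calls toward undetermined (both
property-tested).

`audit_sites()` asks whether a donor call survives scrutiny of its
alignment: among parsimony-informative columns, it counts those where the
query shares its base exclusively with one candidate group, then flips
the query base at each supporting column to the opposing group's state
and recounts. A call is *fragile* when a single flip changes the winning
group. In the bundled rpl20-style alignment exactly one column (position
187, an A/G contrast) attaches the query to Lamiaceae, so the audit
reports fragile with pivotal site 187. Fragile calls are **not**
auto-demoted: a topology-based verdict resting on one site is a finding
to report, not to erase — demotion is available as
`run_config(demote_fragile = TRUE)`.

`build_nj_tree()`/`bootstrap_support()` provide a deliberately small
tree builder (neighbor joining on p-distances, seeded column resampling,
clade counts via `ape::prop.clades`) so fixture trees can be built
end-to-end; maximum-likelihood inference is out of scope, and user trees
are consumed as Newick with support labels.

## Pathway completeness

`map_expression()` counts detected genes per pathway component and
reports off-pathway evidence separately rather than dropping it.
"Detected" is a caller-supplied boolean — the package does not quantify
expression, matching how transcriptome evidence is used here
(presence/absence). The shipped ko00195 roster is a frozen synthetic
63-gene list (30 plastid + 33 nuclear) with an alias table for
subunit-style names (alpha/beta/C/B → `atp` symbols); exact KEGG
membership is version-dependent, so the roster is data, not code, and can
be edited. Component placement follows the analysis convention of
counting *petB*/*petD* under photosynthetic electron transport rather
than under the cytochrome b6/f complex. `find_chain_break()` walks an
ordered reaction chain and returns the earliest step with no detected
gene and the last reachable product. In the bundled chlorophyll chain the
evidence detects the nine Hem genes (glutamate → protoporphyrin IX) and
the Mg-chelatase/methyltransferase/cyclase steps, but not the divinyl
reductase (EC 1.3.1.75), so synthesis ends at divinyl
protochlorophyllide; for the break to land there, the intermediate steps
must carry evidence, which the fixture encodes explicitly.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions, fixed once: a 96,074 bp
plastome (LSC 30,072, SSC 480, IR 32,761 × 2) with 68 intact gene copies,
the 11 named pseudogenes and 40 reference genes absent; a three-chromosome
mitogenome (87,933 / 303,254 / 241,909 bp) carrying 75 local genes
(39 protein-coding, 26 tRNA, 10 rRNA, split 9/28/38) with all 24 core
genes and nine planted plastid-derived fragments of eight genes (ycf2
twice), all ORF-incomplete; donor trees reproducing four IGT placements,
one Orchidaceae attachment (85%, sister clade 64%), two Gentianaceae
attachments (100%), and two fragments too short to place; and expression
tables reproducing the photosynthesis detection pattern (11 genes,
3/2/2/4 by component) and the chlorophyll chain break.

Pseudogene defects are planted with the seeded RNG as either an internal
stop at a position uniform in 10–60% of the CDS or truncation to 40% of
the reference length — both satisfy the classifier's criteria by
construction, and the truncated tail is replaced by intergenic filler so
region budgets stay exact. Filler is i.i.d. nucleotides at GC 35%
(plastid) / 44% (mitochondrial), approximating the reported GC contents
and, more importantly, guaranteeing no spurious homology. Reference gene
lengths default to 300 bp (transferred genes are longer so realistic
sub-fragments can be planted); real gene lengths are irrelevant to the
logic under test. Around every planted boundary — the IR margins and each
fragment flank — a short window is forced to mismatch the would-be
continuation, so greedy extension provably stops at the planted
coordinate and planted-truth recovery at mutation rate 0 is exact rather
than probabilistic.

What the fixtures do **not** emulate: codon-usage or substitution-model
realism, RNA editing, repeats and recombination isoforms of real plant
mitogenomes, assembly error, or annotation ambiguity. Passing tests
therefore demonstrate the correctness of the classification, detection
and decision logic under controlled truth — not robustness to the
annotation noise of real accessions. Species gene-content tables beyond
the documented totals, and the mitochondrial content table, are synthetic
fill (marked `synthetic` in their filenames): per-species totals are
encoded exactly where documented, gene identities are arbitrary but
consistent. One such total is internally inconsistent in its source (a
hemiparasite reported with one gene lost alongside a 4–4.6× loss ratio
for genomes with 40+ losses); the table encodes the printed per-species
counts and no test asserts the irreconcilable ratio.

## Numerical choices and degenerate inputs

Seeds: every stochastic step (fixture assembly, defect placement,
bootstrap resampling) runs under a caller-supplied seed through an
RNG-state-preserving wrapper, so identical spec + seed give byte-identical
outputs and library calls never disturb the user's RNG. Reference
catalogs use fixed internal seeds so all generators share one consistent
reference. Degenerate inputs are defined, not errors: a circle with no
repeat partitions as a single LSC; a zero-baseline region comparison
returns `NA` with a warning; an empty homology result is a valid scan;
an empty profile stages as Absent. Division and rounding: region changes
and comparison ratios are reported to one decimal in percent.

## Problem sizes used by the test suite

The suite runs the full-size study fixtures once each (96 kb plastome,
633 kb mitogenome scan) and scales the property sweeps down so the whole
suite stays within a few minutes on one CPU: monophyly versus the
exhaustive oracle on ≥ 1,000 random subset cases over 4–8-tip trees,
partition-length conservation on 500 random circular fixtures of 0.5–3 kb,
rotation/reverse-complement invariance on 40 planted-repeat toys, and
planted-truth transfer recovery across 100 seeds on 9 kb chromosomes.
These sizes were chosen as the smallest that still exercise every code
path several hundred times.

## Known limitations

* The homology scanner is ungapped; indel-containing transfers would be
  reported as chained split hits rather than one gapped alignment (the
  chaining margin covers small indels only).
* The significance approximation uses fixed ungapped constants; it is a
  gate, not a calibrated BLAST e-value.
* Nestedness classification requires a correct tip-to-group map and a
  designated outgroup; reticulate histories (multiple donors per gene)
  are outside the model.
* The interface is the exported functions plus `run_all()` and the
  acceptance script; no shell entry point is shipped, as the package is a
  library, not a command-line tool.
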