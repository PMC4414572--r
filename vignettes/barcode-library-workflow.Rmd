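---
title: "Building and auditing a DNA barcode reference library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and auditing a DNA barcode reference library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodelib)
```

## The problem

A DNA barcode reference library is a curated set of specimens whose COI-5P
sequences, species identifications and metadata are good enough to support
identification of unknown queries. Curating one means answering, record by
record: is the sequence of barcode quality? does the name on the specimen
exist in the nomenclatural baseline (a taxonomic checklist), and if not, is
it a synonym, a typo, a species described after the checklist, or genuinely
new? and do the sequence clusters (OTUs, "BINs") agree with the names?

`barcodelib` implements that workflow as composable steps — QC, distances,
clustering, name reconciliation, concordance audit, library assembly,
summary tables — plus a synthetic-data generator with a planted-truth ledger
so every step is testable end to end without touching any external database.

## Quality control

A record passes QC when its sequence is **longer than** `min_length`
(default 500 bp, counted over non-gap characters), carries **strictly fewer**
ambiguous bases than `max_ambiguity_fraction` (default 1%) of its length,
and (for library membership) bears a species-level name. Both operators are
taken literally: a 501 bp sequence passes, a 500 bp one does not; exactly 1%
Ns fails. Failures carry every applicable reason code
(`NO_SEQUENCE`, `TOO_SHORT`, `TOO_AMBIGUOUS`, `NO_SPECIES`); an empty
sequence reports `NO_SEQUENCE` and `TOO_SHORT` but not `TOO_AMBIGUOUS`,
whose fraction is undefined at length zero.

## Distances

Sequences are compared only when pre-aligned to equal length; COI-5P
barcodes are effectively indel-free within an insect order and are anchored
at the 5' primer end, so truncated reads can be right-padded with gaps
(`pad_sequences()`) rather than re-aligned. Any site where either sequence
carries a gap or an ambiguity code is excluded (**pairwise deletion**). The
uncorrected distance is $p = P + Q$ where $P$ and $Q$ are the transition
(A↔G, C↔T) and transversion fractions over the comparable sites. The
Kimura 2-parameter distance is

$$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

which always satisfies $d \ge p$, with equality exactly at $p = 0$. When the
logarithm's argument is non-positive the distance is saturated; the value is
flagged undefined (`NA` plus a classed warning) rather than silently set to
infinity, and matrix construction turns it into an error naming the pair.

Whether BOLD's own K2P uses pairwise or complete deletion of ambiguous sites
is not documented; pairwise deletion is the common choice for barcode data
and the one used here, so divergence values may differ slightly from
BOLD-reported ones on records with many Ns.

Per-species divergence summaries treat the $n(n-1)/2$ within-species
pairwise distances as observations: the reported SE is the sample standard
deviation of those pairs divided by $\sqrt{\text{pairs}}$. Pairs sharing a
specimen are not independent, so this SE is a descriptive summary, not a
basis for inference. Species whose mean exceeds 2% (strictly) are flagged as
potential cryptic complexes.

## BIN-style clustering

OTUs are assigned by a staged process on **uncorrected** distances:

1. **Single linkage at a threshold** (default 0.022, the published seed
   threshold for BIN-style clustering of COI barcodes): two sequences share
   an initial cluster iff a chain of pairs each ≤ the threshold connects
   them.
2. **Markov-clustering refinement** within each initial cluster of size ≥ 3:
   edge weights $\max(0, 1 - d/\text{scale})$ with the scale defaulting to
   the threshold, self-loops at weight 1, expansion 2, inflation 2.0,
   iterated to convergence (max-change < 1e−8, entries < 1e−12 pruned, cap
   100 iterations). The cluster is split along the resulting attractor
   basins. Clusters of size < 3 pass through; a non-converging run keeps its
   cluster unsplit with a warning.

Refinement **only splits**: bins never merge across initial clusters. The
underlying BIN description mentions refinement "within, and between"
clusters; since no merging rule is published, merging is deliberately left
out of the default path rather than guessed — split-only keeps the
single-linkage nesting invariant (bins at a finer threshold nest inside
coarser ones) and is what the tests verify. All iteration orders are fixed
by input order; clustering involves no randomness. Labels are `SYN:NNNN`
ordinals (by first member's input order) and are never real BOLD BIN URIs;
prior `bin_label` values from a download are kept separate and can be
compared via `compare_partitions()` (contingency table + Rand index).

## Name reconciliation

Names are normalized before matching: whitespace collapsed, parentheticals
(subgenera, parenthesized authorships) removed, trailing authorities
stripped, genus capitalized, epithet lowercased, trinomials truncated to the
binomial. Genus-only names and placeholder epithets ("sp.", "cf.", "nr.")
normalize to the empty name and are treated as not identified to species.
A capitalized token directly after the genus is taken as a miscased epithet
(authorities follow an epithet); this heuristic misreads the rare
genus-plus-author string, a documented trade-off.

Resolution order, stopping at the first hit:

1. exact checklist match → `MATCHED`;
2. synonym-table match → `SYNONYM`, `SPELLING_VARIANT`, or
   `POST_CHECKLIST` per the entry's kind (the local table replaces live
   Catalogue-of-Life queries so runs are reproducible);
3. same-genus spelling match: epithet within Levenshtein distance ≤ 2, or a
   Latin gender-suffix swap (-us/-a/-um, -is/-e) on an exact stem →
   `SPELLING_VARIANT`. The same-genus restriction is deliberately
   conservative: congeners' epithets can be close, and a cross-genus fuzzy
   match would fabricate merges;
4. otherwise `TENTATIVE_NEW`. A changed generic combination (same epithet,
   different genus) is *not* auto-resolved — the evidence field carries a
   same-epithet hint and the decision is left to a taxonomist.

Status counts are over distinct normalized input names, so they partition
the name set and sum to its size.

## Concordance and the library

With species counted by accepted (post-reconciliation) name — so synonym
pairs cannot fabricate discordance — each bin is `CONCORDANT` (one named
species), `DISCORDANT` (two or more) or `UNNAMED` (none); unnamed members
never create discordance, because unnamed bins are handled separately as
possible new species records (optionally filtered to bins with records from
a country of interest). Each species is `IDENTIFIABLE` (all its bins
concordant — spanning several concordant bins is fine), `SHARING` (some bin
discordant) or `UNPLACED` (no bin). Both classifications are exhaustive
partitions, and the tests assert the identities (concordant + discordant +
unnamed = bins; identifiable + sharing + unplaced = species).

A record enters the library iff it passes QC, resolves to the checklist
(`MATCHED`, `SYNONYM`, `SPELLING_VARIANT` — `POST_CHECKLIST` stays out
because the checklist is the fixed baseline), and has a bin. Exclusions
carry full reason lists; building is idempotent. Summary products: a
suborder roll-up (records whose higher taxonomy conflicts with the
checklist's placement of their species land in `Not.assigned`), per-family
coverage proportions, concordance triples (family × species-per-bin ×
specimens-per-bin, optionally restricted to specialist-identified records
via an identifier whitelist), and a family × primer success matrix where
success = a non-empty sequence.

## The synthetic generator

`simulate_dataset()` generates the conditions the audit assumes of real
COI-5P data, with guarantees by construction rather than by sampling luck:

- one root sequence; each haplotype cluster's ancestor mutates a
  cluster-specific **disjoint block** of $\lceil \text{inter} \cdot L / 2
  \rceil$ sites, so every between-cluster p-distance is ≥ the configured
  interspecific floor (default 6%);
- specimens add $\mathrm{round}(\text{intra}/2 \cdot L)$ substitutions at
  sites outside all blocks (default intraspecific target 0.5%), bounding
  within-cluster distances above by twice that count; substitutions are
  transition-biased with $P(\text{transition}) = \kappa/(\kappa+2)$,
  $\kappa = 3$ by default, a typical mitochondrial bias;
- realized extremes are measured on the generated matrix and recorded in
  the ledger, not assumed;
- species forced into a `sharing_group` share one ancestor and therefore
  one bin, yielding a known discordance;
- planted artifacts — one-edit misspellings, old-combination synonyms (with
  the synonym-table rows that resolve them), emptied names, sub-500 bp
  truncations, >1% N injections — are chosen from species untouched by other
  artifacts, so each maps to exactly one downstream signal, all recorded in
  the truth ledger.

The generator's defaults (20 species, 3–8 specimens each, 658 bp) are the
scale at which the test suite and the acceptance script run; one pipeline
pass at this scale takes seconds. What the generator does **not** emulate:
indels and alignment error, rate heterogeneity across sites, coalescent
population structure, geographic signal, and the heavy-tailed abundance
distributions of real campaigns. Passing tests therefore demonstrate the
correctness of the bookkeeping and the algorithms under clean separation,
not clustering performance on taxa with a weak barcode gap.

## Degenerate inputs and tie-breaks

Empty matrices give empty partitions; a single sequence is a singleton bin;
a species with one specimen has undefined (NA) divergence statistics and is
never flagged; comparing two sequences with no comparable sites is an
error, not a zero. Spelling resolution ties break toward the smallest edit
distance, then checklist order. MCL node-to-attractor assignment follows
input order. Duplicated checklist names deduplicate (first wins) with a
warning.

## Limitations

- The clusterer is a faithful *style* of the BIN algorithm (threshold
  single-linkage + MCL refinement), not a byte-level reproduction of RESL;
  labels are local to a run.
- Equal-length comparison (with right-padding) presumes 5'-anchored,
  indel-free barcodes; it is not a general aligner.
- The audit of a real BOLD download reuses the download's own `bin_label`
  assignments when asked to; cross-database discordance (the "on BOLD"
  view) depends on the live database and is out of scope.
- Distance computation is quadratic in specimens; at reference-library
  scale (tens of thousands of records) per-species and per-bin subsets are
  the intended unit of distance work, not the full matrix.
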