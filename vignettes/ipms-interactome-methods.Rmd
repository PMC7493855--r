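---
title: "Methods: interactor selection and enrichment analysis for IP-MS studies"
author: "IPMSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactor selection and enrichment analysis for IP-MS studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IPMSelect)
```

# The analysis problem

Co-immunoprecipitation coupled to mass spectrometry (IP-MS) recovers the
proteins that co-purify with a bait protein, but the raw identification list
is dominated by artefacts: proteins from contaminating cell types, proteins
that bind the beads or the antibody scaffold rather than the bait, and
sticky, highly abundant proteins that appear in nearly every pulldown ever
deposited in control repositories. IPMSelect implements the standard
stringent selection used for such studies — here modelled on a two-stage
oligodendrocyte design, with pulldowns performed in oligodendrocyte
precursor cells (OPC) and mature oligodendrocytes (OL) against a matched IgG
control — together with the downstream stage-resolved analysis: differential
expression of the two stages' transcriptomes, partition of the interactome
into shared and stage-specific components, term over-representation, and a
kappa-linked term network.

Because raw data for such studies are frequently unavailable, the package
ships a ground-truth synthetic generator that emulates the study design end
to end, so every stage of the pipeline is testable and its operating
characteristics (precision, recall, error calibration) are measurable.

# The interactor filter cascade

Each protein identified in a stage's bait channel passes through three
independent predicates, applied in this order for accounting purposes:

1. **Lineage (specificity) filter.** The protein's gene must be expressed
   (non-zero counts) in the matching stage's transcriptome. This removes
   identifications originating from other cell types in the culture.
2. **Enrichment (reliability) filter.** The protein must either be
   undetected in the IgG control channel, or its log2 bait/control LFQ ratio
   must *strictly* exceed the threshold (default 2, i.e. more than
   four-fold). The strictness matters at the boundary: a ratio of exactly
   four fails.
3. **Contamination filter.** Using a CRAPome-style repository of proteins
   recurrently seen in control pulldowns, a protein is flagged when its
   repository max spectral count strictly exceeds 200, or when (number of IP
   experiments × max spectral count) strictly exceeds 100. The multiplier
   defaults to the study's own IP experiment count (2, one per replicate
   pulldown); the alternative reading — the repository's own detection
   count — is one configuration flag away
   (`productUsesRepositoryCount`), because the verbal form of this rule is
   genuinely ambiguous. Proteins absent from the repository carry no
   evidence and are never flagged.

A `FilterLedger` records the count at every stage; its validity method
enforces the accounting identities
(`n_after_lineage = n_identified − n_lineage_removed`,
`n_final = n_enrichment_pass − n_contaminants`), and the pooled ledger
counts unique proteins across stages, so the final interactome is the union
of the per-stage final sets.

## Normalization against the control

The bait and IgG channels come from separate purifications, so their
intensity scales differ. Two normalizations are provided:

- **`median-ratio`** (default): the bait channel is divided by the median
  per-protein bait/control ratio over proteins detected in both channels.
  This is the size-factor convention: it assumes only that *most*
  co-detected proteins are non-specific background with a true ratio of 1 —
  exactly the assumption an IgG comparison rests on.
- **`equal-total`**: the bait channel is rescaled so the two channels'
  totals match.

Median-ratio is the default for a structural reason. A successful pulldown
concentrates real interactors in the bait channel, so the bait channel's
*total* intensity is inflated by the very signal the filter is looking for.
Equal-total scaling divides that inflation back out of every protein: in
the default synthetic scenario (a quarter of proteins enriched around
eleven-fold) it removes about two log2 units from every ratio and collapses
cascade recall from ≈0.97 to ≈0.37. The median, by contrast, sits in the
background mass and is unaffected until enriched proteins approach half of
all co-detected proteins. Equal-total scaling remains available for data
already known to be balanced.

Normalization is applied per replicate experiment (each has its own
bait/control pair), before replicates are combined. Replicate combination
defaults to union — a protein counts as identified if seen in any
replicate, keeping the maximum intensity and spectral count per channel —
with intersection available for stricter use.

# Stage-resolved expression analysis

**RPKM.** `computeRpkm()` uses
`count × 1e9 / (library_size × gene_length_bp)` with library size the
per-sample count total.

**Differential expression.** `deTest()` pools counts within stage and
compares the two pooled proportions with a z-statistic. A naive
two-proportion test treats the pooled count as binomial, which is badly
anticonservative for replicated RNA-seq: biological replicates are
overdispersed, and at a negative-binomial dispersion of 0.1 the naive
test's null type-I error at the 0.05 level is roughly 0.3. `deTest()`
therefore plugs a common negative-binomial dispersion into the variance of
each pooled proportion. The dispersion is estimated once, across genes,
from within-stage replicate variation by maximizing the Cox–Reid adjusted
profile likelihood (`estimateCommonDispersion()`); the adjustment removes
the downward bias — a factor of about (n−1)/n — that comes from fitting a
per-gene, per-stage mean on few replicates. With the correction the
statistic is calibrated (measured null type-I ≈ 0.04–0.05 at dispersions 0,
0.1 and 0.3) and reduces exactly to the classic two-proportion z-test when
the estimated dispersion is 0. This is a deliberately simple substitute for
a full per-gene GLM framework: one global dispersion, no trend, no
shrinkage of fold changes — adequate for a two-group triplicate design,
and documented as not identical to any specific published DE method.

The log2 fold change is computed from stage-mean RPKM with a pseudo-RPKM of
1 added to both means (avoiding division by zero and damping low-abundance
noise); the sign convention is positive = higher in OL. A gene is classed
`OL_up` when `fdr < 0.05` and `log2FC > 1`, `OPC_up` for the mirrored
condition, `NS` otherwise; p-values are BH-adjusted across genes.

**Partition and cross-tabulation.** `vennPartition()` splits the two stage
interactomes into shared and stage-specific sets;
`stageCrosstab()` tallies each stage-specific set by DE class (up in own
stage / up in the other stage / NS) with percentages reported to two
decimals, matching the reporting convention of such studies.

**Heatmap matrix.** `heatmapMatrix()` returns `log2(rpkm + 1)` for a gene
panel, with rows and columns ordered by agglomerative hierarchical
clustering (average linkage, Euclidean distance — unstated in typical
figure legends, so these conventional choices are exposed as the
defaults and documented here). The display copy is clipped to [0, 8],
matching the usual colour-scale range; the unclipped matrix is always
returned, and any analysis uses it. Clustering uses `stats::hclust`, whose
tie-breaking by input order makes the ordering deterministic.

# Term enrichment and the kappa network

`enrichTerms()` computes, per term, the hypergeometric upper-tail
probability P[X ≥ k] of observing k query genes in a term of K universe
genes, for a query of n drawn from a universe of N (`stats::phyper`, exact
and numerically stable). Term membership is intersected with the universe
before counting. Significance follows the raw-p convention (`p < 0.01`)
used by ClueGO-style analyses; the BH FDR is reported alongside and can be
made the criterion instead. Multi-category collections are corrected
jointly by default, per-category by flag. The default universe is the set
of genes expressed in the relevant stage — the most defensible background
when the query itself was lineage-filtered — and is an explicit argument.

`kappaScore()` is Cohen's kappa on the 2×2 membership table of two gene
sets over a universe, with the Pe = 1 degenerate case defined as 1.
`buildTermNetwork()` connects enriched terms whose memberships —
intersected with the query, following the ClueGO convention that term
similarity is assessed among the genes actually observed — reach kappa ≥
0.4 (inclusive at the boundary). Edge weight is the kappa score; node size
is carried as −log10(p); a bipartite layer links each term to its query
genes. Networks serialize to GraphML (via igraph) and plain edge-list TSV;
layout and rendering are out of scope.

# The synthetic-data generator

`simulateStudy()` emulates the study design: two IP replicate experiments
per stage, two stages, a transcriptome in triplicate per stage, and an
annotated gene-set collection sharing one gene namespace with the proteins
(a mapping file is unnecessary by construction, though the readers accept
one-to-one foreign tables).

Protein labels partition into true interactors (25%), repository
contaminants (8%), non-lineage proteins (7%) and non-specific background
(60%). The generative model, chosen as the simplest that exercises every
filter branch:

- Abundance is log-normal (log10 mean 5, sd 0.5), with per-replicate,
  per-channel log10 measurement noise of sd 0.1 — about 26% CV, a typical
  LFQ replicate spread — and a 95% per-replicate detection probability.
- True interactors multiply their bait channel by 2^x,
  x ~ Normal(3.5, 0.8); 30% of them are never detected in the control
  channel (the bait-only detection route). 45% are present at both stages,
  30% only in OPC, 25% only in OL, giving a realistic shared/specific
  partition.
- Contaminants are sticky abundant proteins: bait-enriched
  (x ~ Normal(3, 1), so most pass the enrichment filter and must be caught
  by the repository rules) with Poisson spectral counts of mean 300 in both
  channels. In the repository table they receive a max spectral count over
  200 with probability 0.7 and otherwise one in (50, 200] that triggers the
  product rule; non-contaminants stay at or below 40, under both rules.
- Other spectral counts are Poisson with mean increasing in LFQ rank.
- Non-lineage proteins look like interactors in the quant tables but their
  genes have zero counts in every transcriptome sample, so only the lineage
  filter can remove them.
- The transcriptome is negative-binomial (dispersion 0.1, three samples per
  stage, mild log-normal library-size variation), 3000 genes; 12% of
  expressed genes are shifted by |log2FC| = 2, split evenly between stages.
  Gene lengths are log-uniform in [500, 10000] bp.
- The collection holds 40 terms of 10–80 genes; 4 planted terms are
  composed 70% of true-interactor genes, so they are detectably enriched in
  a well-recovered interactome.

Everything is deterministic under `seed`; sub-generators use fixed offsets
from it so each is individually reproducible.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: correlated contamination structure (real CRAPome
frequencies correlate with abundance class), missingness that depends on
intensity, isotope or fractionation artefacts, batch effects between
replicates, transcript-level length biases, or annotation terms with the
dependency structure of a real ontology. Results on the synthetic scenario
demonstrate that the implementation recovers the truth of its own model,
not that the thresholds are optimal for any particular real dataset.

# Numerical and design choices

- All rule inequalities are strict (`> 2`, `> 200`, `> 100`) and the kappa
  edge rule is inclusive (`≥ 0.4`), matching how these rules are
  conventionally printed; boundary cases are tested explicitly.
- The ratio pseudo-intensity (default 1) is added to both channels only
  when the control is non-zero; bait-only detections have an undefined
  (NA) log2 enrichment and pass by the detection rule instead.
- Top-term selection orders by ascending p, then descending overlap k,
  then term id — a total, deterministic order.
- Ledger identities are enforced by S4 validity, so inconsistent
  accounting cannot be represented.
- Degenerate inputs: an empty expressed set errors (a missing
  transcriptome is a usage error, not an empty result); an empty final
  interactor set is valid with a warning; an empty enrichment result
  yields an empty, still-serializable network; zero-count genes get p = 1
  and class NS, flagged `all_zero`.
- Problem sizes in the test suite are the generator defaults (600
  proteins, 3000 genes) with 2000-gene null calibrations — sizes at which
  the binomial error of a type-I estimate (±0.005) is well inside the
  ±0.015 band being checked.

# Limitations

- The DE statistic uses one common dispersion; strongly gene-specific
  dispersion would call for a per-gene GLM framework instead.
- The enrichment model is the plain hypergeometric; no ontology topology,
  term redundancy collapsing, or meta-analysis across categories.
- The contaminant rules are threshold rules on repository summaries, not a
  probabilistic interaction score; proteins absent from the repository are
  trusted.
- `stageCrosstab` treats genes missing from the DE table as NS (logged),
  which is the conservative choice but can understate stage association if
  the DE table is incomplete.

# A minimal run

```{r example, eval = FALSE}
res <- runPipeline(list(seed = 7L), outdir = tempfile("ipms-run-"))
ledgerCounts(filterLedger(res$calls))
res$summary$venn
```

The run directory contains the interactor calls and ledgers, the DE table,
Venn partition, cross-tab, heatmap matrix with row/column orders, per-stage
enrichment tables and GraphML/TSV networks, a `summary.json` echoing every
count, and a log with the seed and config hash for provenance.
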