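---
title: "Designing and running KASP diagnostics with kaspdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and running KASP diagnostics with kaspdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspdx)
library(dplyr)
```

## The problem

Cryptic species complexes cannot be told apart morphologically, and
single-locus barcodes (such as the mitochondrial COI fragment
traditionally used for *Bemisia tabaci*) misassign a substantial
fraction of individuals relative to genome-wide data. Genome-wide SNP
genotyping (e.g. reduced-representation sequencing) resolves the
populations reliably but is too slow and expensive for routine
monitoring. A practical middle road is a small panel of *diagnostic
SNPs* — loci at which two sets of populations are fixed for opposite
homozygous alleles — assayed with Kompetitive Allele-Specific PCR
(KASP): two allele-specific primers carry tails that release FAM or HEX
fluorophores, so a single endpoint fluorescence read encodes the
bi-allelic genotype.

`kaspdx` implements the complete computational side of such a
diagnostic:

1. **panel design** — find fixed homozygous differences in a labelled
   genotype matrix, including *scope-restricted* markers that are only
   diagnostic within a subset of populations; check flanking sequence;
   emit assay-submission sequences; build a hierarchical decision key;
2. **genotype calling** — turn raw FAM/HEX endpoint reads into
   `XX`/`XY`/`YY`/`no_call` states with no-template-control (NTC) and
   cluster-quality gating;
3. **classification** — walk each sample through the decision key with
   fallback and confirmation markers;
4. **concordance** — score assignments and per-marker calls against a
   reference genotyping, reproducing the published validation summaries
   of the packaged cassava *B. tabaci* panel;
5. **synthetic data** — generate genotype matrices and fluorescence
   plates with known truth, so that 1–4 are testable end to end without
   any sequencing data.

## Diagnostic markers and the decision key

A marker is a locus with alleles X and Y (X is the FAM-labelled allele
throughout) and a bipartition of its *scope*: the set of groups within
which every sampled individual is homozygous for one of the two
alleles. `find_diagnostic_loci()` applies a strict fixation rule: a
group counts as fixed only when 100% of its non-missing calls are
homozygous for one allele *and* its call rate is at least
`min_call_rate` (default 0.8). The published markers are strict fixed
differences, so no fixation tolerance is exposed; the call-rate floor
is a parameter because genotype matrices from reduced-representation
sequencing have appreciable missingness. Full-scope and within-subset
searches are deliberately separate calls, mirroring the two-stage
manual search that produced the original panel (genome-wide markers
first, then markers valid only within `{SSA-ECA, SSA-WA}` or
`{SSA-ESA, SSA-CA}`).

`build_decision_tree()` assembles the key greedily: at each node, among
markers whose scope covers the current group set and whose bipartition
splits it, the most balanced split wins. Ties are broken by the
marker's position in the input table — not alphabetically — because the
natural input order (the order markers are published and reported in)
then reproduces the published flow chart exactly: the gateway marker
BTS99-319 at the root, BTS141 before its complement BTS613, and
BTS46-203 before its alternative BTS1161. A marker that induces the
same split as the chosen one is attached to the node as a
*confirmation* marker; the first confirmation doubles as the *fallback*
consulted when the primary call is heterozygous or missing. This
follows the published protocol, where heterozygous BTS46-203 calls were
re-tested with BTS1161.

Classification (`classify_sample()`) is a deterministic key, not a
probabilistic assignment: a heterozygous or missing call at a decisive
node without a usable fallback yields `unresolved` rather than a forced
call, and a homozygous confirmation call pointing at the other side of
a split yields `unresolved` with a `confirmation_discordant` flag. A
sample with no amplification at all (every marker `no_call`, or an
explicit `amplified = FALSE` flag) is `non-target`: the gateway
marker's conventional PCR does not amplify non-cassava *B. tabaci*, so
absence of product is a species filter that precedes any genotype
logic.

## The endpoint caller

The commercial cluster-calling step is visual; no algorithm is
published. The caller here is a deterministic, auditable stand-in for
the "only samples in distinct clusters are scored" judgement. Signals
are background-subtracted (post-read minus pre-read, floored at zero)
and expressed in polar form: `theta` is the angle in degrees from the
FAM (allele X) axis toward the HEX (allele Y) axis, `magnitude` the
Euclidean norm. Three gates follow, per plate and marker:

* **NTC gate.** Sample wells whose magnitude does not exceed
  `ntc_factor × (mean + ntc_k × SD)` of the plate's NTC magnitudes
  (defaults 2.0 and 3) are `no_call("low signal")`. With no NTC wells
  the caller refuses to run unless `ntc_free = TRUE` supplies an
  absolute floor. NTC wells themselves are never genotyped; a
  fluorescent NTC is flagged as possible contamination.
* **Band assignment.** Fixed angular bands map angle to state: XX in
  `[0°, 30°)`, XY in `[30°, 60°]`, YY in `(60°, 90°]`. The heterozygous
  band is symmetric around 45° because dual dye incorporation yields
  intermediate signal. Absolute bands (rather than cluster rank) mean
  plates carrying only one or two genotype classes — common in
  practice — are still called correctly.
* **Cluster-quality gate.** Well angles are clustered by deterministic
  1-D k-means (quantile-initialised Lloyd iterations) with k chosen
  from 1–3 by mean silhouette width. A multi-cluster candidate is
  eligible only when its cluster centres fall in distinct genotype
  bands: true genotype clusters are at least a band apart by assay
  design, so a high-silhouette split *within* one band is noise, not
  structure, and collapses to k = 1. Wells with silhouette below
  `quality` (default 0.5), or lying within `band_margin` (default 5°)
  of a band boundary while their cluster centre sits in a different
  band, are `no_call("ambiguous cluster")`.

These defaults are declared, not inferred — the published criterion is
visual and carries no numeric threshold. The caller is invariant to
well order and to global rescaling of all fluorescence values, and its
errors degrade safely: on simulated plates the average number of wrong
(non-`no_call`) calls does not increase with channel noise up to twice
the default noise level (10% of the cluster magnitude). Beyond that the
genotype clusters physically overlap and occasional wells land deep
inside the wrong band looking exactly like good calls; no endpoint
caller can reject those without rejecting everything, which is why the
safety property is stated over the assay's operating range.

## The synthetic-data generator

`simulate_genotype_matrix()` emulates the discovery cohort: named
groups at their study sizes (the packaged default,
`canonical_group_sizes()`, is the 217-individual six-haplogroup
cohort), planted diagnostic loci that are fixed homozygous within
scope and uniformly `XX`/`XY`/`YY` outside it, background loci drawn
independently of group under Hardy–Weinberg proportions with
minor-allele frequencies uniform on (0.05, 0.5), and per-call
missingness (default 0.02). Per-call heterozygous perturbation
(`het_rate`) and `apply_allelic_dropout()` (heterozygotes collapsing to
random homozygotes, as happens at low read depth in RAD data) are off
by default: the real within-haplogroup heterozygosity and missingness
of the source matrix are not published, so these defaults are free
parameters chosen at realistic post-filtering levels, not estimates.

`simulate_plate()` places each sample well on the polar ray of its
genotype cluster (defaults 10°/45°/80°, magnitude lognormal around
1000 with sdlog 0.05) plus Gaussian channel noise (default SD 50, i.e.
5% of the cluster magnitude), and NTC wells near the origin at 5% of
the sample magnitude. Pre-reads are 5% of the post-read plus
proportional noise — the pre-read exists for background subtraction but
no published values constrain it, so the baseline fraction is a
declared convention. What the generator does *not* emulate: plate
spatial effects, dye cross-talk, amplification failure of specific
wells, multi-modal NTC contamination, or linkage between loci. Passing
tests therefore demonstrate the correctness of the *algorithms* under
the stated noise model, not the field performance of any particular
assay.

## Numerical conventions

* Genotypes are unordered nucleotide pairs (`"A/G"` ≡ `"G/A"`,
  missing `"./."`); reports use colon notation (`"A:G"`). Malformed or
  half calls normalise to missing.
* All reported percentages round half away from zero to one decimal
  (`round_half_up()`); this is the only rounding rule that reproduces
  every published validation percentage from its printed counts
  (151/152 → 99.3, 72/73 → 98.6, 39/41 → 95.1, 33/41 → 80.5,
  28/152 → 18.4).
* Coordinates are 1-based inclusive. Submission sequences render the
  variant site as `[X/Y]` in the marker's allele order regardless of
  which allele the reference carries; a reference base matching neither
  allele is a hard error (a strand or representation mismatch should
  never be silently "fixed").
* Heterozygous calls against a homozygous reference expectation count
  as mismatches in concordance rows.
* Degenerate caller inputs: a well with zero signal on both channels
  has no defined angle and is `no_call`; plates with fewer than three
  live wells, or all-identical angles, skip clustering (k = 1,
  quality 1).

## The packaged panel and validation data

`load_canonical_panel()` returns the seven-marker panel for the six
cassava *B. tabaci* haplogroups, with primer sequences, amplicon
coordinates and reference-method metadata attached. Two
idiosyncrasies are preserved deliberately:

* **BTS1161 allele labels.** The KASP-space alleles (C:C for SSA-ESA,
  A:A for SSA-CA) differ from the reference-method (NextRAD-space)
  labels for the same marker (A:A / G:G). The correspondence (strand
  or locus representation) is not documented, so the panel stores both
  and converts neither.
* **Genome coordinates.** The exact SNP positions within the published
  amplicon ranges are not public, so panel markers carry `null`
  coordinates (the amplicon ranges ride along as metadata) and the
  simulator substitutes synthetic per-marker contigs when planting
  loci.

The validation summaries ship as count-level CSV fixtures
(`load_validation_counts()`): the 152-sample haplogroup confusion
counts, per-marker call counts by reference class, and COI labels by
haplogroup. `validation_cohort()` expands them to per-sample tables
with synthetic ids (the per-sample appendix is not redistributed; any
expansion consistent with both marginals gives identical concordance
results). Two published inconsistencies are handled as follows: the
per-marker class sizes at BTS141 (35 + 117) do not decompose from the
haplogroup-level counts (34 SSA2/SSA4 samples) — two reference calls
were missing at that marker — so marker rows are computed from their
own published counts rather than from the confusion fixture; and the
misidentification arithmetic of the legacy barcode requires treating
recorded-but-ambiguous COI labels (SSA1-SG2, SSA1-SG1/SG2, SSA3, each
compatible with more than one haplogroup) as misidentifications, which
is how `coi_mismatch_summary()`'s default map encodes them (explicit
`NA` entries). Labels absent from the map entirely are tallied
separately as unmappable; the two correctly-grouped SSA-CA samples,
whose COI labels are not individually published, carry the placeholder
label `"unknown"` in the fixture and fall in that category.

## A worked run

```{r demo}
demo <- run_demo(seed = 7)
demo$summary[c("n_samples", "n_diagnostic_found_full_scope",
               "n_diagnostic_found_scoped", "concordance_pct")]
```

The demo simulates the 217-sample cohort with the panel's fixed
differences planted among 100 background loci, rediscovers all seven
markers (four at full scope, three in the two subset searches),
simulates plates for every marker at default noise, calls them,
classifies every sample and scores the result against the simulation
truth.

```{r published}
cohort <- validation_cohort()
glance(confusion_matrix(cohort$assignments, cohort$reference))
coi_mismatch_summary(cohort$reference)[c("count", "percent")]
```

Problem sizes throughout the test suite are desk scale by design: the
brute-force discovery oracle runs on matrices of at most 20 samples by
50 loci (100 random draws), caller recovery is measured on 1,000
simulated wells, and the end-to-end demo at the 217-sample study
scale — large enough to exercise every code path, small enough that
the whole suite runs in a couple of minutes.

## Limitations

* Primer/oligo thermodynamic design (Tm, GC clamps, tails) is out of
  scope — performed by the assay vendor; the shipped primer sequences
  are inert metadata.
* Endpoint reads only: no real-time amplification curves, no dye
  spectral deconvolution.
* The caller's thresholds mimic, but cannot replicate, a visual
  "distinct clusters" judgement; on instruments with very different
  noise geometry the defaults (`kasp_caller_params()`) should be
  re-examined.
* Assignment is deterministic; samples from populations absent from
  the panel surface as `unresolved` or `non-target`, never as a
  probability.
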