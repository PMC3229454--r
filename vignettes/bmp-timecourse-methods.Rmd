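---
title: "Methods: fold-change filtering, synexpression discovery and temporal clustering of BMP time courses"
author: "bmptc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BMP time-course analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmptc)
```

## The data model

The experimental design this package targets profiles several breast cancer
cell lines treated with a BMP ligand (BMP4 or BMP7) against vehicle at six
time points: 30 min, 1 h, 3 h, 6 h, 12 h and 24 h. Each array yields one
column of log2(treatment/vehicle) ratios; a *(cell line, ligand, time
point)* triple is an **event**, and with the canonical design of 5 cell
lines per ligand a probe can be regulated in at most 30 events per ligand.
Columns are named `CELLLINE_LIGAND_TIMEh` (e.g. `HCC1954_BMP4_0.5h`); the
grammar encodes the full event key losslessly, which is why underscores are
reserved and cell-line names may carry hyphens. One column per event is
assumed — if replicates exist they are expected to be pooled upstream, as
is usual for this design.

Missing values are allowed on input. They never count as regulation events
(a conservative choice that keeps the event-count bound valid), and probes
with missing values are excluded from correlation clustering, where
pairwise-complete correlations would silently change the metric between
pairs.

## Normalization

"Linear normalization" is implemented as a per-array affine adjustment in
log2-ratio space: each event column is median-centered
(`method = "median_center"`, the default), optionally also rescaled so its
median absolute deviation equals the grand median MAD across arrays
(`"median_center_scale"`). Both variants are idempotent, rank-preserving
within each column, and exactly invertible from the emitted report
(offset + scale per event). Location-only adjustment is the default because
it is the minimal between-array correction that leaves fold-change
magnitudes untouched; whether the original analysis also matched scale is
not stated anywhere we could rely on, so both are offered and neither is
claimed as the original. Intensity-dependent (loess) normalization is out
of scope: the downstream thresholds are pure fold changes on ratios.

## Fold-change filtering

A probe is regulated at an event when |log2 r| ≥ log2 τ; thresholds are
inclusive because "at least τ-fold" reads as inclusive. The three schemes:

* **cell-line-specific** — ≥ 2-fold at ≥ 1 of the six time points of one
  (cell line, ligand) series;
* **time-point-specific** — ≥ 2-fold at the given time point (in any cell
  line present in the supplied matrix; on a single-line matrix this is the
  single-event rule);
* **general** — ≥ 3-fold in ≥ 3 events *and/or* ≥ 2-fold in ≥ 4 events,
  per ligand across all its cell lines. "And/or" is a logical OR: the
  exclusive reading would drop the most strongly regulated probes, which
  would contradict the point of the filter. A ≥ 3-fold event is by
  definition also a ≥ 2-fold event, so the stronger events count toward
  the weaker clause.

Event counting (per gene: up events, down events, total ≤ 30) uses the
2-fold cutoff. Ranking is by total events descending, ties broken by up
events descending then gene id ascending — the tie rule is this package's
own, as none is printed anywhere authoritative. Gene-level counting is
restricted to uniquely annotated probes; when several uniquely annotated
probes map to one gene the probe with the largest mean |log2 ratio| across
events represents the gene. This collapse rule is deterministic and favors
the most responsive measurement; the original workflow resolved such cases
by hand, which cannot be reproduced mechanically. Multiply-annotated
probes stay flagged `multiple` and are excluded from gene-level statistics
unless the user supplies a resolved mapping.

## Synexpression groups

Probes surviving the general filter are clustered by UPGMA (unweighted
average linkage) on the correlation distance d = 1 − Pearson r computed
across all events of one ligand. Pearson (not rank) correlation is used —
the standard choice for log-ratio microarray profiles of this vintage.
Zero-variance probes are dropped with a warning before clustering.

The tightly co-expressed groups that appear as boxed blocks on a clustered
heat map are operationalized as: cut the tree at height `cut_height`
(default 0.3, i.e. average within-group correlation ≈ 0.7+), keep groups
with ≥ `min_size` members (default 20) whose mean pairwise correlation is
≥ `tightness` (default 0.8), sorted by size. The originals were drawn by
eye on a dendrogram, so these defaults are explicitly *not* a claim about
the original boundaries — they are tunable everywhere they appear. The
cross-ligand synexpression group is the probe-level intersection of one
tight cluster per ligand, with its uniquely annotated gene subset reported
alongside.

## Temporal clustering and responder categories

Per cell line, the six-point profiles of cell-line-filter survivors are
scaled to unit Euclidean length (shape, not amplitude, drives the
clustering; all-zero profiles are excluded) and fitted with finite
Gaussian mixtures by EM. Five covariance families are available —
spherical/diagonal × equal/varying, plus full covariance — and the
(family, K) pair maximizing BIC = 2·logL − p·ln n is selected, with p the
free-parameter count. Numerical choices:

* seeded k-means initialization, 10 restarts per (family, K) by default;
  all randomness derives from one integer seed and the caller's RNG state
  is restored afterwards;
* convergence when the relative log-likelihood change falls below 1e-8, or
  after 500 iterations; the per-iteration log-likelihood trace is kept and
  is non-decreasing (asserted in the test suite);
* variances floored at 1e-6 to guard against singular covariances; full
  covariances get an escalating diagonal ridge until Cholesky succeeds;
* EM runs in which any component's effective membership drops below 2 are
  rejected: such solutions ride variance-floor likelihood spikes and would
  bias BIC toward spurious extra clusters (the classic degenerate-GMM
  failure mode).

Each cluster is then categorized from its **mean profile on the original
log2 scale** by the earliest time it crosses the regulation threshold
(default 2-fold, the same cutoff as the filters): 0.5/1 h → early,
3/6 h → early-intermediate, 12 h → late-intermediate, 24 h (exclusively) →
late, never → undetermined. Whether the original analysis categorized
clusters or individual probes, and at which threshold, is not stated; the
cluster-mean rule is the default because the published summaries are
per-cluster, and a per-probe majority mode (`classify = "probe"`) is
provided as the alternative. "Undetermined" is defined as a mean profile
that never crosses the threshold — the published tables carry such a
column without a printed definition.

## GO enrichment

One-sided over-representation only (the published tables report enriched
categories), with the hypergeometric upper tail computed exactly:
p = Σ_{i≥k} C(m,i)·C(N−m,K−i)/C(N,K) for k study genes carrying a term out
of K, against m of N background genes. The background is an explicit,
required argument — conventionally all uniquely annotated genes on the
array. No multiple-testing correction is applied to the primary p-values
(the published raw p-values around 0.005–0.05 are inconsistent with FDR
control); Benjamini–Hochberg q-values are emitted as an extra column. The
term→gene map is flat: no ontology-graph ancestor propagation, so callers
must pre-propagate if they want true-path semantics. Terms with fewer than
`min_term_size = 5` background genes are skipped as a conventional noise
guard. Per-category enrichment pools the member genes of each temporal
category's clusters; results from different cell lines are combined by
term-wise concatenation, never by pooling p-values.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions so every stage has a
recovery benchmark with known truth: two ligands, 5 cell lines each with a
3-line overlap, 6 time points, and per-event noise N(0, σ²) with σ = 0.25
log2 units — a modest two-color array noise level. Default structure:

* 20% responders with a sustained step response of magnitude A = 1.5 log2
  units from an onset time drawn within one of the four category windows
  (equal mixture); a transient single-time-point pulse is available as an
  option, but the sustained step is the default because the category rule
  explicitly ignores expression after onset;
* per-(probe, cell line) response sign: a base sign flipped with
  probability 0.3, making cell-line-heterogeneous regulation (up in some
  lines, down in others) a first-class feature of the data;
* a planted synexpression group (40 probes per ligand, 75% shared) whose
  members follow one latent step profile per (cell line, ligand) plus
  N(0, (σ/2)²) probe noise; the shared members reuse identical latent
  profiles across ligands in the shared cell lines;
* annotation statuses drawn at 66% unique / 16% multiple / 18% unannotated,
  matching the annotation yield typical of this array generation;
* a flat ontology of 200 terms of ~40 genes drawn uniformly from the
  uniquely annotated universe, plus one planted term drawn from the genes
  of a single onset category.

All randomness flows from one seed; a fixed seed reproduces the dataset
exactly. What the generator deliberately does **not** emulate: probe-level
intensity/dye physics, spatial artifacts, intensity-dependent bias,
correlated noise between time points, and annotation errors. Passing the
recovery benchmarks therefore demonstrates that the machinery is correct
under the stated statistical assumptions, not that real arrays meet those
assumptions.

## Problem sizes and benchmarks

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is cleanly identified: 2000-probe
datasets for filter recall, temporal category recovery (five seeds, one
cell line each, K searched over 2–20 with the varying-spherical family)
and synexpression recovery; 100 observations per component for mixture
model selection (K ∈ {3, 5}, component separation 8√2 σ); 200 terms for
enrichment calibration; an 800-probe, 3-cell-line dataset for the
end-to-end determinism check. The exhaustive oracles (brute-force filter
scans, naive O(n³) UPGMA for n ≤ 12, hypergeometric tail enumeration for
N ≤ 50) bound their own sizes by construction. The published gene lists
and counts themselves are not reproduced: they require the original GEO
arrays and a historical genome re-annotation, which are outside this
package's inputs.

## Pipeline orchestration

`run_pipeline()` executes normalize → filter → rank → cluster →
synexpression → temporal → enrichment per ligand from one YAML config with
a block per stage. Every stage is a pure function of (inputs, config,
seed); the manifest records the config snapshot, input digests and an md5
digest per output, so rerunning the same config yields a byte-identical
manifest — that property is asserted in the test suite. The pipeline's own
temporal defaults (K from 2 to 12, varying-spherical and varying-diagonal
families, 5 restarts, seed 7) are leaner than the module defaults, sized
for routine whole-pipeline runs; the module-level default of K up to 25
covers the cluster counts reported for this design (12–22 per cell line).

## Known limitations

* Fold-change filtering has no variance model; it inherits the design's
  pooled-replicate limitation and will admit high-variance probes that a
  moderated test would shrink.
* Tight-cluster extraction depends on the cut height and tightness chosen;
  the defaults recover strongly planted structure but visual curation of a
  dendrogram cannot be reproduced exactly.
* The mixture model assumes Gaussian clusters on the unit sphere after
  scaling; heavy-tailed profiles can inflate K.
* Enrichment treats the term map as flat and genes as exchangeable; probe
  multiplicity is collapsed before testing.
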