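---
title: "Dotplot-based LCR detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dotplot-based LCR detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotlcr)
```

# The model

A low complexity region (LCR) is a contiguous protein segment dominated by
few residue types. In a self-comparison dotplot — the N×N binary matrix
with a dot wherever two residues are identical — an LCR appears as a dense
block on the diagonal, and two compositionally matching LCRs of the same
protein additionally produce a dense block at their off-diagonal
intersection. `dotlcr` operationalises this picture in three steps.

**Density.** The dotplot is convolved with a uniform k×k kernel
(default k = 10), so each pixel holds the integer count of dots in its
window, 0..k². The window is anchored at offsets −4..+5 in both axes for
k = 10; even-width kernels have no centred anchor, and this choice is what
makes the later −4/+5 boundary correction of called LCRs exact. The
convolution is computed with a summed-area table (exact integer counts,
zero padding outside the matrix), and for pooled histograms the rows are
streamed so memory stays O(N) per protein even for titin-scale sequences.
The kernel width sets the minimum LCR length scale: a k-mer of a single
residue saturates one window.

**Calibration.** What counts as "dense" is calibrated per proteome. A
*null proteome* is simulated — one sequence per real protein, same length,
residues i.i.d. uniform over the 20 standard amino acids — and both
proteomes' convolved pixel intensities are pooled into histograms. For
every candidate threshold t,

$$\mathrm{FDR}(t) = \frac{n_{\mathrm{null} \ge t}}
{n_{\mathrm{real} \ge t} + n_{\mathrm{null} \ge t}},$$

and the smallest t with FDR(t) ≤ 0.002 (and at least one passing pixel) is
the proteome-wide segmentation threshold. A uniform composition for the
null is deliberate: it judges a given sequence identically regardless of
which proteome it appears in, while length matching absorbs differences in
protein length distributions. The histograms pool full N×N matrices
(diagonal and both symmetric halves); the symmetric duplication inflates
real and null counts alike and cancels in the ratio.

**Segmentation and typing.** Pixels ≥ t are labelled into connected
components under 8-connectivity — repeat signatures run diagonally, and
4-connectivity would fracture them (the labelling is a two-pass union-find
in C++; connectivity is configurable). Components containing at least one
diagonal pixel become LCR calls: the call's raw extent is the min..max of
the component's *diagonal* indices — an off-diagonal lobe of the same
component does not stretch the call — then widened by −4/+5, clamped to
the protein, and calls whose widened intervals overlap or abut are merged.
For every pair of calls, any labelled pixel inside the off-diagonal
rectangle rows(a) × cols(b) (using the widened intervals) makes an edge;
connected components of the resulting per-protein graph are the LCR
*types*, component size is the copy number, and proteins fall into
`single` / `multiple-same` / `multiple-distinct` / `multiple-mixed` by
their total and distinct counts.

# Downstream analyses

**Entropy validation.** Shannon entropy
$H = -\sum_a f_a \log_2 f_a$ of each called LCR is compared with one
length-matched sequence sampled uniformly from the concatenated proteome
(sampling may span protein boundaries, exactly as uniform position
sampling over the concatenation implies; a flag redraws boundary-spanning
samples). A one-sided Wilcoxon rank-sum test asks whether LCR entropies
are lower. Raising the segmentation threshold selects denser dotplot
regions and provably lower-entropy sequence, which the test suite checks
as a monotone trend.

**Composition map.** Each LCR becomes a 20-dimensional residue-frequency
vector (non-standard letters X/U/O/B/Z are excluded from numerator and
denominator; an LCR with no standard residues is dropped with a warning).
UMAP (2 components) provides display coordinates; clustering runs on the
20-D vectors themselves, never on the 2-D projection, via a Jaccard-
weighted shared-nearest-neighbour graph and Leiden community detection.
Cluster names are a reproducible proxy for manual labelling: all residues
with mean frequency ≥ 0.5 × the cluster's top mean frequency, joined by
"/" in descending order. "Top-quartile" residue-enriched subsets use the
default linear quantile of the reference set's frequencies with ≥
selection, so an all-tied reference selects everything and a 4-value
reference selects exactly its top value.

**Enrichment.** Per residue, a two-sided Wilcoxon rank-sum test compares
annotated LCRs against all others (or one annotation set against another,
with rows in both sets excluded); the signed standardised statistic with
tie correction is reported as a z-score (positive = enriched in the
annotated set), with Benjamini–Hochberg correction across the 20 residues
and a significance call at adjusted p < 0.001.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `kernel_size` | 10 | dotplot window width (residues); minimum LCR scale |
| `target_fdr` | 0.002 | null fraction of passing pixels tolerated |
| `pad_left`, `pad_right` | 4, 5 | boundary widening of calls; pinned to the kernel anchor |
| `connectivity` | 8 | pixel adjacency for segmentation |
| `null_seed` | 1 | null-proteome simulation seed (recorded in outputs) |
| `n_null_reps` | 1 | nulls averaged for the threshold (one, as standard; more for stability studies) |
| `entropy_base` | 2 | entropy logarithm base (bits); comparisons are base-invariant |
| `n_neighbors` | 15 | UMAP neighbourhood (200 for very large multi-species maps) |
| `cluster_k` | 15 | kNN graph size for clustering |
| `resolution` | 0.1 | Leiden resolution (modularity) |
| `embed_seed`, `cluster_seed` | 73 | seeds for embedding and clustering |
| `quartile_q` | 0.75 | quantile defining "residue-enriched" subsets |
| `enrichment_alpha` | 0.001 | adjusted-p cut-off for significance |

## Why resolution 0.1

`igraph`'s Leiden implementation with the modularity objective needs an
explicit resolution. On planted two-island composition sets (500 poly-K +
500 poly-E LCRs with background flanks) any resolution in 0.01–0.25
recovers exactly the two islands across seeds with purity 1; at 1.0 each
island fragments into ~3 subclusters of no compositional meaning. The
default 0.1 sits in the middle of that stable plateau. It is a
granularity knob, not a truth parameter: raise it to subdivide clusters by
finer composition differences.

# Numerical choices and degenerate inputs

- Intensities are exact integers, so histograms need no binning and the
  FDR curve is computed by cumulative-from-above sums.
- Thresholds that no pixel passes are never selected; if no threshold
  meets the target FDR (e.g. real and null histograms identical), a typed
  error carrying the full FDR curve is raised.
- Component labels are assigned in order of first appearance in a
  column-major scan, making masks byte-reproducible across runs and
  matching the flood-fill oracle used in tests.
- Exact duplicate composition rows are collapsed before building the kNN
  graph (they are one point in composition space); an all-identical input
  yields one cluster by definition. Ties in quantiles use the ≥ rule so
  boundary values are always included.
- Identical groups in a rank-sum test have zero tie-corrected variance;
  the z-score is defined as 0 and p as 1.
- A single-character protein ("A") has one pixel of intensity 1; kernels
  wider than the matrix simply clamp.
- Seeds: every stochastic step (null simulation, sequence sampling,
  embedding, clustering) takes an explicit seed and restores the caller's
  RNG state; identical inputs and seeds give byte-identical outputs.

# The synthetic generator, and what passing tests do not show

`make_planted_proteome()` draws background residues i.i.d. from a
configurable composition (uniform by default, so the calibration null is
exactly composition-matched) and plants low-entropy blocks — homopolymers
or two-letter repeats, entropy ≤ 1 bit — at random positions with a
minimum spacing. Planted blocks give ground truth for recall, interval
coverage, and same-type/distinct-type recovery; a biased-background option
stresses the uniform-null assumption.

Real proteomes differ in ways the generator deliberately does not mimic:
residue composition is non-uniform and autocorrelated, LCR boundaries are
fuzzy rather than planted, repeat units are often imperfect (insertions,
substitutions), and protein lengths are heavy-tailed. Passing the planted
benchmarks therefore demonstrates correctness of the machinery — exact
agreement with brute-force oracles, calibrated FDR, recovery of planted
structure — not that any particular biological proteome will yield a given
LCR count. On real data the uniform null makes compositionally common
residues easier to call in composition-biased proteomes; this is a known,
intended property of the calibration, discussed above.

Problem sizes in the test suite and acceptance script (200-protein
benchmark proteomes of 150–250 residues, 50-protein oracle-equivalence
sets of 80–180 residues, 1000-LCR maps) were chosen so the whole suite
runs in well under a minute on a laptop while leaving every statistical
check comfortably powered.

# Known limitations

- Matching is exact character identity; no substitution-matrix similarity,
  so degenerate repeats with alternating synonyms are split or missed.
- Types are within-protein only; no cross-protein LCR type identity.
- One null proteome per run by default; threshold variance across null
  seeds is small (±1 intensity unit in practice) but nonzero — record the
  seed, or average with `n_null_reps`.
- Embedding determinism is promised per uwot version; run metadata records
  package versions.
- External per-residue scores (disorder, binding propensity) are consumed
  from files, never computed.

# A two-island map in five lines

```{r map-example, eval = FALSE}
pp <- make_planted_proteome(
  500, c(60, 80),
  blocks = list(list(list(len = 25, alphabet = "K")),
                list(list(len = 25, alphabet = "E"))),
  seed = 1)
thr <- lcr_threshold(pp$proteome, seed = 2)
calls <- call_proteome(pp$proteome, thr$threshold)
comp <- composition_matrix(calls)
labels <- cluster_lcrs(comp)          # 2 clusters: the K and E islands
label_clusters(comp, labels)          # names them "K" and "E"
```
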