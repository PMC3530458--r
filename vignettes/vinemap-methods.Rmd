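---
title: "Methods: fingerprint processing, sampling design and mixed-model networks"
author: "vinemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint processing, sampling design and mixed-model networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinemap)
```

# The problem

Grape berries carry complex epiphytic yeast communities whose composition
depends on the farming system (conventional, integrated, biodynamic) and —
importantly — varies between locations inside a single vineyard block.
`vinemap` implements a complete analysis chain for such studies:

1. **ARISA fingerprint processing** — community profiles read as
   fluorescent fragment-length peaks are filtered, binned into OTUs and
   assembled into a sample × OTU fluorescence matrix.
2. **Sampling design** — vineyard blocks are treated as two-dimensional
   lots in the sense of the Theory of Sampling (TOS), unfolded into a
   linear sequence of sampling points with metric coordinates, and checked
   for pseudoreplication by regressing community similarity on inter-point
   distance.
3. **Community networks** — a sample correlation network pruned to a
   maximum spanning tree, a bipartite sample–OTU probability network, and
   their union pruned by a second spanning-tree pass (the "mixed-model"
   network).
4. **Culture-based diversity** — Shannon, Pielou and Menhinick indices
   from species × vineyard isolate tables.
5. **Synthetic data** — a generator producing electropherograms and
   isolate tables with the statistical structure the analysis assumes, so
   the whole chain is testable without any deposited raw data.

# ARISA processing

An electropherogram is summarized as peaks (fragment length in bp,
fluorescence in RFU). Peak **area** is the preferred quantity, since areas
carry the relative proportions of the fragments; whether the instrument
exported height or area is the caller's concern. Three retention rules are
applied per sample, in a fixed order:

1. fluorescence ≥ 50 RFU (background exclusion);
2. 300 bp ≤ length ≤ 1000 bp (analysis window);
3. fluorescence strictly greater than 0.5 % of the sample's total
   fluorescence.

The order matters only for rule 3's denominator. By default the total is
taken over the peaks surviving rules 1–2 (`relTotal = "window"`), which
makes the floor insensitive to out-of-window noise; since the alternative
reading (total over all above-threshold peaks) cannot be excluded, it is
exposed as `relTotal = "all"`. The floor is strict (`>`, not `≥`): a peak
exactly at 0.5 % is removed.

**Binning.** Capillary sizing is less accurate for long fragments, so bins
are 3 bp wide below 700 bp and 5 bp wide from 700 bp up. Bins are
half-open intervals `[edge, edge + width)` anchored at the window minimum:
edges 300, 303, …, 699 (the last sub-breakpoint bin is truncated to
[699, 700)), then 700, 705, …, 995, with the final bin closed at 1000.
This cover is deterministic, gapless and non-overlapping; the breakpoint
itself belongs to the 5-bp regime ("below 700 bp" read strictly). Any
anchoring choice is arbitrary up to an offset — published peak labels such
as 518/545/568 bp do not lie on a common 3-bp grid and are best understood
as rounded fragment lengths, not bin edges — so the package fixes the one
consistent convention above and labels each OTU by its bin's lower edge.
Co-binned peaks are summed, so total fluorescence per sample is conserved
exactly through binning (a tested invariant).

`buildOTUMatrix()` takes the union of bins occupied in at least one sample
as columns; candidate bins never occupied are absent, matching the removal
of elution points without a peak in any sample. All-zero samples are kept
(flagged with a warning) so the design stays complete; operations that
need variance or positive totals reject them by name.

```{r arisa-example}
ps <- PeakSet(data.frame(sample = "S1",
                         length_bp = c(250, 520, 610, 800),
                         fluorescence = c(500, 5000, 20, 4000)))
peakData(filterPeaks(ps))  # 610 bp fails the RFU rule, 250 bp the window
```

# Sampling design and the pseudoreplication test

A vineyard block is a two-dimensional lot: rows crossed with panels
(trellis segments of six vines). `linearizeLayout()` unfolds the lot into
a serpentine sequence — row-major, panel order reversed on alternate rows,
the path a sampler walking the unfolded lot takes. The `linear_index` is
bookkeeping only; distances come from the metric coordinates
*x = row × 2.5 m* and *y = panel × 9 m*. Using the printed row and panel
*numbers* (not re-indexed positions) preserves the non-consecutive row
spacing of the reference designs (rows 9, 11, 13, … vs 1, 4, 7, …).
Bunches are placed at the panel origin; no finer intra-panel resolution is
claimed. The three built-in layouts (`defaultLayouts()`) give 18 (CONV),
21 (BD) and 18 (IPW) sampling points.

If location rather than treatment drove community composition, community
similarity would fall with distance inside a vineyard. The test computes,
for every unordered pair of points, the Euclidean distance
√(dx² + dy²) and the Pearson correlation of the two OTU vectors, then fits
OLS of community correlation (dependent) on distance (independent). Three
summaries are reported side by side: `r_distance` (the correlation of the
scatter), `r_squared` (its square, in [0, 1]) and `signed_r2`
(sign(slope) × R²). The signed variant exists because some studies print
negative "R²" values, which a coefficient of determination cannot be; the
published values this design echoes (0.1063, −0.115, 0.0106) anchor that
sign convention but cannot be recomputed without the original fingerprint
matrix, which was never deposited.

# Network models

**Correlation network.** All-against-all Pearson correlations between
sample vectors, a complete weighted graph.

**Maximum spanning tree.** Edge weights are transformed to inverse
correlations 1 − |r| and a *minimum* spanning tree is found on the
transformed costs, selecting the strongest-|r| backbone; surviving edges
keep their original signed correlations. The optimality criterion, not the
algorithm, is the contract; the package uses an explicit Kruskal with a
deterministic tie-break (edges sorted by cost, then by lexicographic
endpoint pair), so output is unique and invariant to input order. Tests
check it against exhaustive enumeration of all spanning trees on graphs of
up to 6 nodes and against an independent library implementation on
tie-free instances.

**Probability network.** Each sample vector divided by its total turns
fluorescence into occurrence probabilities (rows sum to 1, a validity
condition of the `ProbabilityMatrix` class). The bipartite graph links a
sample to exactly the OTUs with probability > 0, weighted by that
probability.

**Mixed-model network.** The pipeline is literal and order-sensitive:
(1) backbone tree edge weights × 10; (2) union with the probability
network; (3) every weight w → |1 − w|; (4) minimum spanning tree with the
same deterministic tie-break; (5) surviving edges restored to their
original weights (unscaled correlation / probability); (6) sample nodes
sized by degree, OTU nodes by the probability on their surviving edge
(the maximum when several survive).

Taken literally, |1 − 10r| makes scaled backbone edges costly (≈ 7 for
r ≈ 0.8) relative to probability edges (|1 − p| < 1), so the literal
pruning tends to drop backbone edges unless they are needed for
connectivity. Published mixed-model figures appear to retain the
sampling-point backbone, but the text does not let one decide whether a
preferential retention was intended; both behaviours are therefore
provided — literal is the default, and `forceBackbone = TRUE` pins every
backbone edge into the tree before the remaining edges compete. `scale`
is likewise configurable.

Exports: GraphML (attribute-complete, round-trip tested), SIF (edge kind
as the interaction label) and a CSV edge list; rendering (layout, colour,
width) is left to viewers such as Cytoscape.

# Diversity indices

For each vineyard column: richness S (species with positive abundance),
Shannon H′ = −Σ pᵢ ln pᵢ, Pielou J = H′/ln S, Menhinick D = S/√N.

* **Natural log, fixed.** Back-computation from published values shows
  base e (1.20/ln 11 = 0.50 matches the printed evenness); no base option
  is offered, to avoid silent mismatches.
* **Percent mode.** Percentages/100 are used directly as proportions, with
  no renormalization; column sums may deviate from 100 by up to 0.5
  (rounding slack), larger deviations are an error. N and D are undefined
  without true counts and reported as `NA` — D is never estimated from
  percentages.
* **Degenerate input.** S = 1 gives H = 0 and J = `NA` (evenness
  undefined).

Two known inconsistencies in the reference values are documented, not
reproduced: the published IPW evenness 0.63 matches S = 10 rather than the
reported S = 9 (1.45/ln 9 = 0.66), and the published biodynamic H′ = 2.15
exceeds the ≈ 1.94 recomputable from the rounded percentage table —
presumably computed from unrounded counts that were never printed.

```{r diversity-example}
tbl <- readIsolateTable(system.file("extdata",
  "table2_isolates_percent.csv", package = "vinemap"), mode = "percent")
diversityReport(tbl)
```

# The synthetic generator: what it emulates, and what not

`simulateProfiles()` states the world the analysis assumes:

* **Shared dominant bands.** `nSharedOtus = 6` OTUs with fragment lengths
  drawn once from 500–600 bp carry on average `dominantFraction = 0.6` of
  each sample's total fluorescence (log-normally dispersed, sdlog 0.15 at
  the group level and 0.3 per OTU) — typical ARISA profiles of sound
  berries are dominated by a few bands in that range, and the dominant
  black-yeast fraction on real berries is 50–70 %.
* **Vineyard-private minors.** `nPrivateOtus = 12` per vineyard, geometric
  rank-abundance (decay 0.65), each present at a point with probability
  `occupancy = 0.6` — independent Bernoulli draws create the intra-vineyard
  heterogeneity; distinct private lengths make vineyards discriminable.
  12 private + 6 shared OTUs gives ~15–18 detected OTUs per sample,
  realistic for fungal ARISA on grapes.
* **Noise.** 5 peaks per sample under 50 RFU with lengths in [100, 1050],
  so both the threshold and the window filter are exercised; none survive
  default filtering (tested).
* **Spatial kernel (off by default).** With `spatialKernel = TRUE` each
  private OTU gets a random focus in its vineyard and its occupancy decays
  as a Gaussian of range 20 m (rescaled to keep the vineyard-average
  occupancy), inducing genuine distance decay — the positive control for
  the pseudoreplication test. 20 m is of the order of the inter-point
  spacing, so neighbouring points share minors while far corners do not.
* **Scale.** `fluorescenceScale = 5e4` RFU total per sample, comfortably
  above threshold after splitting across peaks.

`simulateIsolates()` draws per-vineyard multinomials over a geometric
profile led by a shared dominant species (share 0.6), guarantees each
configured species at least one isolate so realized richness equals the
configuration (11/9/17), and splits the 628-isolate total across vineyards
proportionally to their sampling-point counts by largest remainder.

What the generator does **not** emulate: electrophoresis trace shape,
size-standard calibration error, PCR amplification bias, pseudo-peaks
(stutter), or any sequence-level content. A green end-to-end test
therefore establishes that the pipeline recovers structure *of the kind
assumed*, not that it would denoise a miscalibrated instrument.

Distributional choices (log-normal dispersion, geometric rank-abundance)
are conventional simple forms; nothing downstream depends on them beyond
their dispersion, and they are config-exposed. All generators take an
explicit `seed` and reseed locally drawn streams; identical seeds give
bit-identical outputs, including exported network files.

# Numerical choices and degenerate inputs

* Probability rows must sum to 1 within 1e-9; fluorescence conservation is
  checked to 1e-9 relative.
* Spanning-tree tie-breaks: cost ascending, then lexicographic sorted
  endpoint pair — output unique even on degenerate equal-weight graphs.
* Zero-variance sample vectors (constant fluorescence) make Pearson
  correlation undefined; correlation operations error naming the sample
  rather than propagating `NA`.
* Cross-vineyard point pairs are rejected: the distance-decay procedure is
  defined within a vineyard only.
* An empty filter result leaves the sample in the set (empty peak list,
  message), and it appears as an all-zero, flagged row in the matrix.
* The last 3-bp bin is truncated at the 700 bp breakpoint ([699, 700)) and
  the final 5-bp bin is closed at 1000 bp, so the window is covered
  exactly.

# End-to-end example

```{r end-to-end, message = FALSE}
ps <- simulateProfiles(seed = 1)
m <- buildOTUMatrix(filterPeaks(ps))
m

tree <- maximumSpanningTree(correlationNetwork(m))
vineyardAdjacencyTest(tree, nPerm = 200, seed = 2)$p_value

mixed <- mixedModelNetwork(tree, probabilityNetwork(probabilityMatrix(m)))
mixed

pts <- linearizeLayout(defaultLayouts()$BD)
pseudoreplicationTest(m[, sampleData(m)$vineyard == "BD"], pts)
```

# Known limitations

* Published network figures and pseudoreplication R² values cannot be
  reproduced exactly: the underlying fingerprint matrix was never
  deposited. The package validates those components by construction
  (exhaustive enumeration, hand-traced arithmetic) and by parameter
  recovery on synthetic data instead.
* The Menhinick index genuinely requires isolate counts; percent-mode
  tables yield `NA`, by design.
* No variographic estimation of the minimum increment number, no PCA
  ordination, no rarefaction or richness estimators — out of scope.
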