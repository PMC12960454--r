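---
title: "The CoSS model: methods, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CoSS model: methods, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cossr)
```

# The model

`cossr` scores the spatial organisation of each feature of a well-based
spatial omics sample with the Coefficient of Spatial Structure (CoSS), the
$L^p$ norm of the 0-dimensional persistence barcode of the feature's
smoothed, inverted expression landscape. The underlying intuition: a
feature with genuine spatial structure has an expression surface with
distinct hills (and valleys); tracking connected components of the
superlevel sets $\{z \ge t\}$ as the threshold $t$ sweeps downward gives
each hill a bar whose length measures its prominence, and aggregating bar
lengths gives one number per feature that is blind to where the hills are,
hence insensitive to the coordinate frame and to continuous deformations of
the tissue.

The pipeline assumes:

* wells lie (approximately) on a regular hexagonal or square grid;
* counts/intensities are nonnegative, and only their *relative* spatial
  allocation matters (each feature is normalized to unit total mass, so
  the score is invariant under positive rescaling of a feature);
* spatial structure of interest is larger than the well size, and occupies
  at least a mass fraction `m` of the feature's total signal.

## Smoothing: weighted distance-to-measure with network distances

For well $p$, all wells are ordered by their actual Euclidean distance to
$p$ ($p$ first) and their unit-normalized weights accumulated until the
running total first reaches `m`; with this count $k$,
$\mathrm{dtm}(p;m) = \frac1k \sum_{i \le k} d_i^2$, where $d_i$ is the
distance to the $i$-th nearest site of the *infinite ideal lattice*
($d_1 = 0$). Substituting idealized network distances for the raw ones is
the load-bearing robustness device: wells near tissue edges or holes would
otherwise see their distance sequence grow abnormally fast and receive
inflated smoothed values. A raw-distance variant
(`weighted_dtm(..., distances = "euclidean")`) is retained purely to
demonstrate this contrast in tests; it is not recommended for analysis.

The smoothed surface is low over high expression, so it is inverted,
$z_i = \max_j \mathrm{dtm}_j - \mathrm{dtm}_i$, giving a landscape with
minimum exactly 0 that is high over hotspots.

## Persistence and scoring

The filtered complex has wells as vertices with index $z_i$ and lattice
adjacency pairs as edges with index $\min(z_i, z_j)$ (upper-star rule).
A union-find sweep in decreasing index order computes 0-dimensional
persistence: a component is born at its highest vertex, and at a merge the
younger component dies (elder rule). Components that never die are, by
default, assigned death at the global minimum vertex value
(`essential_policy = "kill_at_min"`), which keeps every norm finite and —
importantly — lets *voids* of expression contribute: a depleted disc inside
an expressed background produces a single long essential bar. The
alternative `"drop"` policy discards essential classes and scores only
internal merges.

CoSS is $(\sum_b \ell_b^p)^{1/p}$ over lifetimes, $p = 2$ by default;
larger $p$ emphasises features whose structure is carried by few prominent
regions. The ratio statistic $\ell_{\max} / \#\text{bars}$ (bars counted
above a lifetime tolerance) flags single-bar features such as one highly
expressed well; no default numeric flag threshold is imposed because
informative values are platform-dependent.

# Tunable parameters

| parameter | default | units / range | guidance |
|---|---|---|---|
| `m` | 0.1 | mass fraction, (0,1) | fraction of tissue the smallest interesting feature occupies; 0.01 for high-resolution MSI pixels |
| `p` | 2 | norm order, [1, Inf] | 2 balances count and prominence of regions |
| `essential_policy` | `kill_at_min` | — | `kill_at_min` detects voids; `drop` scores only internal structure |
| `lifetime_tolerance` | `1e-12 * max(z)` | z-units | float-noise guard for bar counting only |
| `sensitivity` | 1 | — | kneedle confirmation margin; raise to be more conservative |
| `smoothing_window` | adaptive | odd integer | `2*floor(n/200)+1`; see below |

CoSS carries units of (lattice spacing)². Comparisons across samples
therefore require equal spacing and equal `m`; the `diff` CLI verb refuses
mixed `m` without `--force`.

# Numerical choices

**Distance ties.** On an exact lattice, every distance shell around a well
is a tie group, and the printed accumulation rule is ambiguous about the
order within a group. Breaking ties by well index makes the score depend on
how wells happen to be labelled — relabeling the same sample shifted CoSS
by a few percent in experiments, which is unacceptable for a score meant to
be compared across samples. `cossr` therefore accumulates tie-group members
in *ascending weight order*, a symmetric function of the group: the result
is exactly invariant under well relabeling and rigid motions, reduces to
the plain sequential rule whenever no tie group straddles the mass
threshold, and keeps the closed forms (uniform weights on a complete hex
lattice, $m = 0.07$, give $k = 7$ and $\mathrm{dtm} = \tfrac67 s^2$
everywhere, hence CoSS exactly 0 for uniform features). Tie groups are
detected with an absolute squared-distance gap of
$10^{-6} \times \text{spacing}^2$ — far below the smallest genuine shell
gap (which is $\ge \text{spacing}^2$ on ideal lattices) and far above
floating-point noise. The ascending choice is the conservative end of the
within-group ambiguity (it maximises $k$); for a feature whose whole mass
sits in one well sharing its shell with others, $k$ runs to the end of
that shell rather than to the massive well's arbitrary position within it.

**Zero-lifetime bars.** A component that is merged away at its own birth
index was never a homology class (the vertex and edge enter the filtration
together); such instantaneous pairings produce no bar. Essential bars are
always kept, including zero-lifetime ones — a constant landscape yields
exactly one bar $(c, c)$. Consequently, for generic (all-distinct) fields
the bar count equals the number of local maxima of the landscape.

**Kneedle.** The knee finder min–max normalizes both axes, forms the
difference between the chord and the curve, and confirms the first local
maximum of the difference curve that the curve subsequently undercuts by
`sensitivity / (n - 1)` before another local maximum replaces it. Two
practical choices matter. First, candidates are *replaced* by newer local
maxima rather than rejected outright, matching the original online
formulation. Second, the curve is pre-smoothed by a centered moving
average whose default window grows mildly with the curve length
(`2*floor(n/200)+1`, i.e. off below 200 points): the original algorithm
smooths with a spline before knee finding, and on raw sampled CoSS–rank
curves of transcriptome size the difference curve's sampling noise
otherwise confirms spurious knees far above the true elbow. Degenerate
curves — short ($n < 5$), constant, or straight lines — return no knee,
and `call_svgs()` then calls nothing with a warning rather than forcing a
cutoff; the same graceful refusal applies to qualitatively non-elbowed
score–rank profiles, as seen on some MSI samples.

**Lattice alignment.** Spacing is estimated as the median nearest-neighbour
distance; the lattice type is inferred from the angular distribution of
neighbour bearings (a 6-fold vs 4-fold circular moment); the basis is
fitted by iterated least squares (integer assignment → basis refit, to
convergence). Wells failing the snap tolerance (default 0.25 × spacing)
beyond a 5% allowance, collinear inputs, duplicate coordinates, and two
wells snapping to one site are all hard errors — silently merging or
dropping wells would hide corrupt input. Disconnected tissue pieces are
kept in one lattice and each contributes an essential bar, killed at the
global minimum for a consistent background level across the sample.

**Degenerate features.** All-zero features cannot be normalized to unit
mass; they are reported with `NA` scores and an `all_zero` flag rather
than dropped, so downstream joins stay aligned. A single-feature matrix
under counts-per-million becomes constant over occupied wells and scores
0 — intended, since cpm removes all between-well contrast in that case.

# The synthetic world

`simulate_sample()` generates the situations the score is meant to detect
or ignore: multi-center Gaussian hotspots, rings, linear gradients,
expression voids, uniform backgrounds, single-well spikes, and low-depth
features (k positive wells), on hexagonal or square lattices (default
32×32, spacing 100 — a Visium-like length scale) with optional masks for
irregular boundaries, holes, and disconnected pieces, and counts drawn from
a negative binomial model (dispersion 0.5, the overdispersion regime
typical of spatial transcriptomics counts; Poisson and noise-free switches
exist for sharper tests). Patterns are specified in relative coordinates of
the lattice bounding box, so one spec scales across lattice sizes — with
the corollary that morphology-robustness experiments must *subset* a
generated sample rather than regenerate it with a mask, or the pattern
itself silently shrinks with the bounding box.

What a green synthetic test establishes: that the implementation detects
the stated pattern classes against their own spatial-permutation nulls at
the stated rates, on ideal grids with stationary noise. What it does not
establish: performance on real tissue, where expression patterns correlate
across genes, noise is not stationary, morphology is irregular in ways a
mask only caricatures, and ground truth is unknown.

Two structural facts about the permutation null deserve note. First, a
single-well spike is *invariant in distribution* under spatial
permutation — the null of "all mass in one random well" is again "all mass
in one random well" — so no statistic whatsoever can separate a spike from
its own permutation null; the ratio statistic, not the permutation test,
is the right instrument for that pattern class. Second, the same
exchangeability argument means a uniform noisy feature sits at the median
of its own null by construction; "uniform features score low" is therefore
asserted against the nulls of structured features instead.

# Known limitations

* The score's absolute value scales with (spacing)² and, through $k$, with
  well count; cross-sample comparisons need matched platforms and `m`.
  Removing a fraction of wells (different capture area, aggressive QC)
  shifts background smoothing levels of features whose mass is
  renormalized, of order the removed mass fraction.
* Ring-shaped patterns are detected mainly through the single essential
  bar (a ring is one connected component), so their power against
  permutation nulls is lower than for multi-hotspot patterns of equal
  amplitude; thin rings near the noise floor sit at the detection
  boundary.
* Gradients without boundaries produce shallow landscapes and score low —
  inherent to a component-counting (0-dimensional) method.
* The distance-ordering matrix is O(n²) memory; fine for 10³–10⁴ wells,
  not for transcript-resolved (non-gridded) platforms, which are out of
  scope along with 3-D lattices and loop (1-dimensional) homology.
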