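# cossr — topology-based spatial structure scores for well-based spatial omics

`cossr` quantifies how spatially organised each feature of a spatial omics
sample is. It targets well/pixel-gridded platforms — Visium-style spatial
transcriptomics (hexagonal spot arrays) and mass spectrometry imaging
(square pixel grids) — where the data for one sample are well coordinates
$(x_i, y_i)_{i=1:n}$ and, per feature $g$, nonnegative counts or
intensities $(w_i)_{i=1:n}$.

Each feature receives a single nonnegative number, the **Coefficient of
Spatial Structure (CoSS)**. Genes with well-defined expression hotspots (or
voids) score high; diffusely expressed genes score near zero. Because the
score is continuous and robust to tissue morphology, it supports not only
spatially-variable-gene (SVG) calling within a sample but also comparisons
of spatial organisation *between* samples — e.g. quantifying the loss of
tubular-marker organisation between acute and chronic kidney disease
sections.

## The pipeline

For one feature with normalized weights $w_i$ ($\sum_i w_i = 1$):

1. **Smoothing** — a weighted distance-to-measure with idealized network
   distances. For each well $p$, order all wells by distance to $p$ and take
   the smallest $k$ with $\sum_{i=1}^{k} w^{(i)} \ge m$; then

   $$\mathrm{dtm}(p; m) = \frac{1}{k} \sum_{i=1}^{k} d_i^2,$$

   where $d_i$ is the distance of the $i$-th nearest site in the *infinite
   ideal lattice* ($d_1 = 0$), not in the data. This substitution treats
   every well as if it sat in the bulk of the grid, so tissue edges and
   holes do not inflate the smoother. The mass fraction $m \in (0,1)$
   (default 0.1) should be roughly the fraction of tissue occupied by the
   smallest feature of interest (0.01 suits high-resolution MSI).
2. **Inversion** — $z_i = \max_j \mathrm{dtm}(x_j;m) - \mathrm{dtm}(x_i;m)$,
   the "expression landscape": high over hotspots, minimum exactly 0.
3. **Persistence** — on the well adjacency graph (6-connected hexagonal or
   4-connected square), vertices carry $z_i$ and edges
   $\min(z_i, z_j)$; 0-dimensional persistent homology of the upper star
   filtration tracks connected components of $\{z \ge t\}$ as $t$
   decreases. Each component is a bar $(\text{birth}, \text{death})$;
   never-dying components are killed at the global minimum (so voids of
   expression also contribute).
4. **Scoring** — $\mathrm{CoSS} = \left(\sum_b \ell_b^{\,p}\right)^{1/p}$
   over bar lifetimes $\ell_b$, default $p = 2$. A companion **ratio
   statistic** $\ell_{\max} / \#\{\text{bars}\}$ flags features whose
   structure is one dominant bar (e.g. a single highly expressed well, a
   common technical artifact).

SVG calling ranks features by CoSS and places the cutoff at the knee of the
CoSS–rank curve (kneedle algorithm); any practitioner-chosen rank or score
cutoff can be used instead. Differential analysis ranks features by the
difference in group-mean CoSS between two sample groups.

## Worked example

```r
library(cossr)

spec <- synthetic_spec(
  n_rows = 20, n_cols = 20, spacing = 100,
  features = list(
    glom  = pattern_hotspot(rbind(c(0.25, 0.3), c(0.7, 0.65)), 60, 0.07),
    tub   = pattern_ring(c(0.5, 0.5), 0.3, 0.06, 40),
    house = pattern_uniform(20),
    spike = pattern_single_well_spike(300)),
  noise = "nb", seed = 7)
s <- simulate_sample(spec)
s
#> sample_data: 4 features x 400 wells (hexagonal, raw counts)

tab <- coss(s, m = 0.1)
called <- call_svgs(tab, cutoff_rank = 2)
called[, c("feature_id", "coss", "ratio", "n_bars", "rank", "sv")]
#>   feature_id      coss      ratio n_bars rank    sv
#> 1      spike 551931.25 275962.500      2    1  TRUE
#> 2       glom 185486.51  57740.458      3    2  TRUE
#> 3        tub  77458.90   8240.741      9    3 FALSE
#> 4      house  35946.27   1711.468     19    4 FALSE
```

Reading the output: the two-hotspot gene `glom` scores 5× the uniform
housekeeper `house` and carries its structure in 3 prominent bars; the ring
gene `tub` sits in between; and `spike` — all mass in one well — tops the
table but with an extreme ratio statistic (one bar explains everything),
the signature of a technical artifact rather than tissue structure. CoSS
units are (lattice spacing)², here spacing = 100. On a curve with hundreds
of features the `call_svgs()` knee is found automatically; with only four
features a manual `cutoff_rank` is used.

Real data come in through `read_sample()` (wide/long tables, MatrixMarket
triplets, Visium directories with `tissue_positions.csv`), normally followed
by `cpm_normalize()`. Raw coordinates are aligned to the ideal grid by
`align_to_lattice()`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cossr", package = "cossr"))')
$CLI simulate --out-prefix demo --hotspots 3 --uniforms 20 --seed 5
$CLI score    --input demo_counts.tsv --positions demo_positions.tsv \
              --format long_table --m 0.1 --out scores.tsv
$CLI call     --scores scores.tsv --out called.tsv
$CLI diff     --manifest samples.tsv --group-a AKI --group-b CKD --out diff.tsv
```

Every output is accompanied by a JSON run manifest (resolved configuration,
input digests, package version). Exit codes: 0 ok, 2 usage error, 3 data
error.

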