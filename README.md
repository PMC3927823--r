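# arcmorph

Did a clade speciate by geographic fragmentation (vicariance) or by
adaptive divergence in sympatry? `arcmorph` answers that question for
small clades — the kind produced by mountain-uplift radiations — from
three ordinary data streams:

* **point localities** (herbarium or field records) per species,
* a **dated species tree** (newick with branch lengths in Ma),
* **specimen trait measurements** (here: capitulum length/width and leaf
  length/width, in mm).

The logic: vicariant speciation predicts allopatric ranges (little or no
overlap between close relatives) and modest morphological divergence;
adaptive speciation permits range overlap and predicts strong trait
divergence. The package quantifies both sides of that contrast and tests
it between clades.

## What it computes

1. **Convex-hull ranges.** Localities are projected to a planar km frame
   (equirectangular, anchored at the data centroid, R = 6371 km) and each
   species' range is the convex hull of its points. Pairwise overlap is

   ```
   overlap(i, j) = area(range_i ∩ range_j) / min(area_i, area_j)
   ```

   so 1 means the narrower range is fully embedded in the wider one.
   Degenerate ranges (fewer than 3 non-collinear localities) are scored by
   the fraction of their points inside the other polygon.

2. **Nested average of range overlap at each node** (the age–range
   correlation table). For a node with daughter clades L and R,
   O(L, R) is the pairwise overlap for two tips and otherwise the plain
   average over a clade's two daughters — equivalently a weighted sum of
   cross-clade tip overlaps with tip weights (1/2)^(depth in its clade).

3. **Morphometric divergence.** Species means, pooled within-group
   covariance S_W = Σ (n_i − 1) S_i / (N − k), squared Mahalanobis
   distances D²(i, j) = (μ_i − μ_j)ᵀ S_W⁻¹ (μ_i − μ_j), and canonical
   (discriminant-function) axes — eigenvectors of S_W⁻¹B scaled to unit
   within-group variance, so centroid distances in canonical space equal
   D².

4. **Clade contrasts.** Within-clade pairwise values are compared between
   two clades with a pooled-variance Student t (df = n₁ + n₂ − 2; two
   clades of 6 and 4 species give 15 and 6 pairs, df = 19) and with a
   species-label permutation null that respects the non-independence of
   pairs sharing a species.

5. **Alignment checks.** FASTA/NEXUS readers and a parsimony-informative
   site counter (a column is informative when ≥ 2 resolved states each
   occur in ≥ 2 taxa; gaps, `?` and IUPAC ambiguity codes count as
   missing) for validating molecular input matrices.

6. **Synthetic data.** A seeded generator producing a two-clade Yule
   tree, ranges that fragment (vicariant) or duplicate (sympatric) at
   speciation with Gaussian dispersal, noisy localities, and four
   correlated log-Brownian traits with opposite mean shifts at sympatric
   splits — so the whole pipeline is testable without any downloads.

## Worked example

```r
library(arcmorph)

ds <- generate_dataset(sim_config(seed = 42))   # clade A vicariant, B sympatric
paths <- write_dataset(ds, "demo")
run_pipeline("all",
             localities = paths[["localities"]], tree = paths[["tree"]],
             specimens = paths[["specimens"]], clades = paths[["clades"]],
             out = "demo/results", seed = 42, permutations = 999)
cat(readLines("demo/results/clade_contrasts.txt"), sep = "\n")
```

```
Clade contrasts (pooled-variance t, species-label permutation null)
within-clade range overlap: mean A/B = 0 vs 0.5463; t = -10.9426, df = 19, parametric P = 1.21e-09, permutation P = 0.007 (B = 999, seed 42)
within-clade Mahalanobis D2: mean A/B = 22.27 vs 406.3; t = -5.1952, df = 19, parametric P = 5.15e-05, permutation P = 0.038 (B = 999, seed 42)
```

Clade A (vicariant) shows zero within-clade range overlap and mean
squared Mahalanobis distance 22; clade B (sympatric-adaptive) overlaps
heavily (mean 0.55) and is an order of magnitude more divergent
morphologically (mean 406) — the signature the method is built to
detect. `demo/results/arc_table.csv` holds the per-node nested overlaps:

```
  node_id   age_ma nested_overlap
1      n9 6.038414      0.3693741
2      n8 3.816191      0.4243012
3      n5 1.923816      0.0000000
4      n2 1.703442      0.0000000
```

The same stages are available from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "arcmorph.R", package = "arcmorph"))')" \
    simulate --out demo --seed 42
```

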