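---
title: "Discriminating vicariant from adaptive speciation with arcmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating vicariant from adaptive speciation with arcmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcmorph)
```

## The question and the data

Two classic geographic modes of speciation leave different footprints in
extant clades. Under **vicariance** — fragmentation of a continuous
range, for example by landscape erosion — sister species should occupy
non-overlapping (allopatric) ranges and, absent divergent selection,
differ only modestly in morphology. Under **adaptive (ecological)
speciation**, divergence is driven by selection, ranges may remain
overlapping, and morphological differences should be pronounced.
`arcmorph` operationalises this contrast for small clades from three
inputs: point localities per species, a time-calibrated species tree,
and specimen-level measurements of a small set of putatively selected
traits (floral-head and leaf dimensions in the motivating system).

## Range construction and overlap

Localities (decimal degrees) are projected onto a single equirectangular
plane anchored at the data centroid with Earth radius 6371 km:
$x = R\cos\phi_0\,(\lambda-\lambda_0)\pi/180$,
$y = R(\phi-\phi_0)\pi/180$. For study extents of a few hundred
kilometres the distortion is far below locality precision (here several
km); geodesic-exact areas are a non-goal. Each species' range is the
convex hull of its projected localities, built by the monotone-chain
algorithm with collinear boundary points dropped, its area by the
shoelace formula. Convex hulls over-estimate ranges, which makes low
measured overlap a *conservative* indicator of allopatry.

Pairwise overlap is the intersection area (convex–convex clipping)
divided by the smaller range's area, so complete embedding scores 1.
Ranges with fewer than three non-collinear localities have zero area;
rather than inflating them with an arbitrary buffer radius, a degenerate
range is scored by the fraction of its localities lying inside or on the
other polygon, and two degenerate ranges count as overlapping only when
localities coincide within $10^{-6}$ km. The carried `precision_m`
column is deliberately *not* used to buffer hulls, matching practice
when imprecise records are used directly.

## Nested overlap on the tree

For an internal node with daughter clades $L$ and $R$ the nested average
of range overlaps is defined recursively: for two tips it is the
pairwise overlap; for a clade with daughters $X_1, X_2$ it is the plain
average $(O(X_1,\cdot)+O(X_2,\cdot))/2$. Equivalently each tip receives
weight $(1/2)^{d}$ inside its daughter clade, where $d$ counts the
internal nodes between the clade root (inclusive) and the tip, and the
node value is the weighted sum over cross-clade tip pairs. Both forms
are implemented (the recursion in the package, the closed form as an
independent oracle in the tests) and agree to $10^{-12}$ on a thousand
random trees. The per-node table, ordered by node age, is the age–range
correlation (ARC) table; a descriptive OLS fit of overlap on age is
attached, without the Monte-Carlo null of full ARC inference, which the
motivating analysis did not use. Trees must be binary; polytomies are
resolved into a caterpillar of zero-length edges with a warning, which
leaves the nested average invariant for the affected ages.

## Morphometric divergence

With $k$ species measured on $p = 4$ traits, species means feed a pooled
within-group covariance $S_W=\sum_i (n_i-1)S_i/(N-k)$ over species with
$n_i \ge 2$ (a species with one specimen keeps its mean but contributes
no covariance; the motivating data include a species with only two
specimens). Squared Mahalanobis distance
$D^2_{ij}=(\mu_i-\mu_j)^\top S_W^{-1}(\mu_i-\mu_j)$ is the squared
Euclidean distance after whitening; it is invariant to affine
transformations of the measurements, so no log transform or
standardisation is applied beforehand. Distances are reported as $D^2$
(with $D$ as a secondary column) because the large printed magnitudes in
this literature (hundreds) are consistent with squared distances. A
condition number above $10^{12}$ in $S_W$ raises an error rather than a
silent pseudo-inverse; with four hand-measured traits this indicates a
redundant trait.

Discriminant (canonical variates) axes are eigenvectors of $S_W^{-1}B$
scaled so within-group score variance is 1 per axis, computed via a
Cholesky whitening and a symmetric eigenproblem for stability. With that
normalisation, centroid distances in the full canonical space reproduce
$D^2$ exactly — a tested identity. Whether such an analysis is run on
specimens or on species means is often ambiguous in practice; both entry
points exist (`level = "specimen"` weights the between-group scatter by
$n_i$ and is the default; `level = "species"` weights species equally).

## Clade contrasts and the permutation null

The contrast statistic compares the $\binom{n_1}{2}$ and
$\binom{n_2}{2}$ within-clade pairwise values (overlaps or $D^2$)
between two clades with a pooled-variance Student $t$,
$df = n_1 + n_2 - 2$; clades of 6 and 4 species give 15 and 6 pairs and
$df = 19$. The pooled (not Welch) form is used precisely because that df
arises from treating the pairwise values as plain samples. Pairs sharing
a species are not independent, so the randomised null permutes **species
labels** (clade sizes preserved), recomputes the within-clade values and
$t$ for each draw, and reports
$p = (1 + \#\{|t^\ast|\ge|t_{obs}|\})/(1+B)$, two-sided, with $B = 9999$
by default and the seed recorded. Draws with zero pooled variance
(possible when an overlap matrix is mostly zeros) are redrawn with a cap
of $100B$ attempts. Because the null regenerates exactly the label
randomisation, the test is exact: its type-I error at $\alpha = 0.05$
sits inside the exact binomial 99% interval over 500 null replicates in
the acceptance suite. No multiple-testing correction is applied across
the two contrasts, mirroring standard practice for two pre-planned
comparisons.

Within-clade pair counts of 15 and 6 also illuminate a bookkeeping
subtlety in the motivating literature, where a count of "12
comparisons" and a df of 14 appear for a 6-species clade; those numbers
are not derivable from complete pairwise enumeration, so this
implementation always computes all $\binom{n}{2}$ pairs and documents
the discrepancy rather than guessing at exclusions.

## Alignment statistics

`read_alignment` accepts FASTA (via seqinr) and simple
DATA/CHARACTERS-block NEXUS, interleaved or sequential (via ape). A
column is parsimony-informative when at least two resolved states (A, C,
G, T; U folded into T) each occur in at least two taxa. Gaps, `?` and
IUPAC ambiguity codes are treated as **missing**, a conservative and
deterministic rule; tools that treat ambiguities as polymorphic can
count a handful more sites, which is why the summary report flags the
rule explicitly.

## The synthetic-data generator

The generator emulates the study design the pipeline targets, and its
defaults are fixed as the package's reference conditions:

| parameter | default | why |
|---|---|---|
| `n_species_per_clade` | A = 6, B = 4 | the motivating clade sizes; gives 15/6 pairs, df 19 |
| `birth_rate` | 0.45 / Ma | Yule rate putting 6-tip crown ages near 3–4 Ma (Pliocene) |
| `range_mode` | A vicariant, B sympatric | the two regimes under contrast |
| `root_range` | 300 × 150 km | scale of a montane endemism belt |
| `split_fraction` | 0.5 | unbiased range fragmentation |
| `dispersal_sd` | 10 km/√Ma | modest post-speciation range drift (secondary contact possible) |
| `localities_per_species` | 12 | herbarium-scale sampling (minimum of ~6 in the motivating data) |
| `locality_noise_sd` | 5 km | map-precision georeferencing error (records accurate to 5–10 km) |
| `bm_rate` | 0.02 /Ma (log scale) | ~15% trait drift per Ma, typical slow morphological BM |
| `bm_corr` | 0.5 | sizes of organs co-vary |
| `sympatric_divergence_boost` (κ) | 5 | see below |
| `specimens_per_species` | 20 | the standard measurement effort per species |
| `measurement_cv` | 0.1 | 10% within-species variation in linear measurements |

Trees are forward pure-birth processes conditioned on the tip count
(interval with $k$ lineages $\sim \mathrm{Exp}(k\lambda)$, plus one
final $\mathrm{Exp}(n\lambda)$ stretch), joined at a root aged at the
taller clade plus one expected waiting time $1/\lambda$ — the crown/stem
detail is irrelevant to the contrasts. The root range is copied to both
basal clades, since the regimes are defined within clades. Vicariant
splits cut the parent polygon by a random chord positioned (by
bisection on the half-plane offset) so one daughter takes
`split_fraction` of the area: daughter overlap is exactly 0 at birth.
Sympatric splits copy the polygon: overlap exactly 1 at birth. Dispersal
is pure translation — the simplest displacement model that creates
secondary contact or withdrawal without changing range shape.

Traits evolve on the **log scale** (guaranteeing positive mm values)
by correlated Brownian motion; at each sympatric split the daughters
receive opposite shifts of magnitude $\kappa\sqrt{\texttt{bm\_rate}}$ on
one random trait axis — a minimal model of character displacement. The
default $\kappa = 5$ is calibrated so the adaptive clade's mean pairwise
$D^2$ exceeds the vicariant clade's by roughly an order of magnitude,
the contrast scale reported for strongly ecologically diverged clades
(within-clade $D^2$ mostly below 30 on one side versus values of
100–900 on the other): pairwise Brownian variance is about
$p \cdot 2\bar t\,\sigma^2$ while the boosts contribute about
$(4 + \text{extra splits})\kappa^2\sigma^2$, and $\kappa \approx 5$
reproduces that ratio. Measurement noise is lognormal with the given CV
($\sigma_{\log} = \sqrt{\log(1+\mathrm{cv}^2)}$).

What the generator does **not** emulate: real herbarium sampling bias
(collectors revisit accessible sites), non-convex or disjunct true
ranges, substrate- or climate-structured trait selection, and
phylogenetic signal in sampling effort. Passing the recovery tests
therefore shows the pipeline detects the regime contrast under idealised
allopatry/sympatry geometry and displacement-style divergence — not that
it would be equally powered on any empirical dataset.

## Numerical choices

* Orientation predicates use plain double-precision cross products;
  collinear hull vertices are dropped. Overlap proportions are clamped
  to [0, 1] against rounding at the third–fourth decimal of area ratios.
* Half-plane clipping uses a $10^{-12}$ tolerance on signed distances;
  point-in-polygon membership uses $10^{-9}$ so boundary points count as
  inside.
* The permutation p-value uses the add-one estimator, which can never
  return 0 and keeps the test exact.
* Ages are derived as max tip depth minus node depth, so slightly
  non-ultrametric inputs (rounding in tree files) are accepted with a
  warning instead of an error.
* All generators consume a single seeded RNG stream; `generate_dataset`
  seeds once and the sub-generators inherit the stream, so datasets are
  byte-reproducible from (config, seed).

## Problem sizes in the test suite

The suite exercises the geometry oracle on 50 hull and 50 intersection
instances with $2\times10^5$ Monte-Carlo samples each, the
nested-overlap identity on 1,000 random trees of up to 16 tips, the
permutation calibration on 500 null replicates of a 199-permutation
test, and regime recovery on 100 full-pipeline replicates at the default
configuration — sizes chosen to give stable pass/fail behaviour at
interactive runtimes.

## Known limitations

* Convex hulls ignore range discontinuities; strongly crescent-shaped
  ranges can show spurious overlap (a caveat the motivating study itself
  notes), and no alpha-shape or kernel estimator is offered.
* The nested-overlap recursion requires a binary tree; the caterpillar
  resolution of polytomies is arbitrary but inert for zero-length edges.
* The pooled-t contrast treats pairwise values as exchangeable samples;
  the permutation null is the principled alternative and is always
  reported alongside it.
* The ambiguity-as-missing rule can undercount parsimony-informative
  sites relative to tools that resolve ambiguities.
* Tree inference, divergence dating and ancestral-area reconstruction
  are out of scope: the dated tree is an input.
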