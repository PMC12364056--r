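---
title: "Methods: persistent Stanley–Reisner invariants for alignment-free sequence comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: persistent Stanley–Reisner invariants for alignment-free sequence comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cakl)
```

## The model

`cakl` compares sequences without alignment by encoding, for every
k-mer, *where* it occurs rather than merely how often. The occurrence
positions of a k-mer `x` in a sequence `S` form a finite point cloud
`S_x` on the integer line (1-based start coordinates, overlapping
occurrences all counted). The Vietoris–Rips filtration on `S_x` —
a subset is a simplex at radius `t` iff its diameter is at most `t`,
with the **closed** condition `|x_i − x_j| ≤ t` — evolves from isolated
vertices at `t = 0` to a single full simplex once `t` reaches the
largest gap.

One-dimensional point clouds are special in two ways that shape the
whole design:

1. **Homology is silent.** Every Rips complex on the line has vanishing
   reduced homology in all degrees ≥ 1 (a Mayer–Vietoris induction over
   facets ordered by their minima). Persistent homology barcodes would
   therefore carry only component counts.
2. **Facets are runs.** Each facet (maximal simplex) is a maximal run of
   consecutive sorted points and is uniquely determined by its minimal
   element. The run `[x_a, …, x_b]` is a facet exactly on the scale
   interval `[x_b − x_a, min(x_{b+1} − x_a, x_b − x_{a−1}))`, so the
   full facet barcode is closed-form in the sorted points.

The algebraic viewpoint tracks the Stanley–Reisner ideal of the complex:
its primary components correspond one-to-one with facets, so facet
barcodes are barcodes of persistent prime components; graded Betti
numbers of the Stanley–Reisner ring are computed combinatorially through
Hochster's formula, which on the line collapses to degree shift one:

* `β_{0,0} = 1` always, `β_{i,i+j} = 0` for `j ≥ 2`, and
* `β_{i,i+1}(t) = Σ over index pairs a < b with x_b − x_a > t of
  C(n − (b − a + 1), i − 1)`:
  a pair of points further apart than `t`, taken consecutive inside an
  `(i+1)`-subset, contributes exactly one extra connected component of
  the induced subcomplex, and the remaining `i − 1` vertices may be
  chosen freely outside the enclosed index interval.

For the persistent version across a scale pair `t ≤ t′`, the vertex set
is fixed, so the inclusion-induced map on degree-0 reduced homology of
every induced subcomplex is surjective (components only merge); the
persistent `j = 1` entry therefore equals the static entry at `t′`.
This is a derived simplification, not an assumption: the package keeps a
brute-force union-find route (`method = "oracle"`) and the test suite
checks the two against each other on random instances.

Persistent h-vectors follow from the Betti numbers via
`h_m(t,t′) = α_0^m + Σ_{j=1}^m α_j^m (−1)^{j−1} β_{j−1,j}(t,t′)` with
`α_j^m = C(n − d + m − j − 1, m − j)` and `d = dim(Δ^{t′}) + 1`;
persistent f-vectors are the inverse binomial transform. On the diagonal
`t = t′` both reduce exactly to the classical vectors — an identity the
tests assert on random instances, because it exercises every binomial
convention at once.

## Feature vectors and distances

`feature_config()` fixes the representation layout:

| parameter | default | meaning |
|---|---|---|
| `k` | 4 | k-mer length; 3–5 work well, 4 is the default for classification |
| `grid` | radii 0..50, step 1 | sampling radii; positions are integers, so all birth/death values are integers and an integer grid loses nothing |
| `dmax` | 5 | dimension rows per curve; facets of dimension ≥ `dmax − 1` accumulate into the last row so dense clusters cannot blow up the layout |
| `feature_types` | `"facet"` | which curves enter the vector; `"fvec"`/`"hvec"` add classical f-/h-vector curves |
| `normalize` | off | optional division by the window count `N − k + 1`; raw counts are the default and the convention used everywhere in the tests |

Curves are sampled on the diagonal `r = r′` of the filtration (the
off-diagonal persistent invariants remain available programmatically).
Per k-mer the curve matrix is flattened dimension-major, and blocks are
concatenated over all `|A|^k` k-mers in lexicographic order of the
alphabet as given — a convention, not canon; it only matters that the
layout is identical across sequences compared under one configuration.
Every invariant depends only on pairwise position gaps, so
representations are invariant under global translation of the sequence.

Distances: per feature type,
`d = sqrt( Σ_k Σ_i a_{k,i} ‖v1_{k,i} − v2_{k,i}‖² )`, a weighted
Euclidean metric; the composite distance is the *sum* of the per-type
metrics. The square root is applied to the weighted total because the
rooted form is what makes each term a metric (the unrooted sum of
squares is available via `sqrt_total = FALSE`). Default weights are
`a_{k,i} = 1/2^{k−1}`; with the production choice of a single fixed `k`
this is a global rescaling and cannot change any nearest-neighbor
ranking, which the tests assert. `a_{k,i} = 1/2^{i·K + k − 1}` is
available for dimension-sensitive weighting, and multi-k aggregation is
supported programmatically even though every shipped protocol uses one
`k` at a time.

## Numerical conventions

* **Binomials.** `C(a, 0) = 1` for every `a` (including negative);
  `C(a, b) = 0` for `b < 0`, `b > a`, or `a < 0` otherwise. This makes
  `α_m^m = 1` and the full-simplex case `h = (1, 0, …, 0)` come out
  right without special-casing.
* **Half-open life intervals.** A facet is alive at its birth radius
  and dead at its death radius, so "connects at radius 5, vanishes at
  radius 7" is literal: alive at 5 and 6, gone at 7.
* **Ties.** Duplicate positions cannot occur for a fixed k-mer; the
  filtration code still rejects ties explicitly rather than silently
  deduplicating. UPGMA breaks equal minimal distances by merging the
  pair whose cluster ids (each cluster named by its lexicographically
  smallest leaf) sort first, and orders children the same way, so trees
  are identical across platforms and input orderings. k-NN votes break
  ties by the smaller summed neighbor distance, then the smaller label;
  nearest-neighbor ties go to the smallest id.
* **Integer arithmetic.** All Betti/f/h computation is exact; only the
  distance layer is floating point (plain accumulation; curve entries
  are small integers, so cancellation is negligible at 1e-9 relative
  tolerance).
* **Degenerate inputs.** An empty position set contributes an all-zero
  feature block; a singleton contributes a constant `F_0 ≡ 1` curve.
  Ambiguity codes (N, R, Y, …) are preserved in sequences but any
  window containing one matches no canonical k-mer; only the forward
  strand is scanned, since reverse-complement collapsing would change
  the position sets themselves.
* **`d` for persistent vectors.** The parameter is taken from the
  *later* scale, `d = dim(Δ^{t′}) + 1`, which is the choice under which
  the diagonal case reduces exactly to the classical transforms.
  Off-diagonal persistent f-vectors may be non-integer or negative;
  they are emitted as computed, not clamped.

## Trees, purity, classification

UPGMA (size-weighted average linkage, merge height = distance/2) is
implemented in the package so the tie rule above is fully specified; it
is cross-checked against `phangorn`'s average-linkage implementation on
random tie-free matrices. Purity of a label ℓ marks every node whose
descendant leaves all carry ℓ, takes the maximal such nodes as blocks
`S_1, …, S_k`, and scores `Σ (|S_i|/n_ℓ)²` — 1 iff ℓ is monophyletic,
`1/n_ℓ` when fully scattered; singleton blocks are legitimate blocks.
Purity is evaluated on the rooted UPGMA tree as produced (maximal
subtrees presuppose a root, and UPGMA supplies one), and the average
purity is the unweighted mean over labels.

Two evaluation protocols operate on precomputed distance matrices:
leave-one-out 1-NN (each sample classified by its nearest other sample —
the leave-one-out realization of annotating new genomes by proximity to
references; a fixed reference/query split can be emulated by subsetting
the matrix), and k-NN under stratified 5-fold cross-validation repeated
over 30 seeds, fixed to `0:29` for reproducibility. Accuracy is micro by
definition; F1, recall and precision are macro-averaged over the classes
present in each test fold (precision of a never-predicted class counts
as 0), and balanced accuracy equals macro recall by construction —
asserted on every report. Classes with fewer than 15 members are dropped
by `filter_min_class_size()` before classification, matching the
standard protocol for imbalanced viral family sets.

## The synthetic generator

`simulate_families()` stands in for real labeled datasets: each family
gets an independent uniform-random ancestor, and members accumulate
i.i.d. per-site substitutions uniform over the three alternative bases
(a Jukes–Cantor-like neutral model), optionally with rare single indel
events (uniform length up to `indel_max_len`, insertion or deletion
equally likely). Defaults — 4 families × 10 members, 3 kb ancestors, 1%
substitution rate, no indels — give families whose within-family
distances are clearly below between-family distances, which is the
regime the recovery tests target: UPGMA purity 1.0, LOO-1-NN 1.0, and
perfect 5-NN cross-validation across all 30 seeds.

What the generator does *not* emulate: rate heterogeneity across sites,
coalescent family structure, shared ancestry between families,
compositional bias, or sequencing error. Passing the recovery tests
therefore demonstrates that the pipeline separates what is separable and
is internally consistent — not that it reaches any particular accuracy
on real viral data, where label noise and uneven divergence dominate.

## Problem sizes and validation strategy

Every closed-form route is gated on a brute-force oracle: facet
enumeration and f-vectors against full subset enumeration, graded Betti
numbers against Hochster subset-sums with GF(2) homology ranks, the
persistent shortcut against union-find component ranks — each on ~100
random instances of up to 10 points (the oracles carry a hard `n ≤ 14`
guard; they are test fixtures, not production code). GF(2) coefficients
suffice for the vanishing and rank checks asserted here and avoid
rational pivoting. The suite's end-to-end runs use 2–4 families, 150 bp
to 3 kb ancestors and k ∈ {1, 2, 4}, sizes chosen so the whole suite
exercises every stage in a couple of minutes while the oracle
comparisons stay exhaustive.

## Known limitations

* The closed-form machinery is strictly one-dimensional; none of it
  extends to point clouds in the plane or higher (where Rips homology
  does not vanish), and no 2-D fallback is provided.
* Minimal free resolutions and Tor modules are out of scope; graded
  Betti numbers are only computed through the combinatorial route.
* The default radius grid caps at 50: k-mer occurrence gaps larger than
  that are indistinguishable from "far". For genome-scale inputs with
  sparse k-mers the cap is a real modeling choice and is exposed in
  `feature_config()` and recorded in output metadata.
* Feature vectors grow as `4^k · dmax · |grid|`; k beyond ~6 is
  impractical and, empirically, unhelpful — larger k makes
  representations more unique per genome and less shared per family.
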