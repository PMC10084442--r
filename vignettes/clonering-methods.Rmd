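---
title: "Methods: clonal population genetics of haploid fungi with clonering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal population genetics of haploid fungi with clonering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonering)
```

`clonering` analyses haploid genotype data from clonally propagating,
heterothallic fungi: samples scored at a panel of microsatellite (SSR)
loci plus the single mating-type locus, georeferenced in planar metres
and tagged by tissue role (gleba, ascospore extract, ECM root tip,
soil). This vignette is the package's own account of the statistical
machinery: the models, the defaults and why they were chosen, the
numerical corner cases, and what the synthetic-data generator does and
does not establish.

## Data model and exclusion rule

A genotype table has one row per sample and one integer column per SSR
locus. Alleles are compared as exact integers — fragment-size binning
is an upstream concern of the fragment-analysis software, not of this
package. Records missing any SSR call or the mating type are retained
but flagged `resolved = FALSE` and excluded from genetic analyses as
whole samples (no per-locus missingness handling): partial haploid
profiles cannot be assigned to an MLG unambiguously, and mixing panels
within one analysis would silently change what "identical" means.
Sub-panels (e.g. a marker dropped for one tissue type) are supported by
passing `loci` explicitly, making the active panel a visible argument
of every analysis.

Coordinates are planar metres throughout; any projection from
geographic coordinates happens upstream. All distance-based statistics
(clonal subrange, distance classes, aggregation) are metric.

## MLG identity and the clonality test

Two samples share a multilocus genotype (MLG) only if they agree at
every SSR locus *and* the mating-type idiomorph; MAT is part of genet
identity because two mycelia of opposite mating type are necessarily
distinct individuals. Identifiers are assigned in first-seen order, so
assignment is deterministic.

A repeated MLG may be one clone or a coincidence of sexual events. The
probability of one genotype under random assortment is
`p_gen = prod_l f(a_l)`, the product of its allele frequencies
(linkage equilibrium assumed; reasonable for unlinked SSRs). The
clonality statistic is the binomial tail

`P_sex = P(X >= n_copies)`, `X ~ Bin(N, p_gen)`,

the probability that independent sexual events alone would yield at
least the observed number of copies among `N` genotyped samples. Two
conventions exist for the tail; the plain binomial above is the
default, and the variant that conditions on the first observation
(`P(X >= n−1)` among `N−1`) is available via `method = "parks_werth"`.

Significance is calibrated by Monte Carlo: `n_sim` (default 1000)
replicate datasets of `N` genotypes are drawn locus-wise from the
allele frequencies, the `P_sex` values of every repeated genotype in
the replicates form the null distribution, and an observed MLG is a
significant clone when its `P_sex` lies strictly below the
`alpha`-quantile (default 0.05) of that null. Ties at the quantile
resolve to non-significant — the conservative direction. Two
degeneracies are handled explicitly: with no polymorphic locus the null
is meaningless (repeats are certain) and all repeated MLGs are flagged
with a warning; when the null produces no repeated genotype at all, any
observed repetition is already more extreme than everything the null
can show, and repeats are flagged significant.

Allele frequencies for `p_gen` are computed from clone-corrected
samples by default (one representative per MLG), because raw
frequencies are inflated by the very clones under test. A round-robin
(leave-one-MLG-out) mode exists for sensitivity analysis; an allele
that then has zero estimated frequency is substituted by the smallest
observed frequency, with a warning.

## Clone correction and diversity

Clone correction replaces each *significant* MLG by one representative
placed at the arithmetic-mean centroid of its positioned ramets.
Ramets of repeated but non-significant MLGs are kept as distinct
genotypes — their identity is plausibly coincidental — and singletons
pass through unchanged. Representatives without any positioned ramet
keep `NA` coordinates and drop out of spatial statistics only.

Diversity indices follow the genet/ramet convention:

* richness `R = (G − 1)/(N − 1)`, where `G` counts genotypic units
  (a significant MLG is one unit; each ramet of a non-significant
  repeat is its own unit);
* unbiased Simpson diversity `D* = 1 − Σ nᵢ(nᵢ−1)/(N(N−1))`;
* evenness `ED*`: `D*` rescaled between its minimum and maximum
  attainable at the observed `(N, G)` — the minimum from the maximally
  skewed composition (`G−1` singletons, one clone of `N−G+1`), the
  maximum from counts differing by at most one. The exact evenness
  formula of the legacy clonal-analysis software is not published, so
  this Fager-type construction was adopted and verified against
  brute-force enumeration over all compositions for small `N` in the
  test suite; it is exactly 1 for equal counts and lives in [0, 1].
* gene diversity `uHe = n/(n−1)(1 − Σp²)` per locus, reported with its
  over-locus mean, conventionally on clone-corrected data.

The mating-type locus contributes to MLG identity but is excluded from
`p_gen`, `uHe` and `Φ_PT` by default — it is a biallelic functional
locus under balancing selection, not a neutral SSR. Switches
(`include_mat`, explicit `loci`) expose the alternative.

## Paternal inference and the mating system

Pooled ascospore DNA from one fruitbody carries both parental haploid
genomes, so each locus shows one or two alleles. Paternal alleles
follow by Mendelian subtraction against the maternal (gleba) genotype;
a single shared allele means father and mother coincide there. The
paternal mating type is always the opposite idiomorph —
heterothallism leaves no choice. Inference is rejected per fruitbody
(not per locus) when a spore set lacks the maternal allele
(mismatch/contamination) or holds more than two alleles (two fathers
cannot be resolved; such fruitbodies are logged and excluded).

Reconstructed zygotes give the inbreeding coefficient
`F_is = 1 − mean(Ho)/mean(He)` over loci, with `Ho` the fraction of
heterozygous zygotes and `He = 1 − Σp²` from the zygote allele pool;
the plain ratio-of-means definition is used verbatim, with an optional
`2n/(2n−1)` correction off by default. Monomorphic loci contribute zero
to both means; a fully monomorphic zygote set raises an error rather
than returning 0/0.

Hermaphrodites are genets observed in both sex roles (maternal = gleba
or ECM tissue; paternal = ascospore inference). Because a hermaphrodite
is necessarily a repeated MLG, the report can be restricted to
significant clones.

## Spatial statistics

**Aggregation index.** The published description of the
nearest-neighbour aggregation index is verbal (0 at random expectation,
1 when all nearest neighbours share the label). The closed form
implemented here is

`Ac = (P_nn − P_all) / (1 − P_all)`,

with `P_nn` the proportion of samples whose nearest neighbour carries
the same label (ties averaged over co-nearest neighbours) and `P_all`
the probability that two random distinct samples share a label. This
satisfies both anchor points and is invariant to rotation, translation
and label renaming; it is flagged prominently because it is a
reconstruction, not a transcription. Significance permutes labels over
fixed positions, one-sided for aggregation, with add-one smoothing
`p = (1 + #{Ac_perm ≥ Ac_obs})/(n_perm + 1)`.

**Mantel test.** Pearson correlation of off-diagonal distances with
simultaneous row/column permutation of one matrix; the haploid genetic
distance is the count of differing loci (configurable).

**Kinship autocorrelation and Sp.** Pairwise Loiselle kinship for
haploid indicator coding:

`F_ij = [Σ_l Σ_a (x_ia − p_a)(x_ja − p_a) + p_a(1−p_a)/(n−1)] / Σ_l Σ_a p_a(1−p_a)`,

with reference frequencies from the analysed (clone-corrected) sample
itself, which makes the all-pairs average exactly zero — the
small-sample term cancels the negative bias of sample-centred
cross-products. Monomorphic loci carry no information and are dropped
from both sums. Distance classes default to 13 between a first edge at
5 m and the maximum pair distance, with approximately equal pair counts
per class; explicit edges are accepted and empty classes are dropped
with a warning. Class-wise significance permutes individuals among the
fixed locations (two-sided, add-one). The decay summary is
`Sp = −b/(1 − F₁)` with `b` the slope of *pair-level* kinship on
ln(distance) — the pair-level regression is the default of the
reference autocorrelation software, and a class-level alternative would
weight classes equally regardless of pair counts. Pairs at distance 0
are excluded from the log regression; `max_regression_dist` restricts
the regression (e.g. to the first 5 m) to probe steep short-range
structure.

## Differentiation

`Φ_PT` partitions the sum of squared haploid distances (differing-locus
counts) among and within groups in the AMOVA framework:
`Φ_PT = Va/(Va + Vw)` from the usual method-of-moments variance
components with unequal group sizes. Negative `Va` estimates — expected
noise around zero differentiation — are truncated to 0 with a warning,
the standard convention. Significance permutes genotypes across groups;
pairwise group matrices recurse on the two-group case with
deterministic per-pair seeds.

## qPCR quantification

The standard curve is `Cq ~ log10(copies)` by least squares; efficiency
is `10^(−1/slope) − 1`, and a curve is reliable only with `R² ≥ 0.997`
and efficiency within 90–110%. Quantification refuses unreliable curves
unless forced. Triplicate quality is the coefficient of variation
`(sd/mean)×100` computed on back-transformed copy numbers, not on Cq —
copies are the quantity of interest and the Cq scale is logarithmic;
the flagging threshold (default 15%) is a configurable convention, as
no published cutoff exists. Scaling to copies per gram of dried soil
encodes the extraction defaults (250 mg soil, 100 µl eluate, 5 µl
template at 1:10), all overridable. Mass conversion uses the published
calibration 1 g dried mycelium = 9.37×10¹⁰ ITS copies.

Ring geometry: the centre defaults to a least-squares circle fit
(Coope linearisation) with a centroid fallback below 6 points, and the
growth rate is the least-squares slope of mean annual radius on year.
Age is `floor(radius/rate)` — a whole-years statement, deliberately
coarse given the linear-growth assumption.

## The synthetic-data generator

The generator is the package's test bed: it encodes the structure the
analysis assumes, with defaults fixed at the study conditions of a
natural fairy-ring site.

`simulate_fairy_ring()` places four annual fruitbody cohorts (default
harvest sizes 109, 78, 28, 76) on annuli expanding 0.30 m/yr from a
3.7 m initial radius with 0.15 m radial noise. The panel has 14 loci, 5
monomorphic, 1–8 alleles per locus under a strongly skewed frequency
profile (one dominant allele per locus; allelic weights decaying as
exp(−1.4·rank)), reproducing the low gene diversity of an isolated
population. One dominant maternal genet forms a fraction 0.976 of the
gleba samples; the remainder belongs to a minor genet of opposite
mating type. Fathers are simulated as single meiotic recombinants of
the maternal genotype and a pool haplotype (independent locus
assortment — haploid ascospores), fresh per fruitbody except for
occasional reuse (persistence probability 0.15), which produces the
observed handful of repeated paternal MLGs among many singletons.
Spore extracts are the per-locus unions of the parental alleles, with
both mating-type idiomorphs present (a recombinant pool).

`simulate_multigenet_site()` places genets by a Thomas cluster process,
propagates genotypes parent-to-offspring under a distance-weighted
kernel with per-locus resampling (producing isolation by distance),
assigns mating types by nearest patch seed (producing spatial MAT
aggregation), and fathers each fruitbody either by an ephemeral
recombinant spore or — with the configured probability — by a
persistent genet of opposite mating type under a distance-decaying
mating kernel, the mechanism that generates hermaphroditic MLGs and
positive `F_is` under local mating.

`simulate_ecm_and_soil()` overlays a transect soil survey: the true ITS
copy field is a Gaussian ridge on the current ring radius with decayed
interior (die-back behind the front) and an optional five-position
interior patch of the opposite mating type; ECM root tips appear where
the maternal mycelium is abundant and always carry the dominant
maternal genotype; Cq triplicates come from a configured standard curve
with 0.05-cycle replicate noise.

Every generator is deterministic under its seed (and restores the
global RNG state), and each truth record stores all parent assignments
and parameters, so tests score inferences exactly rather than
qualitatively.

**What passing tests do and do not show.** The generator reproduces the
*statistical skeleton* of real data: clone dominance, annular
expansion, singleton males, IBD, MAT patches, low allelic diversity. It
does not emulate genotyping error or allelic dropout (MLG assignment
here is exact-match; fuzzy multilocus-lineage collapsing is out of
scope), null alleles, uneven detection probability of fruitbodies,
multi-father fruitbodies, or real mycelial growth dynamics (the
interior-decay soil profile is phenomenological). Results on synthetic
data therefore validate the estimators' correctness and power under the
stated model, not robustness to those artefacts.

## Problem sizes and determinism

Simulation-heavy checks in the test suite run at reduced but honest
sizes chosen for a laptop-scale run: Monte-Carlo nulls of 100–1000
replicates, permutation tests of 20–5000 permutations checked against
exhaustive enumeration on ≤6-point instances, 10–50 replicate
simulations for power-style properties, and 10⁴ simulated crosses for
paternal-inference recovery. All Monte-Carlo entry points take an
explicit `seed` (default 1962, an arbitrary documented constant) and
never perturb the caller's RNG stream.

## Known limitations

* Exact-match MLG calling: a single miscalled allele splits a genet.
* `P_sex` assumes linkage equilibrium among loci; physically linked
  markers would overstate clonality significance.
* The `Ac` closed form is a reconstruction of a verbally specified
  index (see above).
* `Φ_PT` inherits AMOVA's method-of-moments behaviour: truncation at 0
  biases small values upward slightly.
* Cluster labels for differentiation analyses are inputs; Bayesian
  admixture clustering is intentionally out of scope.
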