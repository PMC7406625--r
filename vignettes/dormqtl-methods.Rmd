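---
title: "Bin-map QTL mapping of rice seed dormancy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-map QTL mapping of rice seed dormancy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormqtl)
options(dormqtl.quiet = TRUE)
```

## Scope

`dormqtl` maps quantitative trait loci (QTLs) for seed dormancy in rice
populations genotyped at many SNPs: chromosome segment substitution lines
(CSSLs, one or a few homozygous donor segments in a recurrent background),
backcross inbred lines (BILs, a BC1F1 advanced to near-homozygosity by
single-seed descent), and F2 progeny used for locus validation. The
pipeline has five statistical stages — genotype QC, recombination bin-map
construction, germination trait extraction, a ridge-regression genome
scan, and post-scan summaries (variance decomposition, cross-trait
clustering, epistasis tests) — plus a population simulator that provides
ground truth for every stage. This vignette documents the models, the
tunable parameters, and the decisions taken where the underlying methods
leave room.

## Genotype codes and QC

Genotypes are polarized parental-origin calls: `A` donor homozygote, `B`
recurrent homozygote, `H` heterozygote, `-` missing. Two QC rules are
applied before bin calling:

* **Heterozygote recoding** (`recode_het_to_missing()`): BILs are
  near-homozygous (expected residual heterozygosity $0.5 \cdot 2^{-g}$
  after $g$ selfing generations, about 0.4% at F8), so isolated `H`
  calls are mostly genotyping artifacts and are treated as missing. By
  default this is applied to BILs only; CSSL `H` calls are retained but
  are equally non-informative to the window caller, which counts only
  `A`/`B` calls.
* **Line missingness filter** (`filter_lines_by_missingness()`): lines
  with *strictly more than* 20% missing calls are removed. The boundary
  is strict — a line at exactly 20% stays.

## Bin-map construction

The bin caller smooths each line's call sequence with a sliding window
of `window = 15` SNPs and `step = 1`. A window is called from its
informative calls only ($a$ = donor, $b$ = recurrent):

$$\text{call} = \begin{cases}
A & a/(a+b) \ge 12/15\\
B & a/(a+b) \le 3/15\\
\text{undetermined} & \text{otherwise or fewer than 8 informative calls.}
\end{cases}$$

The proportion form reproduces the classical 12:3 / 3:12 counting rule on
complete windows and stays well defined when calls are missing; windows
with fewer than `min_informative = 8` informative calls are never called.
Three projection rules that the counting rule alone does not fix:

* **Window to marker**: each marker takes the majority vote of the
  determined windows covering it; ties are undetermined.
* **Undetermined runs**: absorbed into the flanking determined blocks by
  splitting at the bp midpoint of the span between the flanking
  determined markers; a leading or trailing undetermined run adopts its
  single neighbour. A breakpoint is therefore always the midpoint
  between the last marker of one block and the first marker of the next.
* **Chromosome ends**: blocks and bins run from 0 to the chromosome
  length (half-open), not from the first to the last marker.

The population bin map is the partition of each chromosome by the unique
breakpoint positions of all lines (`build_binmap()`); `merge_tol` (bp)
optionally pools nearly coincident breakpoints and defaults to 0, since
published bin maps of this kind resolve bins down to tens of kb. Because
every line's breakpoints are bin boundaries, each (line, bin) genotype is
unambiguous (`genotype_bins()`), and an internal assertion fails loudly
if that invariant is ever violated.

The window width sets the method's resolution: donor segments shorter
than roughly 12 of 15 consecutive markers cannot produce a called block
and are smoothed away. This is a property of the published rule, not of
this implementation; the simulator-based tests therefore condition their
exactness claims on segments at least twice the window span.

## Germination traits

From cumulative counts of a 50-seed dish scored every 24 h for 7 days:

* `G3d`, `G7d`: cumulative germination percentage at 72 h and 168 h.
* `T50`: time to reach 50% *of the tested seeds*, linearly interpolated
  at the first upward crossing. Lines never reaching 50% are censored at
  168 h and flagged rather than dropped: dormant lines are exactly the
  signal of interest, and the censoring value keeps them in the scan
  with a rank-consistent penalty.
* `AUC`: trapezoidal integral of the percentage curve over [0, 168] h
  (% · h). The trapezoid on the observed 24-h grid replaces any fitted
  germination model: it is deterministic, assumption-free, and converges
  to the underlying smooth curve's integral as the grid refines (a
  property the tests check against the closed-form logistic integral).

Traits are computed per replicate and then averaged
(`aggregate_replicates()`); averaging curves before extraction would give
slightly different T50 values near the censoring boundary, and the
per-replicate order was chosen so replicate SDs remain defined for every
trait.

## Ridge-regression genome scan

All bins enter one linear model jointly, $y = X\beta + \varepsilon$,
with bins coded donor = 1 / recurrent = 0, missing bin calls mean-imputed
per bin (so no line is dropped and no genotype invented), columns
standardized, and an L2 penalty $\lambda \lVert \beta \rVert^2$ on the
coefficients. Adjacent bins are nearly collinear by construction, which
is precisely why a penalized joint fit is used instead of
marker-by-marker regression. $\lambda$ is chosen by 10-fold
cross-validation on a log-spaced grid (25 points, $10^{-2}$–$10^{5}$) and
then held fixed.

Per-bin p-values are pointwise trait permutations: the trait vector is
permuted `n_permutations` times (default 2000), the standardized ridge
coefficients are re-estimated at the fixed $\lambda$ (a single SVD makes
each permutation a matrix product), and
$p_j = (1 + \#\{|\beta^{perm}_j| \ge |\beta_j|\})/(1 + B)$. Lines are
put into a canonical order before permuting so p-values do not depend on
row order, and all draws derive from the scan seed. An analytic
alternative (`p_method = "ridge_t"`), based on the ridge sampling
covariance with effective degrees of freedom, is provided and labelled
approximate. Because $\lambda$ is selected on the observed trait and
then reused for the permutations, the permutation null is conditional on
$\lambda$; the type-I calibration test shows the resulting p-values are
uniform to within Monte-Carlo error at the 0.005 threshold.

**QTL declaration** follows the peak-bin rule: maximal runs of adjacent
bins with $p < 0.005$ collapse to the bin with the smallest p.
Permutation p-values are discrete, and every strongly associated bin in
a run can sit at the attainable floor $1/(B+1)$, which makes "the lowest
p" ambiguous; ties are therefore broken by the larger standardized
coefficient magnitude and only then by the lower genomic coordinate.
Strict adjacency is used — a single non-significant bin splits a run —
and runs never extend across chromosomes.

**Variance decomposition** re-fits the declared peak bins by OLS and
assigns each QTL the LMG share: the average of its $R^2$ increments over
all predictor orderings, computed exactly via subset enumeration up to
15 predictors and by seeded Monte-Carlo over orderings beyond that.
Shares are non-negative and sum exactly to the full-model $R^2$;
perfectly collinear duplicate peaks are merged first.

**Seed-dormancy regions** (`cluster_sd_regions()`): QTLs for different
traits whose contiguous significant spans overlap are grouped, and
groups supported by at least three of the four traits become named
`qSD` regions. The span (not just the single peak bin) is used for the
overlap test: within one bin map, peak bins from different traits
overlap only when identical, which would make "same or overlapping
regions" an empty concept; the significant span is the natural interval
notion of a declared QTL. Touching half-open spans do not overlap.

**F2 validation** uses single-marker statistics: $a = (\bar y_{AA} -
\bar y_{BB})/2$, $d = \bar y_{AB} - (\bar y_{AA} + \bar y_{BB})/2$, a
one-way ANOVA p-value, PVE as the between-class share of the total sum
of squares, and $\mathrm{LOD} = (n/2)\log_{10}(SS_{tot}/SS_{res})$.

**Epistasis** between two loci is the interaction term of a two-way
fixed-effects ANOVA on the (up to) nine two-locus genotype classes.
Type-II sums of squares are used because F2 class frequencies are
inherently unbalanced (1:2:1 per locus); they are computed by nested
model comparison, which degrades gracefully when cells are empty (the
interaction df shrinks) or the residual variance is zero, and agrees
with `car::Anova(type = 2)` wherever the latter is defined.

## The population simulator

Meiosis uses the Haldane model: crossover counts per chromosome are
Poisson with mean (length in cM)/100 and positions are uniform on the cM
scale — no interference, the simplest model adequate for recovery
testing. Physical and genetic coordinates are related by a uniform 270
kb/cM, a rice-typical genome-wide average, configurable in
`genetic_map()`.

* **BIL**: one BC1F1 per line (F1 gamete onto the recurrent parent),
  then 7 rounds of single-seed-descent selfing. Expected donor allele
  frequency 0.25 everywhere; heterozygosity halves per generation.
* **CSSL**: real CSSL pedigrees are bespoke marker-assisted breeding
  programs whose details are rarely published; the simulator instead
  generates a large candidate pool (three backcrosses, then fixation of
  one gamete) and greedily retains lines with at most
  `max_donor_segments` homozygous donor segments that tile the genome,
  reporting the realized coverage. The endpoint — one or a few donor
  segments per line, near-complete genome coverage — matches the real
  populations; pedigree-specific segment-length distributions do not.
* **F2**: two independent F1 gametes per individual.

Planted QTL effects act on *latent germination-curve parameters*, not on
the derived traits: each line's curve is
$G(t) = G_{max}\,\sigma((t - t_{50})/s)$ with $\sigma$ the logistic
function, and an effect shifts $G_{max}$ or $t_{50}$ additively by
`add * dosage + dom * (dosage == 1)` (donor homozygote $= 2a$).
Epistatic terms add $\gamma s_1 s_2$ with $s = \text{dosage} - 1$, a
product coding orthogonal to the additive effects in an F2. Because the
four traits are all functionals of the same latent curve, they inherit
the correlation structure seen in real data (G3d, G7d and AUC positively
correlated, all negatively with T50) without any explicit trait-level
covariance. Each seed germinates with probability $G_{max}$ at a
logistic$(t_{50}, s)$ time, giving binomial sampling noise at dish level;
line-level environmental noise (SD 9 h on $t_{50}$, 0.08 on $G_{max}$)
and a replicate-level shift (SD 3 h) complete the noise model. $G_{max}$
excursions outside [0, 1] are clipped and reported — the analogue of the
ceiling effect in highly germinable real lines.

What the simulator does *not* emulate: genotyping error, segregation
distortion, marker-density heterogeneity, shared field/environment
effects, after-ripening treatment, and interference in meiosis. Passing
recovery tests therefore demonstrate correctness of the pipeline under a
clean generative model, not robustness to every artifact of real data.

All randomness flows from one integer seed through labelled sub-streams
(`substream_seed()`), so identical configurations reproduce bit for bit
and individual stages can be re-run in isolation.

## Bundled study conditions and problem sizes

The packaged fixtures define the default study conditions
(`make_fixtures()`):

* `tiny` — 2 chromosomes × 100 cM, 30 markers each, 40 BILs; used for
  fast structural checks and scan calibration.
* `default` — 5 chromosomes × 120 cM, 120 markers each (600 markers),
  400 BILs; four planted QTLs on separate chromosomes, two on $t_{50}$
  (donor allele delaying germination, hence pleiotropic across G3d, T50
  and AUC) and two on $G_{max}$, with effects (5.5 h, −0.05, 6.0 h,
  −0.05 per allele) calibrated so each locus explains roughly 10–20% of
  the variance of its best trait under the default noise model. QTL
  positions coincide with marker positions, as is conventional in
  mapping simulations, so a locus sits inside a bin rather than on a
  boundary.

The verification suite uses these sizes: 100 random lines against the
brute-force window/block oracle; 1000 pooled null-scan p-values (200
null traits on the tiny fixture at 1000 permutations) for type-I
calibration; 20 seeded replicates of the default fixture (1000
permutations per scan) for end-to-end recovery; 1000 null and 200
alternative simulations at n = 175 for the epistasis interaction test.
The simulator-based exactness claims for ancestry recovery condition on
lines whose homozygous segments are at least twice the window span, and
score concordance at bin midpoints over bins whose true ancestry is
homozygous — heterozygous stretches are unidentifiable by design once
the BIL recoding has run.

## Known limitations

* The window rule cannot see donor segments much shorter than the
  window; bin maps from sparse marker sets underestimate recombination.
* Permutation p-values are bounded below by $1/(B+1)$; runs of floor
  ties are expected for strong QTLs, and peak localization inside a run
  then rests on the coefficient magnitudes.
* Mean imputation of missing bin calls shrinks those lines' contrasts
  toward zero, slightly deflating power at high missingness.
* LMG shares on an OLS refit of peak bins quantify the variance split
  among *declared* loci; they are not unbiased effect estimates of the
  underlying QTLs (winner's curse applies to declaration itself).
* The CSSL generator reproduces the endpoint structure of substitution
  lines, not any particular breeding history.
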