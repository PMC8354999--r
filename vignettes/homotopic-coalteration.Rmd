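---
title: "Mapping homotopic co-alteration from meta-analytic foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping homotopic co-alteration from meta-analytic foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phacr)
```

## The question and the model

Voxel-based morphometry studies report peak coordinates (foci) of
gray-matter alteration per patient group; large coordinate databases such as
BrainMap collect thousands of such experiments. Homotopic regions — mirror
positions across the interhemispheric plane — are the most strongly
functionally coupled region pairs in the healthy brain, and a natural
question is whether pathology also travels preferentially between them:
do the two members of a homotopic pair tend to be altered *in the same
experiment*, beyond what their separate alteration rates predict, and if
so, which member leads?

`phacr` answers this in four stages.

**1. Modeled alteration (MA) maps.** Each focus is the center of an
isotropic 3-D Gaussian expressing spatial uncertainty,

$$p(d) = \frac{1}{\sigma^3\sqrt{(2\pi)^3}}\,e^{-d^2/2\sigma^2},
\qquad \sigma = \frac{\mathrm{FWHM}}{\sqrt{8\ln 2}},$$

with $d$ the voxel-to-focus distance. A voxel's MA value is the maximum
over the experiment's foci of $p(d)\times 8\,\mathrm{mm}^3$ (the voxel
volume on the 2 mm grid), clipped to $[0,1]$. The maximum rule (rather
than a sum or a probabilistic union) makes duplicated foci exactly
idempotent and keeps the value interpretable as "probability that this
voxel is altered under the nearest reported peak". The FWHM defaults to a
fixed 10 mm; a subject-count-dependent width can be plugged in as a
function (`fwhm_model(kind = "subject_based", ...)`), since published
subject-based calibrations live outside this package. Every run records
the model used.

**2. Midline compensation.** A focus a few millimeters from the
interhemispheric plane spills its Gaussian cloud into both hemispheres and
would fabricate homotopic co-alteration. Voxels with midline distance
$d < 12$ mm (the typical extent of the cloud) are therefore re-weighted.
The weight "proportional to $1/d$" can be read two ways, and both are
implemented:

* `inverse` (default): $w(d) = 12/\max(d, 2)$, product clipped at 1 —
  amplifies near-midline values so that near-midline evidence saturates
  rather than leaking asymmetrically; $d$ is clamped at one voxel spacing
  (2 mm) to avoid divergence at the plane itself;
* `attenuate`: $w(d) = d/12$ — suppresses near-midline values to zero at
  the plane.

The kernel choice is recorded in the output. The synthetic fixtures place
all nodes at $|x| \ge 12$ mm precisely so that test outcomes do not depend
on this ambiguous choice.

**3. Thresholding and the alteration matrix.** "Significant at $p=0.05$"
for a single-experiment MA map has no unique operational meaning, so two
methods are provided. `null_quantile` estimates the null distribution of a
voxel's MA value by placing the same number of foci uniformly at random in
the brain mask (1000 draws by default, seeded) and takes the 95th
percentile. `absolute` applies a fixed MA cutoff. The binary maps are then
summarised over a mirror-symmetric parcellation: a node is *altered* in an
experiment when at least 20% of its voxels are suprathreshold (boundary
inclusive). Rows of the resulting matrix are experiments, columns are
nodes.

For the synthetic fixtures the default is the absolute cutoff 0.005:
at FWHM 10 mm this keeps voxels within ~3.2 mm of a focus, which reliably
trips the 20% rule inside a 12-voxel node while never reaching a
neighbouring node across a 4 mm gap. The quantile method remains the
default for real data, where foci counts and node geometry vary.

**4. Per-pair statistics.** For a pair with right member $a$ and left
member $b$, the four joint states over $N$ experiments give counts
$z_1..z_4$ (both altered; $b$ only; $a$ only; neither) and probabilities
$\theta_i = z_i/N$. Patel's kappa is the normalized excess of
$\theta_1$ over the independence expectation
$E = (\theta_1+\theta_2)(\theta_1+\theta_3)$:

$$\kappa = \frac{\theta_1 - E}
{D\,[\max(\theta_1) - E] + (1-D)\,[E - \min(\theta_1)]},$$

where $\max(\theta_1) = \min(\theta_1+\theta_2,\ \theta_1+\theta_3)$ and
$\min(\theta_1) = \max(0,\ 2\theta_1+\theta_2+\theta_3-1)$ are the Fréchet
bounds of the joint probability given the marginals. The weight $D$ is
implemented in the bound-preserving orientation

$$D = \tfrac12 + \frac{\theta_1 - E}{2[\max(\theta_1)-E]} \ \ (\theta_1 \ge E),
\qquad
D = \tfrac12 - \frac{E - \theta_1}{2[E-\min(\theta_1)]} \ \ (\theta_1 < E),$$

which runs from 0 (joint probability at its lower bound) through 0.5
(independence) to 1 (upper bound), so the normalizer interpolates between
the two attainable extremes and $\kappa \in [-1, 1]$ with both ends
attained. The same expression is sometimes printed with the sign of the
second branch's correction term flipped; that orientation pushes the
weight toward the *wrong* normalizing constant for negative deviations and
leaves kappa unbounded below (values near $-200$ appear already on a
0.005-step simplex lattice), contradicting the statistic's advertised
range, so `phacr` uses the bounded form. `patel_bounds()` verifies the
attained range by dense grid search.

Significance is Bayesian: a multinomial likelihood with a flat Dirichlet
prior gives a Dirichlet posterior over $\theta$; 5000 posterior draws are
scored and the edge is significant when more than 95% of draws have
$\kappa > 0.01$. Two posterior parameterizations are available because the
mode-centred form $\gamma_i = \alpha_i + z_i - 1$ (with $\alpha_i = 1$,
i.e. $\gamma_i = z_i$) is improper whenever a cell is empty: the default
`conjugate` mode uses the standard posterior $\gamma_i = z_i + 1$, and the
`paper` mode uses $\gamma_i = \max(z_i, 0.5)$. The mode is recorded in the
output. Measured on independent nodes (marginals 0.3, $N = 200$, 2000
replicates) the conjugate rule's false-positive rate is about 4.5% —
slightly conservative, as the $e = 0.01$ margin intends.

Directionality uses Patel's tau,

$$\tau = 1 - \frac{\theta_1+\theta_3}{\theta_1+\theta_2}
\ \ (\theta_2 \ge \theta_3), \qquad
\tau = \frac{\theta_1+\theta_2}{\theta_1+\theta_3} - 1
\ \ (\theta_2 < \theta_3),$$

computed only on kappa-significant edges (the literal reading of
"thresholded using the threshold obtained before"; no second Monte Carlo).
Algebraically $\mathrm{sign}(\tau) = \mathrm{sign}(P(b) - P(a))$: tau is
positive when the left member is altered more often. Which member that
makes the *source* of a spreading process is an interpretive convention,
not algebra — under the spread reading the member that is more often
altered alone is the likelier origin — so `phacr` exposes the raw signed
tau plus the recorded a = right / b = left convention and leaves
biological direction labels to reporting. Tau is returned whenever its
active branch is defined, i.e. for every pair altered at least once; only
a never-altered pair yields `NA`. The formula keeps $\tau \in [-1, 1]$
with both extremes attained (verified by the same grid search).

## Rendering, networks, comparison

Kappa maps assign $\kappa \times 100$ to every voxel of both member
regions of each significant pair, so they are exactly mirror-symmetric.
Tau maps are rendered antisymmetrically: $+\tau \times 100$ on the right
member, $-\tau \times 100$ on the left, so that directionality proceeds
from positive toward negative areas; this is a documented convention (the
alternative — painting the same signed value on both sides — loses the
direction under the mirror). Unthresholded variants
(`only_significant = FALSE`) recompute tau from the stored joint counts
for every defined pair.

Network decomposition averages the rendered ($\times 100$) statistic over
each network label's voxels, zeros included — the mean level of homotopic
co-alteration a network carries, not the mean over significant voxels
only. Comparing two runs (e.g. morphometric alteration vs functional
activation foci, PHAC vs MHC) is done region-wise: Pearson correlation of
the kappa vectors over shared pairs with defined values, requiring at
least three pairs and nonzero variance.

## Robustness

*Jackknife.* With $S_0$ the ALE union $1 - \prod_i(1-\mathrm{MA}_i)$ of
all experiments and $S_k$ the union without experiment $k$,
$E_k = \sum_i (S_{ik}-S_{i0})^2$, reported $\times 100$. Because the union
is a product form, each leave-one-out map is recovered exactly from the
cached total by dividing out one factor; voxels where some $1-\mathrm{MA}$
is exactly zero are tracked by a zero-factor count so saturation stays
exact. An experiment with no in-mask foci has $E_k = 0$ identically; a
singleton dataset has $E_1 = \sum_i S_{i0}^2$. Both closed cases are
tested to floating-point tolerance.

*Bootstrap.* Experiments are the exchangeable unit, so resampling rows of
the alteration matrix with replacement is algebraically identical to
re-running the whole chain per resample (each MA map depends only on its
own experiment). Summaries are the per-pair selection frequency and the
correlation between bootstrap-mean and full-data kappa. `B` defaults to
200 — full posterior refits per resample put 5000 iterations beyond desk
scale — and the tests check that Monte-Carlo error does not grow with `B`.

## The synthetic generator

`generate_atlas()` plants mirror-image node pairs as 2×2×3-voxel blocks
(12 voxels per side) separated by 2-voxel gaps at $|x| \ge 12$ mm on a
41×48×40 grid at 2 mm, inside a box-shaped all-`TRUE` mask, plus a
network volume partitioning the grid into z-slabs. `generate_dataset()`
draws, per experiment and pair, node states from a `ground_truth`: a
planted pair has a source side altered with probability `p_source`, with
contralateral spread probability `p_spread` given a source alteration and
spontaneous rate `p_spont` otherwise; a null pair has independent members.
Altered nodes receive a shifted-Poisson number of foci (mean 2, minimum 1)
at uniformly chosen voxel centers — voxel-center placement keeps kernel
peaks analytic; sub-voxel jitter is an option. Subject counts are uniform
on [10, 30], typical of VBM group studies. The exact drawn states are
returned as an oracle matrix so recovery can be scored cell by cell; at
the default geometry and cutoff the pipeline recovers the oracle exactly.
`unilateral_null_scenario()` is the worst-case false-positive fixture:
every experiment alters exactly one hemisphere (half left-only, half
right-only), so the joint alteration probability is identically zero and
no edge may reach significance.

What the generator does *not* emulate: cortical geometry and
anatomically realistic node shapes or sizes, disease-specific
topographies, spatially correlated noise between non-homotopic regions,
coordinate-space conversion error, and any generative model of real
database foci (none is published; these are fixtures, not claims about
BrainMap data). Passing tests therefore demonstrate correctness of the
statistical machinery and recoverability of planted structure — not that
real foci data satisfy the model.

## Numerical choices and problem sizes

* Gaussian clouds are truncated at $4\sigma$ (contributions below
  $\sim 3\times10^{-4}$ of the peak are dropped).
* Kappa is clamped to $[-1,1]$ against float overshoot at the attained
  bounds (order $10^{-12}$); degenerate marginals (a node never or always
  altered) return `NA` with a recorded reason rather than dropping the
  pair, keeping column bookkeeping aligned.
* The significance criterion is strict (`> 0.95`), the VOI rule inclusive
  (`>= 20%`).
* The simplex grid search uses step 0.005 (1,373,701 lattice points,
  a few seconds).
* Test fixtures use 30–200 experiments and 4–100 pairs; the Monte Carlo
  calibration check runs 1000 independent pairs at $N = 100$ with 5000
  posterior draws each. These sizes make the full suite run in about a
  minute while keeping every binomial tolerance at 3 SD.

## Known limitations

* Only homotopic (mirror) pairs are scored; heterotopic co-alteration and
  conditional (partial-correlation) structure are out of scope, as is any
  multiple-comparison correction across edges — significance is the
  per-edge Monte Carlo criterion alone.
* Cluster-level ALE inference (cFWE/TFCE) is not implemented; the
  per-experiment threshold is a simpler surrogate with two documented
  readings.
* Midline-plane voxels are excluded from all pairs (exclusion avoids
  double-counting under the flip; how they should be apportioned is
  genuinely open).
* Increases and decreases are kept as separate runs; pooling them into
  one matrix would change the marginals and is deliberately not done.
* The borderline behavior of the significance rule matters when scoring
  many true-null pairs: with a ~4.5% per-pair false-positive rate,
  a batch of 50 null pairs flags 2–3 of them in a typical draw.

```{r, eval = FALSE}
# A complete synthetic run, end to end:
cfg <- sim_config(n_experiments = 100, n_pairs = 20, seed = 7)
world <- generate_atlas(cfg)
truth <- interleaved_truth(20)
ds <- generate_dataset(cfg, truth, world$atlas)
res <- run_phac(ds$foci_list, world$atlas, world$mask,
                phac_config(threshold_method = "absolute", cutoff = 0.005,
                            seed = 7))
head(res$edges)
kappa_map <- render_pair_map(world$atlas, res$edges, "kappa")
network_decomposition(kappa_map, world$networks)
```
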