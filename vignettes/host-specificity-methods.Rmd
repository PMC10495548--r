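---
title: "Models and methods for fig-pollinator host specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for fig-pollinator host specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figwasp)
```

## The scientific problem

Strangler figs (*Ficus*, subgenus *Urostigma*) are pollinated by minute,
short-lived *Pegoscapus* wasps that must locate a receptive tree of the right
species across a diverse forest. Sticky-trap counts at receptive fig trees,
vegetative fig trees and non-*Ficus* control trees, combined with COI
barcoding of a subsample of trapped individuals, allow three questions to be
asked: do wasps arrive preferentially at receptive figs; are wasps trapped at
vegetative trees of their own host species (implying attraction cues beyond
the receptive syconium); and how abundant is each wasp species at each class
of tree?

`figwasp` implements the full analysis chain for such data — count models,
barcode species assignment, and a joint bootstrap for species-level
abundance — together with a synthetic-data generator with known truth so the
chain can be validated end to end without any field download.

## Count model

Pooled per-event counts $y_i$ (four traps per tree, exposed $d_i \in [1,6]$
days) follow a zero-inflated Poisson mixture

$$P(y_i = 0) = p_i + (1-p_i)e^{-\lambda_i}, \qquad
  P(y_i = k) = (1-p_i)\frac{\lambda_i^k e^{-\lambda_i}}{k!},$$

with a log link for the conditional mean and a logit link for the
structural-zero probability:

$$\log \lambda_i = x_i^\top\beta + \log d_i + b_{s(i)} + c_{t(i)}, \qquad
  \mathrm{logit}\, p_i = w_i^\top\gamma + u_{s(i)}.$$

The log-exposure offset is confined to the conditional part, so $\beta$
describes capture *rates* per trap-day. Tree type (non-*Ficus* reference, so
coefficients are directly the receptive/vegetative vs control differences)
is the fixed effect of interest; fig species ($b$, $u$) and trapping date
($c$) are independent Gaussian random intercepts with one variance each —
no covariance structure, since the data provide nothing to identify one.

`fit_zip_glm()` maximizes the fixed-effects likelihood by BFGS from a
deterministic start (Poisson GLM for $\beta$; logit of the observed
excess-zero fraction for the $\gamma$ intercept) followed by Newton polish
with analytic gradient and Hessian, to a gradient norm below $10^{-6}$.
`fit_zip_mixed()` integrates the random effects by the Laplace
approximation: the joint mode is found by damped Newton on the analytic
joint Hessian (assembled by factor-index accumulation, so cost is linear in
observations), and the outer optimization over $(\beta,\gamma,\log\sigma)$
uses BFGS with warm-started inner modes and a Nelder–Mead fallback. On
shared test data the fit agrees with glmmTMB's Laplace ZIP to all reported
digits (log-likelihood, fixed effects, variance components, standard
errors).

Failure is a result, not an exception: fits report a typed status
(`converged`, `boundary`, `boundary_no_zeros`, `non_convergence`) and a
`separated` flag, because with near-empty strata (a control arm with a
handful of captures) the conditional/structural split is genuinely
unidentified and downstream stages must be able to see that.

Inference uses Wald $z$-tests on difference parameters, likelihood-ratio
tests between nested fits, AIC ranking (with a response checksum so models
on different data cannot be compared), and single-step simultaneous
("Tukey-type") pairwise intervals computed from the equicoordinate quantile
of the multivariate normal with the contrasts' correlation matrix. The
multivariate-normal integrals are evaluated with a fixed internal RNG state,
so all reports are byte-reproducible.

## Barcode assignment

Queries are first screened for protein-coding plausibility under the
invertebrate mitochondrial code (translation table with AGA/AGG = Ser,
ATA = Met, TGA = Trp; stops only TAA/TAG), auto-selecting the first
stop-free frame; sequences with internal stops in all three frames are
flagged as putative nuclear pseudogene copies and excluded. Distances are
Tamura–Nei (TN93), computed with pairwise deletion of ambiguous/gap sites
and base frequencies pooled over each pair; a non-positive logarithm
argument is reported as saturation, distinct from any numeric distance. In
its symmetric limit (equal base frequencies, equal transition proportions)
the implementation reproduces the Kimura two-parameter closed form to
$10^{-9}$, and it matches `ape::dist.dna(model = "TN93")` on simulated
fragments.

Assignment is the nearest-reference rule: a query takes the species of its
minimum-TN93 reference when that distance is strictly below 2% (exact ties
broken by lexicographic species label and flagged); otherwise it is recorded
as "new sp." with the closest reference noted. Distances in the 2–3% band
are flagged as borderline. This deterministic rule replaces the visual
tree-clustering workflow of interactive barcoding software; a
neighbor-joining audit tree over references plus (a capped subsample of)
queries is still emitted for inspection. The NJ implementation uses the
standard Q-criterion and two-point branch lengths, clamps negative branches
to zero with the deficit moved to the sister branch, and recovers additive
matrices exactly.

## Joint bootstrap for species-level abundance

Counts identify *how many* wasps arrive per tree class; barcodes identify
*which species* they are; neither alone gives species-level abundance. The
estimator resamples both datasets $B = 200$ times — trapping events with
replacement within each fig-species × tree-type stratum (summarized as
total captures per trap-day), and barcoded individuals with replacement
within the same strata (summarized as relative species frequencies) — and
multiplies matched replicates, summing over the fig species belonging to
each of four categories per wasp: receptive/vegetative × usual/other host.
Wasps with two usual hosts aggregate over both in the "usual" categories.
Per-replicate conservation holds exactly: usual + other equals the wasp's
total in that phase.

Intervals are 95% percentile bounds using the inverse-empirical-CDF
(type-1) quantile, so heavily zero-valued replicate vectors legitimately
yield a lower bound of exactly zero. Categories a wasp was never observed
in within any contributing stratum are marked not estimable rather than
zero. Differences between categories are read as significant when their
intervals are disjoint.

Design choices: the exchangeable resampling units are the trapping event
and the individual wasp (tree-level resampling is available behind
`unit = "tree"` for sensitivity analysis); rates (not raw totals) enter the
multiplication by default, matching the per-24h normalization of the
counts, with `rates = FALSE` as the alternative; the two streams use
independent seeds derived from one master seed and are paired by replicate
index.

## The synthetic generator

`sim_config()` encodes the study conditions. Marginal capture rates per
tree type are calibrated to the field totals — 7580 captures/150 trap-days
(receptive), 580/1198 (vegetative), 4/287 (non-*Ficus*) — split between a
structural-zero probability $(0.25, 0.70, 0.95)$ and a conditional rate
$(67.4, 1.61, 0.28$ per day$)$. The non-*Ficus* deficit is placed mostly in
the structural-zero part: captures at non-fig trees are accidental strays,
and this split reproduces the field analysis' near-total zero record and
wide, weakly identified non-*Ficus* parameters. Notably, the implied
conditional and zero-inflation contrasts (conditional vegetative−control
≈ 1.7, zero-inflation receptive−control ≈ −4.0 on the logit scale) agree
with the midpoints of the fitted intervals reported for the field data.
Random-effect SDs default to 0.5 on the link scale — a stated assumption,
since the field study reports no variance estimates. Because
$E[e^b] = e^{\sigma^2/2}$ per random effect, realized aggregate rates run
about 30–60% above the calibration targets; this is intentional (the
calibration fixes the *conditional median* rate).

Host specificity defaults are the observed fractions of barcoded
individuals on a usual host: $s_\text{receptive} = 284/316 \approx 0.899$
and $s_\text{vegetative} = 138/215 \approx 0.642$; non-usual individuals
are spread uniformly over the other wasp species. Barcode subsamples cap at
20 individuals per tree and phase, as in the field protocol.

COI references descend from a random ancestral coding sequence (503 bp,
reading frame 0), each mutated at half the interspecific divergence
(default 10%) with a 4:1 transition:transversion bias — chosen so TN93 and
p-distance measurably differ — and queries mutate their species reference
at the intraspecific rate (default 0.5%). Mutations that would create an
internal stop are reverted, so every simulated sequence passes the
pseudogene screen by construction.

What the generator does *not* emulate: spatial correlation between trees,
seasonal phenology, wasp dispersal, alignment error or indels in the
barcode fragment, and any fig-species structure in specificity beyond the
two phase-level probabilities. Passing tests therefore validate the
statistical machinery under the stated design, not these field
complications.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle: brute-force
mixture evaluation for the ZIP likelihood (100 random datasets, $10^{-10}$);
glmmTMB for both ZIP fitters; `stats::glm` for the binomial IRLS;
seqinr's translation table 5 for the genetic code; `ape` for TN93 and for
additive-matrix NJ recovery; the studentized-range constant for the
three-group simultaneous critical value; and generator truth for
assignment (exact agreement at 0.5%/10% divergence) and for parameter
recovery (fixed effects within 3 SE at $n = 5000$ in ≥95/100 runs;
$\hat\sigma_\text{species} \in [0.3, 0.7]$ for truth 0.5 in ≥80% of 50 runs
of 20 species × 50 events). LRT size is calibrated on 1000 null binomial
simulations at $n = 200$.

Two end-to-end properties are checked at the study's own scale. First,
coverage: 500 independent synthetic campaigns (500 events each, 5 fig
species × 2 trees × 25 events per phase, barcode subsample 20 per
tree-phase) are each bootstrapped with $B = 200$; the 95% percentile
intervals cover the true category abundances (realized conditional
expectations given the drawn random effects) in about 92.5–93% of
wasp × category cells. The shortfall below nominal concentrates in
small-expected-count cells (receptive trees × other-host species, where a
stratum contributes roughly one barcoded individual of a given non-usual
species) and is the familiar percentile-bootstrap undercoverage for skewed
statistics at modest $n$; we report it rather than widen the intervals.
Second, qualitative pattern recovery: in ≥90% of 50 field-scale campaigns
(13 species, ~760 events), the stage-1 report shows receptive trees
significantly above vegetative and control trees with vegetative and
control adjacent on the pseudolog scale of fitted marginal rates, and the
stage-3 binomial LRT detects higher specificity at receptive trees. The
"vegetative ≈ non-Ficus" element is deliberately checked on fitted marginal
rates (the display scale of the capture-rate figure) rather than on the
conditional coefficient alone, because with ~4 control captures the
conditional/structural split is unidentified — the corresponding field
estimates show the same degeneracy (intervals spanning thousands) — while
the marginal rate remains well determined.

## Numerical choices and limitations

* ZIP likelihood and derivatives are evaluated in log space
  (`log1p`/`expm1`-style guards), so $\lambda \to \infty$ and $p \to 0, 1$
  are safe.
* The ZIP log-likelihood is not globally concave in $(\eta, \zeta)$;
  both Newton loops use Levenberg damping and step halving with a
  monotonicity guard.
* Zero-count boundary: data with no zeros return a typed boundary fit with
  $\gamma_0 = -\infty$ and Poisson-GLM conditional coefficients.
* Variance estimates below $10^{-3}$ are reported as boundary fits.
* The outer Laplace objective returns a finite value even where the inner
  solver has not fully converged, so finite-difference outer gradients
  never hit a cliff; such regions score poorly and are abandoned by the
  optimizer.
* Percentile intervals use type-1 quantiles with an epsilon guard against
  floating-point round-up at integer $np$.
* mvtnorm's integration is randomized; the contrast machinery fixes and
  restores the RNG state, making every report deterministic given its
  inputs and seed.
* Laplace (not adaptive quadrature) is the integration rule throughout;
  for the small counts of the control arm this can bias variance
  components slightly, as for any Laplace ZIP fitter.
* The assignment rule is strictly distance-based; the field workflow's
  occasional clade-level judgment calls are out of scope, and 2–3%
  borderline cases are only flagged.
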