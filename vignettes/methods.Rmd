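---
title: "Bayesian comparison of simulated chemical-shift ensembles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian comparison of simulated chemical-shift ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftstate)
```

## The inference problem

An MD trajectory of a candidate conformational state, passed through a
chemical-shift predictor, yields for every backbone nucleus (N, C, CA, CB)
an ensemble of predicted shifts — often hundreds to thousands of values per
nucleus once the four equivalent subunits of a homotetramer are pooled.
These ensembles are conspicuously non-Gaussian: side-chain rotamer hops and
backbone substates skew them. `shiftstate` therefore models each
(nucleus, state, method) sample with a skew-normal likelihood

$$L(d \mid \mu, \sigma, \alpha) = \frac{2}{\sigma}\,
  \phi\!\Big(\frac{d-\mu}{\sigma}\Big)\,
  \Phi\!\Big(\alpha\,\frac{d-\mu}{\sigma}\Big),$$

with location $\mu$ (ppm), scale $\sigma > 0$ (ppm) and dimensionless shape
$\alpha$; $\phi$ and $\Phi$ are the standard normal density and cumulative
distribution function. Every model is fitted independently — no pooling
across residues, nuclei or methods — and the predictor's own per-snapshot
error is deliberately *not* modelled: the two prediction methods are
analysed in parallel instead, and their agreement is the robustness check.

The reported quantity is not $\mu$ but the distribution mean
$\mathrm{mean} = \mu + \sigma\sqrt{2/\pi}\,\alpha/\sqrt{1+\alpha^2}$ — the
population-weighted peak position a rapidly averaging NMR experiment would
see — together with the distribution variance
$\sigma^2\big(1 - \tfrac{2}{\pi}\tfrac{\alpha^2}{1+\alpha^2}\big)$. Both
are computed per posterior draw, so they carry full posterior uncertainty.

### Priors

Weakly informative and anchored on the sample: $\mu \sim
\mathcal N(\bar d, 10~\mathrm{ppm})$, $\sigma \sim
\mathrm{halfCauchy}(\beta = 10~\mathrm{ppm})$, $\alpha \sim
\mathcal N(0, 10)$. The $\alpha$ prior scale is taken as dimensionless —
skewness has no unit. Centering the $\mu$ prior on the sample mean makes
the whole model translation-equivariant, which underpins the offset-immunity
property below.

## Posterior computation

The posterior is sampled with a compiled adaptive random-walk Metropolis
sampler on $(\mu, \log\sigma, \alpha)$, four chains by default. Warmup has
two phases: per-coordinate Metropolis-within-Gibbs with Robbins–Monro step
adaptation (to reach the typical set), then joint proposals whose
covariance is the running empirical covariance of the second phase (scaled
$2.38^2/3$), with a global scale tuned toward ~0.3 acceptance. Adaptation
freezes at the end of warmup, so kept draws form a valid Markov chain.
Chains start mildly over-dispersed around a method-of-moments estimate
(sample skewness mapped to $\alpha$, then $\sigma$, $\mu$ from the sample
variance and mean); the moment map is translation-equivariant, and so is
the entire sampler trajectory — shifting all data by a constant shifts the
$\mu$ draws by exactly that constant and reproduces $\sigma$ and $\alpha$
draws bit for bit.

A three-parameter posterior does not need gradient-based sampling;
empirical calibration (below) confirms the interval coverage this choice
delivers. Split-chain R-hat and effective sample size (via `coda`) are
attached to every fit; fits warn above R-hat 1.01 or below ESS 400. The
symmetric regime $\alpha \approx 0$ is the slowest-mixing (the information
matrix is singular there); the default 4 × 1000 draws after 1000 warmup
handle it, while 4 × 500 after 500 suffice for clearly skewed ensembles.
Degenerate inputs are refused: fewer than 10 points, or constant data
(which would drive $\sigma \to 0$).

A deterministic alternative (`method = "mle"`: maximum likelihood started
from the moment estimate, draws from the asymptotic normal approximation)
exists for interactive work and for exercising pipeline mechanics quickly;
it is labelled non-canonical and the likelihood optimizer deliberately does
not start from $\alpha = 0$, a stationary point that traps gradient
methods.

### Credible intervals

All summaries use the 94% highest-density interval, reported as its
midpoint plus or minus the distance to the bounds; the HDI is computed as
the shortest window containing 94% of sorted draws. An equal-tailed
variant is available (`method = "eti"`). For skewed posteriors the HDI is
shorter; for symmetric ones the two coincide.

### Posterior predictive checks

`posterior_predictive_check()` simulates replicate datasets of the observed
size from posterior draws, histograms them on the observed bins, and scores
the fraction of occupied bins inside the 94% replicate band. Replicate
(not analytic) densities are essential: with thousands of points the
parameter uncertainty alone is far narrower than histogram sampling noise.
Mild bimodality is typically still covered by the skew-normal envelope —
the check reports, it does not reject.

## Discrimination, assignment, classification

A nucleus (per method) has **discrimination power** between the two open
states when both interval *centers* clear their thresholds: the difference
in means beyond the experimental tolerance (0.2 ppm for C, CA, CB; 0.5 ppm
for N) and the effect size beyond 0.5. The pooled standard deviation is
$\sqrt{(\mathrm{var}_{FO} + \mathrm{var}_{PO})/2}$ — the *sum* of
variances, as a pooled dispersion must be (a difference under the radical
could be negative). Draws from the two independent posteriors are paired
by index; independence makes the pairing harmless and reproducible.

State assignment works entirely in difference shifts:
$\Delta CS_{sim}^X = CS_{sim}^X - CS_{sim}^{C}$ against the closed
reference, $\Delta CS_{exp}$ = activated − deactivated, and
$\Delta\Delta CS^X = \Delta CS_{sim}^X - \Delta CS_{exp}$, summarized as
the HDI of $|\Delta\Delta CS^X|$ per draw. Any systematic offset common to
all simulated shifts of a method — referencing, lipid environment, tertiary
contacts the predictor misses — cancels in $\Delta CS_{sim}$, so verdicts
are immune to it; this is asserted to 1e-9 ppm in the tests. The verdict
is the state with the smaller $|\Delta\Delta CS|$ center; if both centers
sit below the tolerance, or tie exactly, the nucleus is undetermined.
Experimental shifts are treated as point values with a tolerance band, not
as distributions.

Boundary conventions are uniformly strict and conservative: a difference
exactly at tolerance is a spectator / not distinguishable; verdict ties are
undetermined. Tallies are reported at nucleus level (each
nucleus-method verdict counts once) and at residue level, where per-method
verdicts are first combined (agreement keeps the state, disagreement is
undetermined) and each residue then takes the majority over its nuclei.
Per-method counting at nucleus level is the default because the two
predictors are deliberately kept separate throughout.

The marker classifier maps the three pairwise distinguishability booleans
(PO–C and FO–C from difference-shift centers versus tolerance, FO–PO from
the difference-in-means center) plus the experimental marker flag to
classes A–E × subtype 1/2. Three boolean patterns match no flowchart
branch (exactly one pair distinguishable); they are geometrically
near-impossible but reachable with noisy centers, so they map to the
nearest regular pattern by Hamming distance (precedence E, B, C, D, A on
ties) and carry an `irregular` flag rather than being dropped. Class D
(open states indistinguishable, both distinct from closed) cannot survive
the discrimination filter by construction.

## The synthetic generator

`synthetic_scenario()` emulates exactly the data-generating assumptions the
analysis makes: per-nucleus skew-normal (optionally two-component mixture)
ensembles per state and method, four exchangeable subunits, and
experimental tables produced from the population mean of a designated true
state plus Gaussian noise (default sd 0.05 ppm — well under the
tolerances, so planted classes survive generation). Planted marker classes
are verified *analytically* at construction from population means,
variances and the thresholds, so an impossible panel fails fast rather than
producing a misleading test. Presets cover the spectator panel, the
FO-only-distinct panel (B1), the all-distinct panel with PO or FO truth
(E2), a bimodal stress panel, and a boundary panel with gaps exactly at
tolerance.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: frame-to-frame autocorrelation (the
pipeline subsamples frames as exchangeable, as the random 2000-point
subsampling assumes), predictor-specific systematic error surfaces (method
offsets are representable but default to zero), realistic protein-specific
shift values beyond plausible per-nucleus ranges, and subunit asymmetry
(an exchangeability deviation can be built by giving one chain different
parameters, but the presets do not).

Default problem sizes keep the suite desk-scale: presets use 250 frames ×
4 subunits (1000 points per nucleus), pipeline tests subsample to a few
hundred points, and the calibration study uses 200 replicates of n = 2000
with 4 × (500 + 500) draws — the empirical 94% HDI coverage of the
distribution mean lands within ±4 percentage points of nominal.

## Structural utilities

The inner-gate metric finds the two *opposing* subunit pairs of a tetramer
by maximizing summed pair distances over the three possible pairings —
robust to arbitrary chain naming — and reports both diagonal Cα–Cα
distances plus their mean, since asymmetric gates make them differ.
Frame-window curation consumes precomputed event series (water-entry
frames, gate-distance time series) rather than raw trajectories: detection
at trajectory scale is out of scope for a tabular pipeline. The stability
heuristic truncates initial frames until the rolling mean of the gate
distance drifts no more than a bound (default 0.5 Å over a 10-frame
window) and refuses windows shorter than twice the rolling window, which a
lone tail value would otherwise satisfy vacuously.

## Interfaces and reproducibility

The exported functions are the interface: `run_pipeline()` orchestrates
ingest → pooling → subsampling → fitting → discrimination → assignment →
classification → tallies, writes per-stage TSV artifacts and a JSON report
when `out_dir` is given, and is fully deterministic for a fixed seed —
re-running an unchanged configuration reproduces every verdict table
exactly, which replaces a posterior disk cache at these problem sizes.
Per-nucleus exclusions (missing assignment, missing state, failed filter)
are logged as messages so the bookkeeping from eligible nuclei down to
verdicts is auditable.

## Known limitations

* The sampler is random-walk based; for strongly multimodal posteriors
  (not observed for these likelihoods) it would mix poorly.
* Mixed populations at a nucleus are not modelled: one dominant state is
  assigned, never a fraction.
* Experimental uncertainty enters only through the tolerance thresholds.
* Glycine CB rows and non-backbone nuclei are dropped at ingest; the
  four-nucleus restriction is deliberate.
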