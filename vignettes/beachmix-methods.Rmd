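---
title: "Diet mixing and trophic position on sandy-beach gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet mixing and trophic position on sandy-beach gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beachmix` analyses the diet and trophic position of a generalist sandy-beach
predator (the ghost crab *Ocypode quadrata* is the motivating consumer) from
carbon and nitrogen stable isotopes, across a set of beaches spanning the
reflective-to-dissipative morphology gradient. This vignette explains the
statistical machinery, the choices that were genuinely open, and what the
package's own validation experiments do and do not demonstrate.

## The mixing model

A consumer's tissue signature is modelled as a proportion-weighted mixture of
three TEF-corrected prey sources (mole crab, wrack-dwelling amphipod, coquina
clam). For isotope $j \in \{\mathrm{C}, \mathrm{N}\}$ and diet proportions
$p = (p_1, p_2, p_3)$ on the simplex,

$$
x_j \sim \mathcal{N}\!\Big(\textstyle\sum_k p_k (s_{jk} + c_{jk}),\;
\textstyle\sum_k p_k^2 (\sigma_{jk}^2 + \tau_{jk}^2) + \sigma_{\mathrm{res},j}^2\Big),
$$

where $s_{jk}, \sigma_{jk}$ are the source mean and SD, $c_{jk}, \tau_{jk}$
the trophic enrichment mean and SD ($c_{\mathrm{C}k} = \tau_{\mathrm{C}k} = 0$:
no carbon enrichment is applied), and $\sigma_{\mathrm{res},j}$ a per-isotope
residual SD. The prior is Dirichlet($\alpha$) on $p$ (all-ones by default) and
uniform$(0, u)$ on each residual SD. This is the single-observation ("solo")
variant: each individual crab is fit on its own, so within-site variation
surfaces as between-individual posterior differences rather than a pooled
error term.

**Residual-SD prior bound.** With one observation per fit the residual SD is
not identified by the likelihood: whatever mass the prior places on large
residual variances survives into the posterior, flattening the likelihood and
dragging every diet posterior toward the prior mean $(1/3, 1/3, 1/3)$. The
bound must therefore be vague only on the *physical* scale of isotope
residuals. Measurement repeatability for these data is about $\pm 0.1$ permil
and trophic-study residuals rarely reach 1 permil, so the default is
$u = 2$ permil — an order of magnitude above repeatability, while keeping the
posterior informative. `resid_upper` is a parameter of
`mixing_model_spec()` for users who want a different bound.

**Sampler.** `sample_posterior()` runs component-wise random-walk Metropolis
on the additive-log-ratio transform of $p$ (so the simplex constraint holds
exactly on every draw) and on the log residual SDs, with the appropriate
Jacobians. Proposal scales adapt during burn-in toward roughly 35%
acceptance and are frozen afterwards, preserving detailed balance for the
retained draws. Initialisation is the uniform diet and residual SD 1 permil.
Degenerate inputs are kept proper by flooring any source/TEF SD of exactly 0
at 0.01 permil inside the likelihood. The default schedule is 100,000
iterations, 10,000 burn-in, thinning by 15 — exactly 6,000 retained draws;
`floor((iterations - burn_in)/thin)` in general.

The sampler is cross-checked two ways in the test suite: the compiled
log-density is compared term-by-term against a plain-R density computation,
and for a reduced model (two sources, one isotope, fixed residual SD) the
posterior mean is compared against dense trapezoid grid integration.

## TEF estimation and amphipod imputation

The nitrogen TEF is estimated *per site* as the mean of the differences
between the site-mean consumer signature and the three source means; its SD
is the sample SD (n = 3) of those differences. Sources are weighted equally
because diet shares are unknown at TEF-estimation time. The procedure is
translation-equivariant and is applied site-wide in the mixing model.

Beaches with little or desiccated wrack often yield no amphipod tissue. For
those sites the amphipod source is imputed from the site's mixed wrack
signature: carbon passes through unchanged (no trophic fractionation
assumed), and nitrogen is predicted from a linear calibration of amphipod
d15N on wrack d15N fitted across replicate pairs at sites where both
materials were measured. Imputed summaries are flagged, carry `n = 0`, and —
because no spread was measured — take the mean of the measured per-site
amphipod SDs elsewhere in the data (0.5 permil if none exist).

## Trophic position

The site trophic position is

$$
\mathrm{TP} = \frac{\delta^{15}\mathrm{N}_{\mathrm{GC}} -
\delta^{15}\mathrm{N}_{\mathrm{RES}}}{\Delta} + 2,
\qquad
\delta^{15}\mathrm{N}_{\mathrm{RES}} = \sum_k p_k\, \delta^{15}\mathrm{N}_k,
$$

with $\Delta = 2.3$ permil per trophic level (a literature constant, kept
configurable) and 2 the level of the primary-consumer baseline. The consumer
value is the site mean over individual crabs and the proportions are the
site-mean posterior diets. Note a curiosity of the published worked example
for the baseline: the printed inputs (proportions 0.325/0.325/0.350, source
d15N 5.3/3.8/5.9) give exactly 5.0225, while the printed result is 5.04; the
package computes the exact sum and documents the 0.0175-permil rounding gap.

## The gradient regression battery

`gradient_analysis()` relates per-site diet, density and TP to the physical
parameters (width, slope, grain size, wrack biomass):

* diet proportions are arcsine-square-root transformed, then each is modelled
  by forward stepwise selection with backward removal using partial-F
  thresholds (F-to-enter 4.0, F-to-remove 3.9 — the conventional defaults of
  the originating stepwise tradition; a p-value mode is also available since
  published descriptions often leave the rule unstated);
* burrow density is log10-transformed (exact zeros offset by +0.01 with a
  recorded flag, never silently) and modelled by stepwise selection plus a
  three-parameter Gaussian $y = a \exp(-\tfrac12((x - x_0)/b)^2)$ against each
  physical parameter — peaked density at intermediate widths is the expected
  pattern;
* TP is modelled by stepwise selection against the physical parameters and by
  linear fits against each diet proportion, with a two-parameter saturating
  hyperbola $y = a(1 - e^{-bx})$ as the nonlinear alternative for the
  mole-crab share;
* any fit can exclude flagged sites (`exclude =`), mirroring the practice of
  dropping a single anomalous beach from one regression.

Nonlinear fits use Levenberg-Marquardt from five deterministic starts
spanning the data range, keep the lowest-SSE solution, and are guaranteed
never to return uphill from any initialisation (a Nelder-Mead polish covers
the rare case where no start converges but a start itself is better). For
nonlinear models $R^2 = 1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$ is reported
as-is (it can be negative for bad fits, and is then flagged), with
$F = MS_{\mathrm{model}}/MS_{\mathrm{res}}$ on (2, n-3) df for the Gaussian
and (1, n-2) for the hyperbola. Standardised coefficients are
$b \cdot \mathrm{SD}(x)/\mathrm{SD}(y)$.

## The synthetic-data generator

`simulate_scenario()` forward-simulates the study design so every downstream
stage can be checked against known truth:

* **Sites.** 16 beaches by default, widths evenly spaced over 15.7–106.6 m
  then jittered; foreshore slope (17.2 down to 2.4 degrees) and median grain
  size (1.5 down to 0.1875 mm, log-linear) co-vary negatively with width.
  Their scatter (SD 3.5 degrees, 0.5 log-units; width correlations near
  -0.75) is deliberately moderate: in the emulated system slope and sediment
  carry little information about diet once width is known, and near-collinear
  proxies would additionally violate the stepwise module's non-collinearity
  precondition.
* **Availability.** Mole-crab availability declines linearly from 1 at the
  narrowest beach to 0 at the widest; coquina is the mirror image; amphipods
  follow a Gaussian peak at 40 m (the intermediate 30–50 m band where damp
  wrack accumulates) with 12 m spread. Only the qualitative shapes of these
  curves are anchored; all magnitudes are package defaults recorded in the
  configuration. True diets are the normalised availabilities (diet tracks
  availability; no selectivity weights), with a uniform fallback where all
  curves are zero.
* **Isotopes.** Source baselines default to mole crab (-17.5, 5.3), amphipod
  (-13.0, 3.8), coquina (-19.5, 5.9) permil — prey nitrogen values follow the
  published worked example; carbon reflects seagrass-wrack versus swash
  feeding. Within-site replicate SD is 0.5 permil, between-site drift 0.5
  permil, the true nitrogen TEF is 2.3 +/- 0.5 permil and consumer residual
  SD 0.3 permil per isotope. Replicates number 2–9 per site and taxon;
  consumers 3–7 crabs per site, drawn from the mixing model's own forward
  equations so zero-noise configurations reproduce the closed-form means
  exactly. Sites with under 20 g of wrack lose their amphipod tissue
  (configurable), exercising the imputation branch the way dry beaches did
  in the field.

What the generator does **not** emulate: tides, storms and seasonal
turnover, bird competition, carrion pulses, C:N-dependent fractionation, and
spatial autocorrelation between neighbouring beaches. Passing recovery tests
on these simulations therefore demonstrates the *estimators* are correct and
well-calibrated under the stated generative model, not that field data meet
those assumptions.

## Validation scenarios

Two named configurations encode the package's validation experiments; both
are deliberate design choices, not tuned quantities.

* `recovery_scenario_config()` — 20 sites whose source centroids are pairwise
  at least 3 permil apart in (d13C, d15N) space *and* form a well-conditioned
  triangle: mole (-17, 9), amphipod (-11, 3.8), coquina (-23, 3.8). The
  conditioning matters as much as the distance — if one source lies near the
  segment between the other two, three proportions cannot be identified from
  two isotopes no matter how far apart the centroids are. The acceptance
  experiment feeds the mixing model the generating enrichment and the
  measured source summaries, and requires site-level mean absolute error of
  at most 0.08 at a 20,000-iteration schedule.
* `tp_scenario_config()` — all prey share one d15N baseline (5 permil), the
  true TEF equals $\Delta = 2.3$, diet identification is carried by d13C
  separation, and noise is small (residual 0.1 permil, TEF SD 0.1, 5–9
  replicates, 5–7 crabs, site drift 0.1 permil — per-taxon drift would break
  the common-baseline premise the scenario exists to encode). Under these
  conditions the full chain must return TP = 3.0 +/- 0.15 at every site.
  Because the baseline is common, the weighted resource d15N is insensitive
  to diet-estimation error; this isolates the TEF-estimation, baseline and
  TP arithmetic, while diet recovery itself is validated by the recovery
  scenario.

The direction-recovery experiment simulates the working model's truth at 2x
signal-to-noise (noise SD equal to half the SD of the transformed signal
across sites) and requires the stepwise procedure to select width with a
negative sign for the mole-crab share and a positive sign for coquina in at
least 90 of 100 seeded replicates.

## Numerical details and edge cases

* SD floor 0.01 permil for degenerate source/TEF SDs; proposals adapt in
  batches of 50 during burn-in only; the ALR transform makes simplex
  violations impossible rather than merely penalised.
* Partial-F statistics define both entry and removal; a constant response
  yields F = 0 (empty model), a perfect fit yields F = Inf; aliased
  candidates are dropped with a warning; a visited-model guard ensures
  termination; selection is invariant to candidate order when partial Fs are
  distinct.
* `log10_density(0)` applies a +0.01 offset and records where it did;
  `arcsine_sqrt` rejects values outside [0, 1].
* CSV writers print doubles with 17 significant digits so read/write
  round-trips are exact, and stamp every file with package version, seed and
  a configuration hash.

## Problem sizes

The test suite and validation experiments run chains of 20,000–100,000
iterations on scenarios of 8–20 sites with 3–7 consumers per site; these
sizes give Monte-Carlo error comfortably below every asserted tolerance
(posterior-mean MC error is about 0.005 on a proportion at the scaled
schedule) and keep a full run of the suite in the low minutes on one core.

## Known limitations

* The solo model treats each crab independently; there is no hierarchical
  pooling across individuals or sites, no covariate-dependent mixing, and no
  model comparison machinery.
* Elemental concentration weighting (C:N) is not implemented; sources are
  mixed on delta values alone.
* The per-site TEF estimator equals the true enrichment only when the diet
  is balanced or the prey share a nitrogen baseline; with unequal prey d15N
  and a strongly skewed diet it absorbs part of the baseline contrast. This
  is a property of the estimation procedure itself, faithfully reproduced.
* Measurement-standard drift (the +/-0.1 permil repeatability of the QC
  standard) is not propagated as a separate error term.
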