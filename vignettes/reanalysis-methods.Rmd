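---
title: "Probabilistic reanalysis of KRT-timing trials: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic reanalysis of KRT-timing trials: models, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical machinery of **bayeskrt**: what the
models are, why the priors and thresholds take the values they do, what the
synthetic-data generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## The setting

Large randomized trials of accelerated versus standard initiation of
kidney-replacement therapy (KRT) in critically ill patients with acute kidney
injury typically report a neutral frequentist result for 90-day all-cause
mortality. A Bayesian reanalysis asks sharper questions: *given the data and
an explicit prior, what is the probability that the intervention helps at
all, that the effect is practically null, or that it reaches a clinically
important size?* The package implements that reanalysis as a reusable,
tested pipeline operating on patient-level two-arm trial tables with a site
identifier, three binary adjusters (sepsis, surgical admission, chronic
kidney disease), binary 90-day mortality, bounded "days alive and free"
endpoints, and survivor-only binary endpoints.

Because the patient-level data of the motivating trial are not publicly
deposited, the package ships a seeded synthetic generator
(`generate_trial()`) that reproduces the *structure* the models assume, and a
margins-based reconstruction (`reconstructed_margins_trial()`) that rebuilds
the primary endpoint's analysis from published death counts.

## Priors on the treatment log odds ratio

All treatment-effect priors are normal on the log(OR) scale
(`normal_prior()`). The three theoretical priors, returned by
`build_theoretical_priors()`, are:

* **neutral** — `N(0, 0.355)`: centred on no effect, with 95% of its mass
  between OR 0.5 and 2.0;
* **optimistic** — `N(-0.257, 0.249)`: centred on the design effect of a
  6-point absolute mortality reduction from a 40% baseline
  (`or_from_risks(0.40, 0.34)` = 0.77), with the sd chosen by
  `sd_from_tail()` so the prior still concedes a 0.15 probability of harm;
* **pessimistic** — `N(+0.257, 0.249)`: the mirror image.

Two printed-versus-derived discrepancies are retained deliberately rather
than resolved. First, `sd_from_interval(0.5, 2, 0.95)` gives 0.3537 while the
published neutral sd is 0.355; `build_theoretical_priors()` uses the
published constant verbatim so that downstream numbers match the published
report, and the exact elicitation utilities sit alongside for general use.
Second, the published minimal clinically important difference (MCID) log-OR
magnitude is 0.175 while the exact value `-log(or_from_risks(0.40, 0.36))`
is 0.1699; the exact OR (0.84375) is used for the MCID probability threshold
and the printed 0.175 for the large-effect margin, because the published
large-effect bounds (OR 0.77 and 1.30) follow from the printed value.

Data-derived priors for earlier trials are built from 2x2 mortality tables
with `prior_from_2x2()`: mean equal to the source trial's log OR and sd equal
to the Woolf standard error `sqrt(1/a + 1/b + 1/c + 1/d)`. The source tables
are user-supplied configuration, not package constants, because the exact
normal parameters used for the published data-derived priors are not printed
in the main text.

## Decision thresholds

`build_thresholds()` assembles:

* the **ROPE** (region of practical equivalence): a Cohen's *d* of 0.1
  converted to the log-OR scale by the logistic factor `pi/sqrt(3)`, giving a
  half-width of 0.18 and OR bounds 0.83–1.19;
* the **MCID**: a 4-point absolute mortality reduction over a 40% baseline
  (OR 0.84375), and a 3-day margin for the day endpoints;
* the **large effect** margin: 1.5 times the MCID log-OR, OR bounds
  0.77–1.30.

Unrounded values are stored; 2-decimal rounding is applied only at report
rendering. ROPE bounds are applied strictly; for continuous posteriors the
boundary has probability zero, so the choice is immaterial but fixed.

## The hierarchical logistic model

For binary endpoints the model is

$$\mathrm{logit}\,P(y_i = 1) = \beta_0 + \theta\,\mathrm{arm}_i +
\textstyle\sum_k \beta_k x_{ik} + u_{s(i)}, \qquad
u_s \sim N(0, \tau^2),$$

with the treatment prior as above, `N(0, 1)` regularizing priors on the
adjusters (0/1 coded, not centred), a Student-t(3, 0, 2.5) prior on the
intercept, and a half-t(3, 0, 2.5) prior on the site SD — the conventional
weakly-informative defaults for logit-scale parameters. Secondary binary
endpoints (the death/KRT composite on all patients; KRT dependence and
rehospitalization among survivors) reuse the same model with the neutral
prior only.

Fitting uses Gibbs/block sampling (JAGS with its GLM samplers). Two exact
reparameterizations keep every update conjugate and were measured to improve
mixing by an order of magnitude: the half-t site SD is expressed as the
Huang–Wand inverse-gamma mixture
(`tau^2 | a ~ IG(3/2, 3/a)`, `a ~ IG(1/2, 1/2.5^2)`), and the Student-t
intercept as a normal with a Gamma(3/2, 3/2) mixing precision. Site effects
use the centred parameterization: for a Gibbs engine the centred, conjugate
form mixes better than the non-centred form that gradient-based samplers
prefer. With one site the random intercept is dropped (not identifiable
beside the intercept); this also serves the collapsed-margins oracle checks.

`prior_predictive_check()` refits with the treatment column held constant,
so the likelihood carries no information about `theta` and the posterior
must return the prior — a sampler validation run as a test.

## The zero-one-inflated beta (ZOIB) model

Day endpoints live on `[0, 90]` with genuine mass at both boundaries (deaths
at 0; uneventful survivors at 90). After scaling by 90, the ZOIB law draws a
boundary value with probability `zoi` (equal to 1 with conditional
probability `coi`), otherwise a `Beta(mu*phi, (1-mu)*phi)` interior value.
Boundary classification is by exact equality after scaling — no epsilon
squeezing, since the boundaries are modelled, not evaded.

The fitted structure (`zoib_model_spec()`) puts treatment on all three
components (logit links; log link for the constant precision), and the
adjusters plus the site random intercept on the beta mean only. The original
analysis's component structure is not fully specified in public material;
this is the most parsimonious structure that lets treatment shift both the
boundary mass and the interior mean, and it is declared, not inferred.

The three components factor exactly in the likelihood, so the sampler
(`fit_zoib()`) treats them as independent blocks within one chain:

* the two Bernoulli components reduce to arm-wise counts and are updated by
  2-parameter adaptive-covariance Metropolis blocks;
* the interior beta regression updates its fixed effects as one adaptive
  block, all site effects in a vectorized per-site Metropolis sweep, the
  precision by a log-scale random walk, and the site SD twice per iteration:
  a centred slice-sampling update given the effects, then an interweaved
  non-centred Metropolis update through the likelihood
  (ancillarity–sufficiency interweaving), which keeps the SD's
  autocorrelation low whether the data identify it weakly or strongly.

Proposal scales adapt by Robbins–Monro only during warmup (targets 0.234 for
blocks, 0.44 for scalars) and are frozen afterwards, so the retained chain
is a valid fixed-kernel Markov chain. The sampler is cross-checked in the
test suite against an independent JAGS fit of the identical model on a small
fixture: all posterior means agree within a few hundredths of a posterior sd.
Random-walk updates decorrelate over a handful of iterations but iterate
cheaply, so the pipeline thins ZOIB chains (keep every 6th iteration) to
reach the effective-sample-size gate at modest wall time.

Day differences (`day_difference()`) are computed per posterior draw as the
difference in expected days under arm = 1 versus arm = 0, averaging the beta
mean over the observed adjuster rows (g-computation) with site effects set
to zero — mirroring "estimated marginal means" behaviour of excluding
group-level terms. Whether the published day differences were
covariate-marginalized or computed at reference covariates is not stated;
marginalization was chosen and is used consistently.

## Posterior metrics

`summarize_effect()` reports, per endpoint-prior combination: the posterior
median of `exp(theta)` (the conditional OR) with its 95% highest density
interval; `P(OR < 1)`; the probability of direction (mass on the side of the
posterior median; 0.5 returned in the measure-zero case of an exactly null
median); %ROPE (the fraction of the *whole* posterior inside the ROPE);
`P(effect not large)`; `P(OR < MCID)`; and the covariate-marginalized
absolute risk difference (median, 95% HDI, and `P(diff < -0.04)`), obtained
by g-computation over the observed adjusters with site effects excluded.
"Significance by practical equivalence" is deliberately reported two ways —
%ROPE (the published quantity) and an HDI+ROPE decision label — because the
phrase is ambiguous; the report labels which is which.

The HDI is the shortest contiguous window over the sorted draws containing
`ceiling(mass*N)` draws, ties broken by the earliest start; it is checked
against an exhaustive shortest-window search in the tests. HDIs are computed
on the reported scale (OR, percentage points, days), since the HDI is not
transformation-invariant.

Convergence diagnostics (`compute_diagnostics()`) are rank-normalized
split-R-hat and bulk ESS — the modern default variants, since the analysis
plan names thresholds (R-hat < 1.01, ESS > 1000) but not variants — computed
for every parameter including the site effects. Zero-variance chains yield
`NA` diagnostics and a non-converged flag with a message, never a crash.
Fits that miss the gates warn (`bayeskrt_convergence_warning`) and the
summary layer refuses them unless `force = TRUE`; the pipeline forces,
flags, and reports rather than aborting, so reanalysis batches remain
resumable.

## The synthetic generator: what it emulates, and what it does not

`sim_config()` defaults encode the emulated study conditions: 2927 patients
in 168 sites, 1:1 allocation, adjuster prevalences 57/33/44%, ~44% mortality
in both arms under a null effect, and KRT-free-day records missing at rate
27/1465 in the accelerated arm only (missing completely at random within
arm — published counts give no mechanism). Site sizes are multinomial with
symmetric Dirichlet(5) weights: realistic imbalance without extra
parameters. The baseline log-odds is calibrated by Gauss–Hermite quadrature
and root-finding so the marginal death rate hits its target exactly under
the configured covariate and site-effect law. The site SD default
(`tau_site = 0.25`) corresponds to a 95% between-site OR range of roughly
0.6–1.6, a moderate heterogeneity typical of large multicentre ICU trials;
adjuster effects default to modest values with the expected clinical signs
(sepsis up, surgical admission down, CKD slightly up).

Day endpoints are drawn from per-arm ZOIB laws whose zero inflation is
boosted for deaths: `zoi' = zoi + link*(1 - zoi)` with `coi` rescaled so the
one-boundary mass `zoi*coi` is preserved (`death_zero_link = 0.8` by
default). The rescaling keeps a degenerate all-at-90 configuration
degenerate while concentrating deaths at zero, matching the zero-heavy
interquartile ranges such endpoints show. The default ZOIB parameters were
chosen once to mimic the published medians and IQRs qualitatively
(KRT-free days piling up near 90 among survivors; hospital-free days low).

The generator does **not** emulate: the joint distribution of death and the
two day endpoints beyond the zero-coupling (unknown in the real data and
flagged as an assumption), KRT receipt or time-to-KRT, eligibility criteria,
per-country structure, or informative missingness. Passing tests therefore
demonstrate that the pipeline recovers the laws it assumes — not that those
laws describe any particular trial.

## Numerical choices and problem sizes

Sampler defaults are 4 chains, 1000 warmup, 2000 kept draws per chain —
sized so the slowest parameter (the site SD) clears the ESS > 1000 gate at
the full 2927-patient scale. `target_accept` exists for interface
compatibility; the Gibbs engine has no such knob and the Metropolis blocks
use the standard random-walk targets. The test suite runs reduced samplers
(2 chains, hundreds of draws) on trials of 100–4000 patients for unit
checks, and full-scale fits where a published quantity is recomputed: the
margins-reconstructed mortality fit (n = 2927, thinned), hierarchical
recovery of a true log(OR) of -0.257 across replicate seeds, and ZOIB
recovery at 2000 patients per arm. In the margins reconstruction the
adjusters are assigned *exactly* independent of the outcome within each arm
(stratified fill), so that covariate adjustment is neutral by construction
and the reconstructed posterior matches the collapsed-margins oracle to the
printed precision; with purely random assignment, chance imbalance of order
0.1 posterior sd would blur the last printed digit.

## Known limitations

* The ZOIB component structure and the marginalization convention are
  declared design choices where the original specification is not public.
* The beta-precision is constant across arms; between-arm spread differences
  are absorbed by the mixture components.
* No multiplicity adjustment and no imputation (complete-case analysis
  throughout), matching the reanalysis being emulated.
* Probability-of-direction uses the median-side convention; for posteriors
  with median exactly zero it returns 0.5.
* The synthetic generator's defaults are study-structure emulation, not a
  fit to any dataset; quantities that depend on the unknown joint law (e.g.
  day-difference magnitudes under informative treatment effects) should not
  be read as reproductions of published results.
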