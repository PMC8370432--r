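---
title: "Conductance-based dynamic causal modelling of auditory mismatch responses: models, inference and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance-based dynamic causal modelling of auditory mismatch responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microdcm)
```

# The scientific problem

`microdcm` implements a complete desk-scale pipeline for studying
GABAergic cortical physiology with biophysical generative models of
magnetoencephalographic evoked responses. The setting is a roving auditory
oddball experiment: a tone repeats three to ten times, then changes
frequency; the first tone of each train is an unexpected *deviant*, the
sixth a well-predicted *standard*. The differential cortical response to
deviants is generated by a frontotemporal network — bilateral primary
auditory cortex (A1), superior temporal gyrus (STG) and inferior frontal
gyrus (IFG) — and is sensitive to disease and to GABAergic drugs.

The pipeline has four stages, each usable on its own:

1. **Generative model** — a conductance-based mean-field model of a
   six-population cortical column, replicated over six sources and coupled
   by forward, backward and lateral connections.
2. **Inversion** — variational Laplace (Gauss–Newton free-energy ascent)
   fits the model to one subject's source-level event-related fields
   (ERFs), returning a Gaussian posterior over log-scaling parameters.
3. **Group inference** — Bayesian model reduction (BMR) and multi-level
   parametric empirical Bayes (PEB): second-level general linear models
   over subjects' posteriors, a third-level "PEB-of-PEBs" over group
   models, free-energy model comparison, and per-effect posterior
   probabilities.
4. **Synthetic cohorts** — a generator producing crossover-study cohorts
   (placebo/drug sessions, three diagnostic groups, a GABA-concentration
   covariate) with effects injected at named synapses, so every claim the
   pipeline makes can be checked against a known ground truth.

# The neuronal model

Each source is a cortical column with six populations: layer-4 spiny
stellate cells (`ss`), superficial pyramidal cells (`sp`), superficial
interneurons (`si`), deep cortico-cortical pyramidal cells (`dp`), deep
interneurons (`di`) and thalamic-projection pyramidal cells (`tp`). Each
population carries a mean membrane potential $V$ and three conductances
$g_{\mathrm{AMPA}}, g_{\mathrm{NMDA}}, g_{\mathrm{GABA_A}}$:

$$C\,\dot V = g_L(V_L - V) + g_{\mathrm{AMPA}}(V_E - V) +
  g_{\mathrm{NMDA}}\,m(V)\,(V_E - V) + g_{\mathrm{GABA_A}}(V_I - V) + u$$

$$\dot g_k = \kappa_k\!\left(\textstyle\sum_j W^{(k)}_{ij}\, r(V_j) - g_k\right)$$

with $m(V) = 1/(1 + 0.2\,e^{-0.06 V})$ the voltage-dependent magnesium
gate on NMDA channels and $r(V)$ the population firing rate. The rate is
the logistic sigmoid $\sigma(V) = 1/(1+e^{-\rho (V - V_T)})$ with its
resting value subtracted and rectified at zero,
$r(V) = \max\{\sigma(V) - \sigma(V_L),\, 0\}$, so that the resting state
($V = V_L$, all conductances zero) is an exact fixed point of the network
and conductances remain non-negative. Exogenous input $u$ is a Gaussian
bump (peak 60 ms after tone onset, dispersion 8 ms) driving the stellate
populations of bilateral A1 and IFG (the frontal input playing the role of
a temporal-expectancy signal).

## Constants

All constants live in one table (`cmm_constants()`); values are
conventional for this model family and every one is overridable:

| constant | default | unit | meaning |
|---|---|---|---|
| $V_L, V_E, V_I$ | −70, 60, −90 | mV | leak / excitatory / inhibitory reversal |
| $C/g_L$ | 10 | ms | membrane time constant |
| $\kappa_{\mathrm{AMPA}}, \kappa_{\mathrm{GABA_A}}, \kappa_{\mathrm{NMDA}}$ | 1/4, 1/16, 1/100 | ms$^{-1}$ | conductance rate constants |
| $V_T$, $\rho$ | −40 mV, 0.2 mV$^{-1}$ | | sigmoid threshold and slope |
| input amplitude | 48 | $g_L\cdot$mV | calibrated once so that peak depolarisations stay in the sigmoid's responsive range and all draws within ±3 prior SD integrate stably |

The intrinsic weight matrices (`microcircuit_spec()`) implement the
canonical laminar circuit: the excitatory chain
ss → sp → dp → tp (with a thalamocortical return tp → ss and collaterals
onto the interneurons), GABAergic self-connections on every population
(*tonic* background inhibition) and four *phasic* interneuron efferents
(si → ss, si → sp, di → dp, di → tp). Only interneurons send off-diagonal
inhibition; self-inhibition is permitted everywhere, which is how tonic
gain control is represented in this model family. The source publications
for this model class do not print the intrinsic weight values (they live
in code releases), so the defaults here are canonical choices documented
in `microcircuit_spec()`, not extracted numbers.

Extrinsic connections follow the usual laminar rules — forward projections
arise from `sp` and terminate on `ss`/`si`; backward projections arise
from `dp` and terminate on `sp`, `si`, `dp`, `di`; lateral connections
link homologous sources — and each directed edge carries one gain
parameter.

## Parameterisation

Every free quantity is a dimensionless log-scaling deviation $\theta$:
`actual = prior_mean * exp(theta)`, so $\theta = 0$ reproduces the
prior-mean model bit-exactly. Four parameter classes can be freed
(`prior_config()`): the ten named GABAergic synapses (shared across the
six sources, so PEB output reads directly as "tonic:di",
"phasic:si->ss", …), the fourteen extrinsic gains, the input amplitude and
latency, and the observation gain. Priors are zero-mean Gaussians with
per-class variances (default 1/16; latency 1/64).

## Numerics

Integration is fixed-step RK4 at 1 ms over the epoch −100…400 ms
(501 samples), in compiled code. Two deliberate approximations are
documented because tests quantify them: the two voltage nonlinearities are
evaluated from 0.05 mV interpolation tables (error < 1e−9, far below
every tolerance in the package), and the finite-difference Jacobians used
inside the optimizer integrate on a 2 ms grid (the integrator's
step-halving error is < 1e−3, so Gauss–Newton steps are unaffected; all
free-energy evaluations and final posteriors use the exact grid, and the
optimum is polished with exact-grid steps). Divergence (|V − V_L| >
150 mV) is a flagged error, never silent NaN. A *linear test mode* freezes
the rate function, magnesium gate and driving forces at their fixed-point
linearisations, giving an exactly linear system used by superposition
oracles in the tests.

# Observation model and conditioning

Source ERFs are a gain-scaled weighted sum of population depolarisations,
dominated by pyramidal cells (`observation_spec()`; weights 0.2 ss, 0.8
sp, 0.4 dp, 0.2 tp), with one free log-gain. Units are arbitrary — the
gain absorbs scale.

Conditioning (`condition_erf()`) applies, identically to simulated and
recorded data, a zero-phase FFT low-pass at 48 Hz (DC retained, content
above the edge removed exactly, zero group delay, idempotent) followed by
a Tukey window that is exactly 1 between 50 and 350 ms and cosine-tapers
to the epoch edges. The taper lengths (150 ms left, 50 ms right) are a
design choice: only the unattenuated interval is prescribed.

# Variational inversion

`invert_erf()` maximises the Laplace free energy

$$F = -\tfrac12 e^\top\Pi e + \tfrac12\ln|\Pi| - \tfrac n2\ln 2\pi
 - \tfrac12(\mu - m_0)^\top\Pi_0(\mu - m_0)
 - \tfrac12\ln\frac{|\Sigma_0|}{|\Sigma|}$$

over parameters $\mu$ (Gauss–Newton with a Levenberg–Marquardt damping
ladder; central finite-difference Jacobians, step 1e−3, cached per
iteration) and per-source noise log-precisions $\lambda$ (guarded Newton
updates against a N(4, 1) hyperprior). On linear-Gaussian models this $F$
equals the analytic log evidence, which the tests exploit. The reported
decomposition is `accuracy − complexity` with complexity the full Gaussian
Kullback–Leibler divergence from the prior (hence always ≥ 0). Accepted
steps never decrease $F$; convergence requires improvements below 0.01
nats on four consecutive accepted steps, confirmed against a
freshly-computed Jacobian. Everything is deterministic given data, priors
and settings.

One modelling point deserves emphasis: after the 48 Hz low-pass the
observation noise is strongly autocorrelated at the 1 kHz sampling rate.
A white-noise likelihood over all 501 samples per source would overcount
the data roughly five-fold and produce overconfident posteriors. The
likelihood is therefore evaluated on a 10 ms grid (51 samples/source),
the spacing at which the band-limited noise decorrelates — this matches
the information content of the passband (about 49 real degrees of freedom
per source for a 0.5 s epoch at 48 Hz) and restores nominal coverage of
the posterior (checked by simulation in the tests). Fit correlations are
still reported on the full grid.

Standard and deviant conditions are inverted separately; downstream group
analyses use the deviant-condition posteriors (the response of interest),
with the standard condition available via `conditions =` in
`fit_cohort()`.

# BMR and hierarchical PEB

`bmr_reduce()` computes, in closed form and without revisiting data, the
posterior and evidence change of a model whose prior has been changed —
the workhorse for pruning (`greedy_prune()`) and for per-effect posterior
probabilities. `fit_peb()` places a GLM over subjects' posteriors with
random effects whose magnitude is one shared log-precision per parameter
class, estimated by deterministic maximisation of the exact (conditionally
conjugate) marginal likelihood; `peb_of_pebs()` stacks a third level over
second-level models, so a group contrast applied to a drug-effect block is
a group-by-drug interaction. Pp for an effect compares the second-level
model with and without that (column, parameter) entry via BMR; the
significance convention is Pp > 0.95.

Design choices that were genuinely open:

* **Crossover blocks.** Each subject's two session posteriors are rotated
  into independent *session-level* (`level|` = average) and
  *drug-response* (`drug|` = half-difference) beliefs before the second
  level (`combine_sessions()`). This makes the crossover design explicit:
  subject trait variance loads on the level block and drug-response
  variance on the drug block, each with its own between-subject
  log-precision. Treating the 2n session rows as exchangeable instead
  leaves pair-correlated residuals that an unmodelled covariate can
  exploit — simulations showed a *permuted* GABA covariate gaining tens of
  nats of spurious evidence that way, which the rotation removes.
* **Separate parameter families.** Group analyses run the extrinsic gains
  and the intrinsic GABAergic synapses in separate PEBs (as the source
  analyses do: between-source connectivity questions versus within-source
  synaptic questions). This also keeps the free-energy comparison of
  covariate designs focused: a GABA column pays complexity only for the
  synapse family it is hypothesised to affect.
* **Second-level shrinkage.** Effect priors at the second level are the
  first-level prior variance divided by 8. Between-subject effects are
  expected to be a fraction of the within-subject prior range; this
  setting balances false-positive control (null-cohort calibration ≈ 0–2%
  of cells at Pp > 0.95 in the recovery simulations) against power for
  0.5-SD effects. It is the package's convention, exposed via
  `peb_settings()`.
* **Saturated third level.** With three group models and three contrasts
  the third-level design is saturated, so the between-model variance is
  fixed small (`gamma_fixed = 8`) rather than estimated — the conventional
  treatment of second-level posteriors as data.
* **Pruning off by default.** The prune-first workflow
  (`analyse_groups(prune = TRUE)`) removes parameters redundant *for the
  group mean*; contrast-coded effects (drug, interactions) have zero group
  mean and can be pruned away before the columns that would detect them,
  so pruning is opt-in.
* **GABA model comparison.** The with/without-GABA comparison concerns the
  covariate as a between-subjects variable, so it is evaluated on the
  session-level block of the GABAergic family only. A between-subject
  covariate effect *is* between-subject variance, so the comparison is
  delicate: per-parameter variance components are estimated once under
  the covariate-inclusive model and both designs are evaluated at them
  (the REML-style treatment of variance parameters when comparing fixed
  effects). A true covariate then leaves residual variances the base
  design cannot meet, while a permuted covariate leaves components that
  fit both designs — permutation simulations confirm near-zero median
  evidence change under shuffling. The GABA-by-drug interaction needs no
  extra column (it is the covariate's loading on the drug-response
  block); GABA-by-group interactions are explored in a separate PEB,
  mirroring the separate interaction analysis of the source study.

# The synthetic cohort generator

`generate_cohort()` emulates a randomized placebo-controlled double-blind
crossover study: 20 controls, 15 PSP, 17 bvFTD; two sessions (placebo,
tiagabine); two conditions (standard, deviant). Subject parameters are
drawn as $\theta = X\beta + \varepsilon$ with between-subject SD 0.1 and
the injected effects (in prior-SD units, default size 0.5):

| locus | type |
|---|---|
| `bwd:lIFG->lSTG` | group contrast (reduced backward frontotemporal gain in patients) |
| `tonic:di` | drug (increased background inhibition of deep interneurons on tiagabine) |
| `phasic:si->ss` | group-by-drug interaction (opposing drug effects in the two patient groups) |
| `phasic:di->dp`, `phasic:di->tp` | GABA-concentration slopes on the deep phasic synapses |

GABA is drawn per group (means 1.0 / 0.85 / 0.80, SD 0.1, arbitrary
units — only orderings and slopes are meaningful) and standardised before
entering designs. Deviants differ from standards by a +0.25 offset on the
four forward gains (the mismatch response as increased ascending drive).
Observation noise is white Gaussian per source at SNR 10 (RMS signal /
RMS noise at the reference trial count of 150; the averaging model scales
noise variance by 1/n with trial count). True parameters and noiseless
ERFs live in a sealed `truth` component that no inversion or PEB code
path reads.

What the generator does **not** emulate: sensor-level physics (data are
source ERFs by construction), conduction delays (deflections peak at
~70–90 ms rather than the 100–250 ms typical of patient recordings),
inter-individual variation in ERF morphology beyond parameter scalings,
artefact structure, or trial-count asymmetries between groups (constant
150 by default so realized SNR is within 10% of nominal). Passing
recovery tests therefore demonstrates internal consistency of the
inference chain under the model's own assumptions — not performance on
real MEG.

# Recovery performance and known limitations

With the default conditions, replicate-cohort simulations (the shipped
checks run five and four replicates; the numbers below pool the
development and shipped runs, eleven full cohorts in all) show:

* the group-by-drug interaction at the stellate phasic synapse is
  detected at Pp > 0.95 in every replicate;
* the drug effect on `tonic:di` reaches Pp > 0.95 in roughly two thirds
  of replicates, and the backward-gain group deficit in roughly half to
  three quarters — both sit close to the threshold. For `tonic:di` the
  reason is structural: the tonic self-inhibition of deep interneurons
  acts on the ERF almost entirely through the very efferents
  (`phasic:di->dp`, `phasic:di->tp`) that are themselves free parameters,
  so its Jacobian column is > 99.6% explained by the other columns and
  per-subject information is scarce; at 0.5-SD effects and SNR 10 the
  pooled evidence hovers around the 0.95 line. (The analogous drug effect
  in the source analyses was likewise reported at posterior probability
  > 0.9.) These are identifiability properties of the model class at
  these effect sizes, not implementation artefacts — the free-energy
  landscape is honest about them;
* effect-free cohorts are well calibrated (0–2% of effect cells above
  0.95) and essentially never select the GABA-inclusive model
  (posterior probability ≤ 0.04 in every null replicate);
* cohorts with GABA slopes select the GABA-inclusive model in about half
  of replicates: the evidence for a two-synapse, 0.5-SD covariate effect
  is itself a stochastic quantity, and the REML-style comparison
  deliberately refuses the spurious evidence a looser variance treatment
  would provide (permuting the covariate across subjects yields median
  evidence change ≈ 0, as it should).

Problem sizes used by the shipped checks: the acceptance-style tests run
five effect-carrying and two effect-free replicate cohorts end-to-end
(about 100 variational inversions each) plus ten single-subject recovery
inversions; the oracle blocks use 100 random reduction instances and 20
conjugate toys. The reproduction script runs four effect-carrying and two
effect-free cohorts. These sizes are the package's chosen desk-scale
defaults; larger replicate counts reproduce the same picture offline.

# Worked example

```{r example}
library(microdcm)

model <- compile_cmm(network_spec())

# simulate one subject's deviant response and look at it
erf <- simulate_erf(model, theta = c("tonic:di" = 0.3))

# a small cohort end to end
coh <- generate_cohort(cohort_spec(n_control = 4, n_psp = 3, n_bvftd = 3,
                                   seed = 1), model)
fits <- fit_cohort(coh, model)
groups <- analyse_groups(fits, coh$subjects)
gaba <- analyse_gaba(fits, coh$subjects)
report <- run_report(fits, groups, gaba, seed = 1)
report

# tidy access and plots
tidy(fits$fits[[1]])
autoplot(fits$fits[[1]])
autoplot(groups$peb3$intrinsic_gabaa)
plot_fit_density(fits$table)
```
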