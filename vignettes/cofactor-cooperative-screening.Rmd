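---
title: "Cofactor-cooperative screening: from DEL counts to cooperativity factors"
author: "delcoop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cofactor-cooperative screening: from DEL counts to cooperativity factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delcoop)
```

## The problem

Cancers that lose the *MTAP* gene accumulate the metabolite
methylthioadenosine (MTA), which occupies the cofactor pocket of the
arginine methyltransferase PRMT5. An inhibitor that binds *preferentially
to the MTA-loaded enzyme* inhibits PRMT5 only where MTA is high — in the
tumor — and spares normal tissue. Such compounds can be discovered by
running DNA-encoded library (DEL) affinity selections against the target
loaded with different cofactors (MTA versus the SAM analog sinefungin,
SIN) and looking for building-block series enriched under one cofactor
only, then quantifying the cooperativity with orthogonal biophysics:
thermal shift, fluorescence polarization (FP) kinetics, binding isotherms
and enzymatic dose–response.

`delcoop` implements that quantitative workflow end to end, together with
seeded synthetic-data generators that emulate every assay, so the whole
pipeline is testable without any instrument data.

## The cooperative ternary-complex model

Everything hangs off a mass-action equilibrium between enzyme E, a
cofactor-site ligand C (MTA), and an inhibitor I:

$$E + C \rightleftharpoons EC \;(K_C), \qquad
  E + I \rightleftharpoons EI \;(K_I), \qquad
  EC + I \rightleftharpoons ECI \;(K_I/\alpha).$$

The cooperativity factor $\alpha$ multiplies the inhibitor's affinity for
the cofactor-bound enzyme; $\alpha$ enters symmetrically (the cofactor's
affinity for EI is $K_C/\alpha$), which `solve_equilibrium()` preserves
exactly (detailed balance). An optional second cofactor-site ligand S
(the cosubstrate SAM) competes for the same pocket; its ternary complex
with the inhibitor is disallowed by default (`alpha_S = 0`), encoding the
steric clash that the extra methyl group of SAM introduces at the
inhibitor interface. At a given free cofactor concentration the observed
inhibitor dissociation constant is the closed form

$$K_{D,\mathrm{app}} = K_I\,\frac{1 + C/K_C}{1 + \alpha\,C/K_C},$$

interpolating between the apo value $K_I$ and the saturated value
$K_I/\alpha$. Conversely, measuring the apo and cofactor-saturated
dissociation constants gives $\alpha$ as their ratio
(`cooperativity_factor()`); the FP measurements of the workflow put the
probe compound at 754 nM apo and 38 nM MTA-bound, i.e. $\alpha \approx
19.8$.

```{r coop}
apparent_kd(K_I = 754, K_C = 5000, alpha = 19.84, C_free = c(0, 5e3, 6e4))
cooperativity_factor(754, 38)
```

`solve_equilibrium()` uses a damped fixed-point iteration on the free
concentrations (geometric damping keeps iterates positive) with a nested
root-bracketing fallback, converging mass-balance residuals below
`1e-12` — deliberately tighter than the `1e-9` the downstream contracts
assume. The mass-action system has a single physical root, so the two
paths agree; the test suite checks both against an independently written
nested-bisection oracle on random systems.

**Tight binding.** The enzymatic assay runs at 4 nM enzyme; once an
inhibitor's apparent $K_D$ falls near that, the measured IC50 floors at
$E_t/2$ (`morrison_ic50()`). The simulated activity assay reproduces this
behaviour mechanistically, because inhibitor depletion is handled by the
full equilibrium solver rather than a free-ligand approximation. One
numerical caveat: at the extreme corner limit $K_{D,app}\to 0$ the
titration curve becomes piecewise linear and the free-Hill 4PL midpoint
lands up to ~5% *below* the Morrison floor — a shape-approximation bias of
the 4PL estimator, not of the model. Away from that limit the fitted IC50
respects the floor.

## The DEL deconvolution stage

Counts are kept as a `count_table` keyed by building-block tuples, with
per-condition totals that include unmapped reads (so CPM, counts per
million, always refers to total sequencing depth; mapped plus unmapped
CPM sums to $10^6$ per condition). The stage follows the screen's
published filtering rule — compounds observed with fewer than three
sequence counts are removed — implemented per compound on the *maximum*
across conditions, because cross-condition comparison requires retaining
a compound that is absent in one arm. Selectivity between two conditions
is `log2((cpm_a + 1)/(cpm_b + 1))`; the 1-CPM pseudocount and log base
are conventions (the screen reports only qualitative enrichment
patterns). Series detection enumerates exact single-position
building-block constraints — DEL hit series are defined by shared
building blocks, so constraint enumeration replaces generic clustering —
and ranks by median member selectivity, then aggregate CPM, with
lexicographic tie-breaks for determinism.

## What the generators emulate, and what they do not

`simulate_selection()` models one condition as: per-round capture
probability $p_i = b + (1-b)\,f_i$, with $f_i$ the bound fraction at the
selection protein concentration given the compound's apparent $K_D$ under
that condition's cofactor, and $b$ a background (matrix-binding) capture
probability; two rounds compound as $p_i^2$; sequencing allocates a fixed
read depth by multinomial sampling (Dirichlet-multinomial when an
overdispersion parameter is set; the multinomial is recovered as
dispersion $\to 0$). Defaults mirror the screening design: 6 µM protein,
60 µM cofactor, two rounds. Choices the assay description leaves open,
fixed here once:

* **Background capture 0.005/round.** No background rate is published;
  0.5% per round survives five washes and yields the read levels at which
  a three-count filter is meaningful at $10^5$ reads.
* **SAM condition = 3% MTA.** SAM hydrolyses spontaneously to MTA; the
  fraction in a working stock is not quantified anywhere, so 3% is a
  placeholder exposed as `sam_mta_contamination`. It reproduces the
  observed *intermediate* enrichment of MTA-cooperative compounds under
  SAM.
* **Desk-scale library.** The tested screen uses a 12 × 15 × 14 library
  (2,520 compounds) with one planted MTA-cooperative series on position 2:
  apo $K_D$ 6 mM, $\alpha_{MTA} = 20$. The weak apo affinity is what makes
  the planted series behave like the real one: at 60 µM MTA its apparent
  $K_D$ is ~320 µM, giving ~2% capture per round against the 0.5%
  background under MTA but near-background capture under SIN, so the
  non-cognate arm's reads stay dominated by background — the regime a
  226-million-compound library is in automatically. At desk scale this
  must be imposed through the planted affinity, otherwise the series
  soaks up the non-cognate arm's depth and CPM contrasts collapse.

Not simulated: PCR-cycle amplification noise, barcode sequencing errors
(tags are tallied exactly; decoding from raw reads is a format concern),
UMI handling, and chemistry-aware structures (building blocks are opaque
ids). Passing round-trip tests therefore demonstrates the *statistical*
recoverability of planted series under multinomial depth sampling, not
robustness to amplification artifacts.

```{r screen}
lib <- gen_library(3, c(12, 15, 14))
truth <- ground_truth(planted_series(c(pos2 = "P2.B007"), kd_apo = 6e6,
                                     alpha = c(MTA = 20, SIN = 1)))
cfg <- selection_config(conditions = c("MTA", "SIN"), depth = 1e5)
ct <- simulate_selection(lib, truth, cfg, seed = 1)
enr <- selectivity_score(cpm_normalize(filter_min_count(ct, 3)),
                         "MTA", "SIN")
head(detect_series(enr, min_members = 10, min_cpm = 100,
                   min_selectivity = 1), 3)
```

## The FP kinetics stage

Association traces follow pseudo-first-order kinetics,
$k_{obs} = k_a[P] + k_d$, with the plateau from the binding isotherm at
$[P]$ (free-ligand approximation: protein is in excess over the 1–25 nM
probe throughout, matching the assay design). Three independent routes to
$K_D$ are implemented and cross-checked by `kd_concordance()` (default
pass threshold: 2-fold max pairwise difference):

1. **Saturation**: `fit_saturation()`, either the one-site hyperbola or —
   whenever $K_D$ is not well above the fixed labeled-species
   concentration — the exact pairwise-binding quadratic
   (`bound_fraction_quadratic()`). The naive hyperbola overestimates a
   9 nM $K_D$ nearly three-fold at a 25 nM probe; the depletion-aware fit
   recovers it exactly.
2. **Kinetic**: per-trace `fit_exponential()` then an unweighted ordinary
   least-squares line of $k_{obs}$ versus concentration
   (`kinetic_kd()`); slope $k_a$, intercept $k_d$. A weighted option
   exists but is not the default, since the source protocol states no
   weighting.
3. **Dissociation**: displacement by excess unlabeled compound
   (rebinding neglected — full blockade assumed), fitted off-rate divided
   by the kinetic route's $k_a$.

**Units.** $K_D = k_d/k_a$ on dimensional grounds (intercept in s⁻¹ over
slope in M⁻¹s⁻¹ gives molar); the protocol text that inverts this ratio
is treated as a typographical slip. Rates are s⁻¹ internally; plate
readers reporting min⁻¹ go through `per_min_to_per_s()` /
`fp_trace(..., time_unit = "min")`, and the suite checks the two paths
give identical $K_D$.

**Read scheduling.** Each simulated trace is read at 12 points
concentrated over its own exponential rise (0.2–1.2 characteristic
times, with plateau anchors to six; `fp_design_times()`), as one would
schedule after a pilot read. This halves the variance of the recovered
$K_D$ relative to a shared doubling grid; the estimation itself never
sees the planted rate. With 8 concentrations spanning 0.25–8 × $K_D$ and
2 mP Gaussian noise, the kinetic route recovers planted $K_D$s with
~11% median absolute error; the saturation and dissociation routes are
severalfold tighter.

## Thermal shift

`simulate_melt_curve()` is a two-state logistic in temperature on a
0.5 °C grid over 25–95 °C (one read per 0.5 °C, mirroring a
0.5 °C/min ramp). `call_tm()` fits a Boltzmann sigmoid after trimming
everything above the smoothed fluorescence maximum (Sypro-Orange dye
release decays after the transition); the fallback/alternative is the
maximum of a smoothing-spline first derivative, which agrees with the
Boltzmann midpoint within 0.25 °C on clean sigmoids. Curves whose
amplitude is below eight times the point-to-point noise floor raise a
"no transition" error rather than returning a number; two derivative
peaks above 30% of the maximum flag the curve multiphasic, and the
larger-amplitude transition is reported. Tm calling is invariant to
affine rescaling of the fluorescence channel. `delta_tm_matrix()` then
tabulates stabilization against a chosen reference condition in kelvin.

The generator's occupancy link for qualitative tests,
$\Delta T_m = c\,\ln(1 + L/K_D)$, is a convenience (thermodynamic
coupling constants are compound-specific and unpublished); it is used
only to check monotonicity, never as a quantitative truth.

## Dose–response

`fit_4pl()` fits the four-parameter logistic in the log-concentration
domain by Levenberg–Marquardt from three deterministic starts
(quartile-derived top/bottom, half-response IC50, jittered), lowest
residual sum wins. Zero doses enter as the exact $x \to 0$ limit of the
model rather than a finite log anchor, which makes noiseless curves with
an untreated well exactly recoverable and keeps the fit exactly
equivariant under concentration rescaling. The Hill slope is free by
default (no slopes are published for these assays); `fix_hill = 1` is
available. The reported IC50 is the curve midpoint (relative IC50); the
fitted asymptotes are returned so an absolute potency can be derived
when the bottom plateau is meaningful.

For the enzymatic assay the generator composes the full system — 4 nM
enzyme, 5 µM SAM (less its 3% MTA contamination, which is carried over
as cofactor), ± 1 µM added MTA — and emits luminescence proportional to
the productive (SAM-bound, inhibitor-free) enzyme fraction. Product
accumulation and substrate kinetics are not modelled; activity is a
pseudo-equilibrium readout. The planted inhibitor $K_I$ is calibrated
with `activity_ki_for_ic50()` so the noiseless +MTA curve fits to the
published 5 nM IC50 at the measured $\alpha = 754/38$; the −MTA arm then
shows the correct potentiation ordering, though not the full published
8-fold ratio — under this model the MTA already present as SAM
contamination compresses the attainable ±MTA ratio below ~7, which is
itself an argument the workflow makes: SAM-dependent activity assays
cannot measure absolute MTA cooperativity.

## Problem sizes and determinism

All stochastic recoveries in the tests and the acceptance script use 20
seeds (50 for the DEL round trip) at the designs above: 8 × 12 FP reads
per condition, $10^5$ reads per selection arm, 141-point melt curves,
12-point titrations. Every generator takes an explicit seed, restores
the caller's RNG state, and yields byte-identical output for identical
seeds. The full suite runs in about two minutes on one core.

## Known limitations

* Building-block chemistry, truncate/deletion encoding artifacts and
  distance-based compound clustering are out of scope; series are exact
  single-position constraints.
* The activity model has no catalytic turnover; IC50s from it are
  binding-limited. Cellular potency shifts (protein abundance, MTA
  levels, SDMA turnover) are not modelled.
* Gaussian signal noise throughout; real plate readers show
  occasional outliers that would call for robust loss functions.
* The equilibrium solver assumes one inhibitor species and at most two
  cofactor-site ligands; higher-order mixtures need the general solver
  pattern but are not exposed.
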