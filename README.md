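# delcoop

Quantitative workflow for discovering and characterising
**cofactor-cooperative enzyme inhibitors** from DNA-encoded library (DEL)
screens — motivated by MTA-cooperative PRMT5 inhibition in *MTAP*-deleted
cancer, where the accumulated metabolite MTA occupies the PRMT5 cofactor
pocket and a cooperative compound binds tightly only to the MTA-loaded
enzyme.

The package is aimed at screening/biophysics scientists and computational
chemists who need the full analysis stack behind such a campaign in one
tested place:

* **DEL deconvolution** — tag-count tables keyed by building-block
  tuples; minimum-count filtering; CPM (counts per million)
  normalisation; cofactor-selectivity scoring; synthon aggregation;
  single-position building-block series detection; qPCR double-delta-Ct
  fold enrichment for conjugate validation.
* **Cooperative ternary-complex model** — mass-action equilibrium of
  enzyme E, cofactor C and inhibitor I with cooperativity factor α
  (`K_D(I|E·C) = K_I/α`), an optional competing cosubstrate whose ternary
  complex is sterically disallowed, the closed form
  `K_D,app = K_I (1 + C/K_C) / (1 + α C/K_C)`, and the tight-binding
  (Morrison) IC50 floor `IC50 = K_D,app + E_t/2`.
* **Biophysical validation** — thermal-shift Tm calling (Boltzmann fit
  with derivative fallback) and ΔTm matrices; FP binding kinetics
  (`k_obs = k_a[P] + k_d`, K_D = k_d/k_a) with saturation, kinetic and
  dissociation-by-displacement routes plus a concordance check;
  ligand-depletion-aware binding isotherms; 4PL dose–response fitting
  and potency ratios.
* **Seeded synthetic-data generators** for every assay, so each stage is
  testable end to end against planted ground truth.

## Worked example

Simulate a two-condition (MTA vs SIN) selection of a 2,520-compound
library carrying one planted MTA-cooperative series on position 2, then
deconvolute it:

```r
library(delcoop)

lib   <- gen_library(3, c(12, 15, 14))
truth <- ground_truth(planted_series(c(pos2 = "P2.B007"), kd_apo = 6e6,
                                     alpha = c(MTA = 20, SIN = 1)))
cfg   <- selection_config(conditions = c("MTA", "SIN"), depth = 1e5)

ct  <- simulate_selection(lib, truth, cfg, seed = 1)
enr <- selectivity_score(cpm_normalize(filter_min_count(ct, 3)),
                         "MTA", "SIN")
head(detect_series(enr, min_members = 10, min_cpm = 100,
                   min_selectivity = 1), 3)
#>   position building_block n_members median_selectivity aggregate_cpm
#> 1     pos2        P2.B007       168           2.688085        604120
#> 2     pos1        P1.B008       146          -1.288528         72160
#> 3     pos3        P3.B005       129          -1.315776         59880
```

The planted building block tops the ranking with a median log2(MTA/SIN)
selectivity of 2.7; the remaining rows are background blocks riding the
depth asymmetry between arms. Validate a hit's affinity by all three FP
routes at a 1 nM probe (planted K_D = 9 nM, 2 mP noise):

```r
res <- fp_three_route_kd(fp_truth(9, probe_conc = 1, noise_sd = 2), seed = 1)
res$concordance
#> K_D concordance across methods
#>   saturation = 8.86 nM, kinetic = 7.55 nM, dissociation = 9.3 nM
#>   geometric mean 8.54 nM; max fold-difference 1.23 (PASS at 2x)
```

Call a melting point and quantify cooperative inhibition under the
enzymatic assay composition (4 nM enzyme, 5 µM SAM, +1 µM MTA; the
planted inhibitor K_I is calibrated so the noiseless +MTA curve fits a
5 nM IC50 at the measured cooperativity α = 754/38):

```r
call_tm(simulate_melt_curve(melt_params(54.4, noise_sd = 0),
                            condition = "apo"))
#> Tm = 54.40 degC (boltzmann method)
#>   transition width 1.50 K, amplitude 9e+03, R^2 = 1.00000

alpha <- cooperativity_factor(754, 38)     # 19.84
ki    <- activity_ki_for_ic50(5, alpha = alpha, mta_added = 1000)
sys   <- activity_system(K_I = ki, alpha = alpha, mta_added = 1000)
fit_4pl(simulate_activity_assay(sys, c(0, 5 * 2^seq(-4, 5)), seed = 1))
#> 4PL fit: IC50 = 4.936 nM, hill = 1.31
#>   top = 433.1, bottom = 13.25, RSS = 505.7
```

The fitted IC50 sits just above the tight-binding floor of
E_t/2 = 2 nM, which is why potency in the +MTA arm is read as a lower
bound on affinity at this enzyme concentration.

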