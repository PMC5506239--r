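# radnp

Quantitative analysis of radio-enhancement by metallic nanoparticles in
radioresistant bacteria: dose–response survival modelling for clonogenic
assays, staged nonlinear least-squares fitting, sensitization metrics, and
the dosimetry arithmetic that links nanoparticle exposure, per-cell uptake
and toxicity.

The package is written for radiobiologists and microbiologists who measure
colony-forming-unit (CFU) survival of *Deinococcus radiodurans*-like
organisms after gamma irradiation, with or without a nanoparticle
sensitizer, and want a reproducible, scriptable replacement for
point-and-click curve fitting.

## The model

A cell carrying `n` genome copies survives if at least one copy remains
functional:

```
S_cfu(D) = 1 - (1 - S(D))^n ,          n = 4 by default
S(D)     = exp( -α D exp[ -β exp(-δ D) ] )
```

with dose `D` in kGy, where

* `α` (kGy⁻¹) — induction rate of lethal double-strand breaks; at high dose
  `S → exp(-α D)`,
* `β` (dimensionless) — repair capacity; it produces the low-dose survival
  "shoulder",
* `δ` (kGy⁻¹) — radiation inactivation of the repair proteins themselves,
  which erodes the shoulder with increasing dose.

Fitting is staged, following how the curve is actually informative: `α` is
first anchored by a through-origin regression of `-ln S` on dose over the
high-dose tail (`S ≈ exp(-α D)` there), then `(β, δ)` are estimated
conditionally, and finally the staged solution is refined by a local joint
least-squares polish (`mode = "staged_refine"`, the default; the strictly
frozen-α variant is `mode = "paper_staged"`).

Derived metrics:

* **SER(50%)** — sensitization enhancement ratio: ratio of doses giving 50%
  CFU reduction without vs. with sensitizer,
* **amplification at dose D** — relative survival reduction
  `(S_ref - S_test)/S_ref`,
* exposure/uptake arithmetic: particles-per-cell ↔ mg/L conversions,
  per-cell particle number, mass and volume occupancy from a bulk ICP-MS
  platinum mass,
* CFU toxicity ratios, minimal inhibitory concentration (>20% reduction),
  OD600 doubling times, and two-factor ANOVA with Tukey contrasts.

## Worked example

```r
library(radnp)

sc <- reference_scenarios()            # packaged parameter rows & constants

# simulate a triplicate clonogenic assay under the control condition
assay <- simulate_clonogenic_assay(sc$table1_control, seed = 2024)
fit   <- fit_survival_model(assay_to_dataset(assay, label = "control"))
fit
#> <radnp_fit> [control]
#>   mode: staged_refine | loss: log | high-dose threshold: 4.5 kGy
#>   alpha [kGy^-1]    0.2488  (se 0.009638)
#>   beta             27.4602  (se 119.2)
#>   delta [kGy^-1]    1.1364  (se 1.007)
#>   adj. R^2: 0.9278 | converged: TRUE | n doses: 17
```

The DSB-induction rate `α` comes back close to the generating 0.290 with a
tight standard error; `β` and `δ` are weakly identified from a single noisy
0–8 kGy curve, and their large standard errors say so honestly (see the
methods vignette for the identifiability analysis). On noiseless data the
fit recovers the generating parameters exactly.

```r
sensitization_enhancement_ratio(sc$table1_control, sc$table1_ptnp)
#> [1] 1.22731        # model-implied SER at 50% CFU reduction

amplification_at_dose(cfu_survival(8, sc$table1_control),
                      cfu_survival(8, sc$table1_ptnp))
#> [1] 0.3968328      # ~40% fewer survivors at 8 kGy with nanoparticles

uptake_report(1.079, 7e8, sc$particle, sc$cell$volume_nm3,
              administered_mass = 20)
#>   total_particles particles_per_cell mass_per_cell_pg cell_volume_fraction_pct
#>           3.33e12              4758.          0.00154                 0.000476
```

So a measured 1.079 µg of platinum across 7×10⁸ cells corresponds to ≈4800
particles (≈0.0015 pg) per cell, occupying ≈0.0005% of the cell volume —
isolated clusters, not a filled cytosol — and ≈5.4% uptake of the
administered 20 µg.

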