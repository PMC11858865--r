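# usp4pbpk

Biorelevant flow-through dissolution and PBPK extrapolation for
modified-release amorphous solid dispersion (ASD) formulations.

`usp4pbpk` is aimed at formulation and biopharmaceutics scientists who run
open-loop USP apparatus IV dissolution experiments with sequential
biorelevant media and want to turn those curves into whole-blood
concentration–time predictions for a poorly soluble, extensively red-cell
bound compound such as tacrolimus.  The package covers the full in vitro–in
vivo extrapolation (IVIVE) loop:

1. **In vitro**: a mixed flow-through cell perfused by a timed gradient of
   five fasted-state media (FaSSGF → FaSSIF-V2 → FaSSIF-V2 midgut →
   SIF Ileum-V2 → FaSSCoF over 6 h), with particle dissolution governed by a
   diffusion-layer model (DLM) carrying a dimensionless per-medium scalar.
2. **Scalar estimation**: windowed least-squares fitting of those scalars
   under the procedural constraint that at most three media enter one fit,
   with explicit non-estimability handling for fast products that finish
   dissolving before the distal media are introduced.
3. **In vivo**: a nine-compartment gastrointestinal transit/absorption model
   (Stomach, Duodenum, Jejunum I–II, Ileum I–IV, Colon) with gut-wall CYP3A
   extraction, coupled to a minimal two-compartment PBPK disposition model
   with well-stirred hepatic clearance and concentration-dependent
   blood-to-plasma partitioning.
4. **Evaluation**: AUC₀–₁₄₄ₕ, Cmax and Tmax with the fold-error criterion
   (≤ 1.25 good, ≤ 2 acceptable), and a grid sensitivity analysis to resolve
   ileal/colonic scalars that the in vitro data cannot identify.

## The models

**Dissolution (Nernst–Brunner diffusion layer).** For a population of
spherical particles of radius *r* with effective boundary layer
*h* = min(*r*, *h*ₘₐₓ):

    dm/dt = −S · Σᵢ Nᵢ · 4π rᵢ (rᵢ + hᵢ) · (D/hᵢ) · (Cs − Cb),   rate ≥ 0

where *S* is the dimensionless DLM scalar (fitted per medium / GI region),
*D* the diffusivity, *Cs* the apparent solubility in the current medium and
*Cb* the bulk concentration.  The open-loop cell is an ideally mixed vessel:
dissolved drug washes out at *Q/V*, and the cumulative percent dissolved
counts cell plus effluent.

**Absorption.** Solid and dissolved drug transit the nine GI compartments
sequentially; per region, dissolution uses the regional scalar and the
matching medium's solubility, absorption flux is 2 *P*eff/*R* times the
dissolved amount (none from the stomach), and absorbed drug crosses an
enterocyte pool with first-order CYP3A4/3A5 metabolism before reaching the
portal vein.  Alternatively, an in vitro cumulative curve *d*(*t*) can drive
release directly through its hazard λ(*t*) = *d*′(*t*)/(1 − *d*(*t*)).

**Disposition.** Two compartments with well-stirred hepatic extraction of
the portal inflow (first pass) and systemic clearance
CLₕ = Q_h·fu·CLint/(Q_h + fu·CLint); whole-blood output via the saturable
red-cell binding ratio B:P(Cp) = 1 + (BPₘₐₓ − 1)/(1 + Cp/C₅₀).

## Worked example

Fit the five per-medium scalars from a slow (reference-product-like)
profile, map them to the nine GI regions, and score a virtual 12-subject
study against an independently simulated population:

```r
library(usp4pbpk)
protocol <- build_default_protocol()
form <- formulation(dose = 5)          # 5 mg, monodisperse 10 um particles

true <- setNames(c(0.05, 0.04, 0.03, 0.02, 0.015), protocol$segments$medium)
profile <- simulate_usp4(form, protocol, true)
fit <- fit_scalars_chained(profile, protocol, form, seed = 1)
fit
#> <scalar_fit>
#>   FaSSGF             0.05
#>   FaSSIF-V2          0.04
#>   FaSSIF-V2 midgut   0.03
#>   SIF Ileum-V2       0.0204
#>   FaSSCoF            0.01592

regions <- gi_regions(protocol,
                      dlm_scalars = map_scalars_to_regions(fit, protocol))
disp <- compound_disposition()
study <- gen_virtual_study(form, regions, disp, n = 12, seed = 7)
pop <- simulate_population(form, regions, disp, n = 12, seed = 8)
metrics_report(split_subjects(study$data), pop$subjects)
#>      metric mean_obs sd_obs mean_sim sd_sim fold_error class
#> 1 auc_0_144   129.65  46.41   149.05 44.193       1.15  good
#> 2      cmax    10.98   3.53    12.40  3.061       1.13  good
#> 3      tmax     3.29   0.62     3.31  0.322       1.01  good
```

The first three scalars are recovered essentially exactly; the ileal and
colonic scalars carry a few percent of approximation error from the
three-media grouping windows.  In the report, fold errors compare the mean
of each metric across arms; all three fall in the "good" class (≤ 1.25).
A fast product that reaches 100% release before the ileal medium enters
returns `non-estimable` flags instead, which `run_pipeline()` resolves by a
grid sensitivity scan against observed PK data (`scan_scalars()` /
`select_scalars()`).

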