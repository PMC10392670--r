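# dnatwist

Torsional mechanics of double-stranded DNA from end-to-end-twist
restrained ensembles.

Over- and underwinding of DNA — the torsional strain generated by
transcription, replication and chromatin remodelling — is probed in
simulation by restraining the **end-to-end twist** of a DNA fragment (the
sum of its base-pair-step twist angles) with a quadratic bias
`K_tw (twist − twist_ref)²`, sampling a cascade of umbrella windows from
underwound to overwound, and reconstructing the twisting potential of mean
force (PMF) with WHAM. The PMF's curvature `K` (from a quadratic fit
`F(δ) = K δ²` on the per-bp-step axis) converts to a **torsional modulus**
through the homogeneous rod model,

    C = 2 K_rad · L_bp / (n · k_B T),      L_bp = 0.34 nm,

equivalently `C = L_bp / Var(θ_step)` for independent steps — a stiffness
expressed as a length, directly comparable to single-molecule estimates
(~100 nm for free B-DNA). The twist-only supercoiling density is
`σ = Δtw/tw₀` (±5°/bp ≈ ±0.15 at tw₀ ≈ 34.3°/bp).

The package is aimed at people analysing (or prototyping analyses of)
twist-restrained molecular simulations of DNA and protein–DNA complexes.
It provides:

* **Helical geometry** — base/bp reference frames (Kabsch fit of standard
  base geometries), the six inter- and six intra-bp parameters with an
  exactly invertible mid-frame convention, end-to-end twist, per-step axis
  bending, groove widths/depths from cross-strand P–P distances, and
  Watson–Crick H-bond integrity; multi-model PDB in/out.
* **Synthetic ensembles** — a Gaussian-mixture rigid-base-pair Monte Carlo
  generator with bimodal "twist-capacitor" pyrimidine–purine steps
  (substates 20° apart), exact or collapsed-Metropolis sampling under the
  twist restraint, and a coordinate builder for fixture structures.
* **Free energies and elasticity** — 1-D WHAM with overlap diagnostics,
  quadratic PMF regression, rod-model moduli, supercoiling conversion.
* **Deformation energy** — a harmonic multi-substate evaluator with
  nearest-neighbour Ising coupling, computed by transfer matrix
  (Boltzmann-summed or minimum-chain), with a JSON parameter loader.
* **Contacts** — protein–DNA hydrogen-bond/hydrophobic classification
  (specific = base moiety, nonspecific = backbone/sugar) and per-frame
  occupancies.
* **Orchestration** — `run_all()` chains simulate → umbrella → WHAM → fit
  → modulus → twist partition → deformation → bend/groove readouts from a
  YAML/list configuration, writing CSV/JSON outputs and a Markdown report;
  a thin CLI wrapper lives in `inst/cli/dnatwist.R`.

## Worked example

Recover the torsional modulus of a synthetic 23-mer whose ground truth is
known exactly (per-step twist SD 3.171° ⇒ 111 nm):

```r
library(dnatwist)

model    <- default_model("GGCGAGTAGCACGTGCTACTCGC",
                          twist_sd = 3.171, bimodal = FALSE)
region   <- restrained_region("GGCGAGTAGCACGTGCTACTCGC", "GTAGCACGTGCTAC")
schedule <- make_umbrella_schedule(model_mean_twist(model, region),
                                   n_frames = 5e4)   # 21 windows, ±5°/bp
windows  <- run_umbrella(model, schedule, k_tw = 0.06,
                         region = region, seed = 1, keep = "cv")
pmf <- wham(windows)
fit <- fit_force_constant(pmf, half_range = 2)
fit
#> <elastic_fit> K = 0.3914 kcal/mol/deg^2 (per bp step), centre = +0.015 deg,
#>               R^2 = 0.99913 (209 bins, +-2 deg)
torsional_modulus(fit)
#> <torsional_modulus> C = 112.7 nm (K = 0.3914 kcal/mol/deg^2, n = 13,
#>                     L = 0.34 nm, T = 300 K)
ground_truth_modulus(model)
#> [1] 111.0022
```

`K` is the curvature of the twisting PMF on the per-bp-step axis; at this
sampling depth the recovered modulus (112.7 nm) sits within ~1.5% of the
generator's exact value, and converges further with more frames per
window. `supercoiling_density(5, 34.6)` reports the `σ ≈ 0.14` reached by
the outermost windows of this schedule; `overlap_report(windows)` confirms
every adjacent window pair shares histogram support (~0.15 here).

The same chain runs end to end from a configuration:

```r
res <- run_all(list(n_frames = 2e4, seed = 7, output_dir = "demo_run"))
```

which writes `pmf.csv`, `elasticity.json`, `twist_partition.csv`,
`deformation.csv`, `bending.csv`, `grooves.csv` and `report.md`.

## Further reading

The methods vignette (`vignettes/dnatwist-methods.Rmd`) documents the
model conventions, the collapsed-Metropolis sampler, the WHAM and
regression defaults, the rod-model derivation and its fluctuation
identity, what the synthetic generator does and does not emulate, and
known limitations.
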