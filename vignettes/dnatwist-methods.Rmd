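---
title: "Torsional mechanics of DNA from twist-restrained ensembles: models and methods"
author: "dnatwist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsional mechanics of DNA from twist-restrained ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnatwist)
```

## The problem

How much energy does it cost to over- or underwind a stretch of
double-stranded DNA, and where in the sequence does imposed torsional
stress go? In simulation studies this is probed by restraining the
*end-to-end twist* of a DNA fragment — the sum of the helical twist angles
of its base-pair (bp) steps — with a quadratic bias, sampling a ladder of
umbrella windows from underwound to overwound, and reconstructing the
potential of mean force (PMF) of twisting by WHAM. The curvature of that
PMF gives a torsional force constant, which the homogeneous rod model
converts into a torsional modulus expressed as a length. `dnatwist`
implements this entire analysis chain, together with the structural
readouts used alongside it (per-step twist partition, axis bending, groove
geometry, Watson–Crick integrity, protein–DNA contacts) and a synthetic
rigid-base-pair ensemble generator that stands in for atomistic
trajectories.

The reference protocol the defaults encode: a 23-mer duplex
`GGCGAGTAGCACGTGCTACTCGC` carrying the E-box element `CACGTG`, restrained
over the central 13 bp steps (`GTAGCACGTGCTAC`), force constant
$K_{tw} = 0.06\ \mathrm{kcal\,mol^{-1}\,deg^{-2}}$ in the *literal*
quadratic $K_{tw}(\mathrm{twist}-\mathrm{twist}_{ref})^2$ (no $\tfrac12$
factor; divide by two to convert to the $\tfrac12 k\delta^2$ convention),
windows every $0.5^\circ$/bp step ($6.5^\circ$ of total twist) out to
$\pm 5^\circ$/bp, i.e. 21 windows; at a relaxed twist of
$\approx 34.3^\circ$/bp the extreme windows correspond to a twist-only
supercoiling density $\sigma \approx \pm 0.15$.

## Helical geometry

Base frames are fitted to ring heavy atoms by Kabsch superposition of
embedded standard base geometries. Step parameters use the symmetric
mid-frame (CEHS/3DNA-style) decomposition: the two z axes are rotated onto
their bisector about the hinge axis, twist is measured between the
resulting x axes, roll/tilt are the polar components of the bend angle,
and translations are projected on the mid-frame axes. This convention was
chosen over a curvilinear-axis scheme because it is *exactly invertible*:
`compose_step()` reconstructs the successor frame from the six parameters
to machine precision, which turns every decomposition into a testable
round trip and makes the coordinate builder (`build_coordinates()`) an
exact fixture generator. Analyses of structures produced by
curvilinear-axis software will therefore show small systematic offsets in
roll/tilt-rich regions; twist sums agree closely.

Groove geometry follows the spirit of the refined cross-strand P–P
distance method: each phosphorus carries a fractional bp level, pairs are
classified minor/major by the sign of their level offset, per-level widths
are minimal cross-strand P–P distances minus the 5.8 Å backbone
correction, and depths are measured from the bp mid-frame origin to the
width vector. No curvilinear axis is constructed; levels whose flanking
phosphates are missing are flagged `NA`, never silently zeroed. The
fibre-geometry phosphate placement in the builder was calibrated once so
that an ideal 36°/3.38 Å helix reproduces B-DNA-like raw P–P minima
(≈11.8 Å minor, ≈17.2 Å major). Watson–Crick integrity uses the canonical
heavy-atom donor–acceptor pairs with a melting flag at distances
$\ge 4.0$ Å (the boundary itself counts as melted).

## The synthetic ensemble generator

`default_model()` builds a Gaussian-mixture rigid-base-pair model: each
step has one or more harmonic substates with energy
$\tfrac12(x-\mu_s)^\top F_s (x-\mu_s) + \varepsilon_s$ over the six step
parameters, and pyrimidine–purine steps (TA, TG, CA, CG) receive two twist
substates separated by 20° — the *twist capacitor* motif. Defaults
(synthetic, chosen once for B-DNA realism, not fitted to any trajectory):
per-substate twist SD 3.0° (2.5–3.2° is the plausible band; the acceptance
pipelines use 3.171° and 2.578°, whose rod-model moduli are 111 nm and
168 nm), translation SDs 0.30–0.45 Å, tilt SD 2.7°, roll SD 5.0°,
twist–roll correlation −0.4, twist–slide +0.3, substate coupling J = 0,
T = 300 K.

Sampling is exact wherever exactness is tractable:

* **Unbiased**: substate labels are drawn from their marginal chain
  (parameters integrated out; transfer-matrix sampling when J ≠ 0), then
  parameters from the conditional Gaussians — i.i.d. frames.
* **Biased, unimodal**: the bias adds a rank-one term to the joint twist
  precision; unbiased blockwise draws are corrected by Matheron-style
  conditioning on a noisy pseudo-observation of the collective variable —
  still i.i.d.
* **Biased, multimodal**: labels move by Metropolis sweeps on the
  *collapsed* distribution. Because the bias sees only the Gaussian CV
  marginal, integrating the parameters out gives the closed-form label
  weight $-\tfrac12\log(1+cV) - c(\mu-\mathrm{ref})^2/(2(1+cV))$ with
  $c = 2\beta K_{tw}$ and $(\mu, V)$ the label-dependent CV mean and
  variance. A naive label/parameter alternation was rejected: with
  substates ~7 SDs apart it switches almost never, whereas the collapsed
  chain accepts 40–70% of moves in typical windows. In fully switched
  extreme windows the acceptance drops because the equilibrium label state
  is frozen — the run warns below 1% and continues. A 10% burn-in is
  discarded on this path only; the i.i.d. paths need none.

The cascade schedule starts from the relaxed reference and moves outward
in both directions, each window seeded from the previous window's final
configuration (the central window seeds both cascades), mirroring the
sequential protocol it emulates. All randomness derives from one master
seed with an independent stream per window, so runs are bit-reproducible
and windows are independent when sequential seeding is off.

What the generator does *not* emulate: backbone BI/BII substates and their
couplings, sequence-specific correlations beyond the twist–roll/slide
defaults, bending anharmonicity, melting and writhe. Passing tests
demonstrate correctness of the analysis chain on a known ground truth, not
fidelity of any particular DNA sequence's mechanics.

## WHAM and elasticity

`wham()` is the standard self-consistent 1-D binned estimator with
log-space accumulation; defaults: 0.25° bins on the total-twist axis
(≈0.02°/bp after axis conversion), shift tolerance $10^{-7}$ kcal/mol,
$10^5$ iteration cap, zero-count bins masked, an explicit error naming the
first non-overlapping adjacent window pair. The output axis is
$(\mathrm{CV} - \text{relaxed mean})/n_{\text{steps}}$ with the relaxed
mean taken from the central window; these choices are declared, not
inferred from any published setting. No statistical-inefficiency weighting
is applied by default because the generator's frames are decorrelated by
construction.

`fit_force_constant()` performs plain least-squares quadratic regression
$F = K(\delta - c)^2 + c_0$ within ±2°/bp of the PMF minimum. The ±2 range
is read as *per bp step* (the PMF's axis); the fragment-total reading
would span less than one window and cannot support a fit. The centre is
fitted freely rather than pinned at zero and is reported, so a pinned
refit is a one-liner for anyone preferring that convention.

The rod-model conversion is
$$C = \frac{2 K_{\mathrm{rad}} L_{bp}}{n\, k_B T},$$
with $K_{\mathrm{rad}} = K (180/\pi)^2$, $L_{bp} = 0.34$ nm and
$k_B T(300\,\mathrm{K}) = 0.5962$ kcal/mol. For a chain of independent
steps this is algebraically identical to the fluctuation form
$C = L_{bp}/\mathrm{Var}(\theta_{\mathrm{step}})$ (in radians): the
fragment PMF of a sum of independent Gaussian twists has curvature
$K_{\mathrm{cv}} = k_BT/(2 n \sigma^2)$; converting to the per-bp axis
multiplies by $n^2$, and substituting into the formula above cancels
everything but $L_{bp}/\sigma_{\mathrm{rad}}^2$. `ground_truth_modulus()`
evaluates that identity from the exact (mixture) variance and is the
independent oracle for the full pipeline: per-step twist SD 3.171° gives
111 nm, 2.578° gives 168 nm, and the simulate→WHAM→fit→convert chain
recovers both within a few tenths of a percent at $2\times10^5$ frames per
window. The supercoiling conversion is twist-only,
$\sigma = \Delta\mathrm{tw}/\mathrm{tw}_0$, deliberately ignoring writhe.

## Deformation energy

The multi-substate evaluator scores a snapshot by Boltzmann-summing over
all substate chains with nearest-neighbour label couplings via a log-space
transfer matrix (a minimum-chain Viterbi variant is exposed with
`method = "min"`); summation is the default because coupling "between all
possible conformational substates" is most naturally a partition sum, and
both conventions are surfaced since published evaluators differ. Energies
are referenced to the lowest-energy substate chain at its harmonic
minimum, so a single-substate model scores exactly zero at its means;
between basins the Boltzmann-summed score can dip marginally below zero.
An exhaustive chain-enumeration oracle in the tests pins the transfer
matrix to $10^{-10}$ kcal/mol on chains of up to 8 steps and 3 substates.

The published tetranucleotide parameterizations of such models are *not*
bundled; `read_deformation_params()` accepts user-supplied JSON keyed by
dimer or tetranucleotide context, and a synthetic dimer-level set matching
the generator defaults ships in `extdata` for tests and examples (file and
docs are labelled synthetic). On the capacitor-bearing default model the
window-averaged deformation energy is nearly flat within ±2.5°/bp —
substate switching absorbs the stress almost freely, differences of order
0.02 kcal/mol — while the rise at ±4.5°/bp is clear; tests assert the
U-shape at this resolvable scale.

## Contacts

Hydrogen bonds: donor–acceptor heavy-atom distance ≤ 3.5 Å, plus a
donor–H–acceptor angle ≥ 120° whenever the donor carries hydrogens in the
structure (distance-only fallback otherwise, as heavy-atom-only
trajectories are common). Hydrophobic: C–C ≤ 4.5 Å. These cutoffs are
package conventions — the protocols this emulates defer to prior work
without printing values — and every one is overridable through
`contact_criteria()`. Moiety partition: base = ring + exocyclic atoms;
sugar = C1′–C5′, O4′; phosphate = P, OP1/OP2, O3′, O5′. A base-moiety
contact is "specific" (readout), sugar/phosphate "nonspecific".

## Numerical choices and degenerate inputs

* Angles are degrees at every interface; radians only inside rotation
  algebra and the final modulus conversion. $k_{tw}$ is consumed in
  deg$^{-2}$ as in the restraint definition.
* Coincident or antiparallel frame z axes short-circuit the hinge
  construction (the cross product, not the arc cosine, decides
  degeneracy).
* WHAM masks empty bins rather than interpolating; the fit requires at
  least five sampled bins in range and refuses concave regions.
* Ensembles persist as CSV plus JSON metadata; structures as multi-model
  PDB readable by standard tools.
* Problem sizes used by the shipped checks — $2\times10^5$ frames per
  window for the two modulus-recovery pipelines, $2\times10^4$ for
  distributional tests — were chosen so that Monte Carlo error sits well
  inside the asserted tolerances (the modulus pipelines land within ~0.5%
  of their 5% bands).

## Known limitations

The mid-frame convention differs systematically from curvilinear-axis
analyses in bent regions; groove widths are cross-strand P–P proxies, not
refined curvilinear measures; the generator's Gaussian-mixture caricature
omits the slow backbone degrees of freedom that dominate real twist
autocorrelation; the deformation evaluator's zero reference and summation
convention are choices, surfaced as flags; and the torsional modulus of a
short restrained fragment is a local quantity — nothing here addresses its
convergence with fragment length.
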