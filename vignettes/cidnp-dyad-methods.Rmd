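---
title: "Models and methods: photo-CIDNP kinetics, field-dependence classification and conformer geometry"
author: "cidnpdyad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cidnpdyad)
```

`cidnpdyad` analyses photo-CIDNP (photochemically induced dynamic nuclear
polarization) experiments on flavin–tryptophan (F–W) dyads joined by
oligoproline linkers, together with the geometric analysis of their conformer
ensembles and pulsed-field-gradient diffusion data. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The cyclic-photoreaction kinetic model

After a laser flash, triplet quenching creates flavin- and
tryptophan-centred radicals that disappear by second-order termination.
With $k = k_t R_0$ the pseudo-first-order termination rate, the radical
population follows the closed form

$$R(t)/R_0 = \frac{1}{1 + k t}.$$

Nuclear polarization is tracked in two pools: $P_R$, residing in radicals,
and $P$, accumulated in diamagnetic products:

$$\frac{dP_R}{dt} = -k_t P_R R - k_t \beta R^2 - \frac{P_R}{T_1},
\qquad
\frac{dP}{dt} = +k_t P_R R + k_t \beta R^2 .$$

The first term transfers radical-borne polarization into products upon
recombination. The $\beta$ term describes spin sorting in F-pair (random
encounter) recombination: each recombining pair deposits $+\beta$ in the
products while the surviving radicals acquire $-\beta$. $\beta$ is tied to
the geminate polarization by $\beta R_0 = \gamma P_G$; for a triplet
precursor $\gamma = 3$, and the default $\gamma = 2.8$ accounts for
incomplete reversibility of the photocycle. $T_1$ is the nuclear
*paramagnetic* relaxation time, which destroys polarization while it resides
in the radical.

Initial conditions are not uniquely dictated by the experiment; the package
default is $P(0) = +P_G$ (geminate polarization present in products at flash
end) and $P_R(0) = -P_G$ (the equal-and-opposite spin-sorted polarization
carried by escaped radicals). Both are overridable arguments of
`integrate_polarization()`.

Two exact limits anchor the implementation and its tests:

* **Fast relaxation** ($T_1 \to 0$): radical polarization dies before any
  recombination, so only the $\beta$ source survives. Since
  $\int_0^\infty k_t R^2 \, dt = R_0$, the product polarization tends to
  $(1 + \gamma) P_G$.
* **No relaxation** ($T_1 \to \infty$): $P + P_R$ is conserved and the
  coupled system solves in closed form,
  $P(t) = P_G (1 + \gamma \ln(1 + k t))/(1 + k t)$, which rises to an
  interior maximum and then decays to zero — every unit of sorted
  polarization eventually returns and cancels. CIDNP survives at long times
  only because $T_1$ is finite: relaxation removes the negative radical pool
  asymmetrically. This conserved closed form is used as an independent
  oracle for the integrator.

The detected signal at a programmed delay $\tau$ is
$\text{scale} \cdot P(\tau + \delta_p/2)$ where $\delta_p$ is the detection
RF-pulse duration: the pulse-centre point approximation, not a convolution
over the pulse window. Because $P$ is strictly proportional to $P_G$, only
the product $\text{scale} \cdot P_G$ is observable; fits therefore fix
$P_G = 1$ and estimate the scale, which being linear is profiled out
analytically.

Integration uses `deSolve`'s adaptive stiff-capable `lsoda` with defaults
`rtol = 1e-8`, `atol = 1e-12` (both exposed). The right-hand side is also
compiled (including a stacked multi-trace variant) so that joint fits cost
one solver call per residual evaluation; the pure-R right-hand side is
retained and tested against the compiled one.

## Fitting sparse kinetic traces

The experimental design for most dyads is three delays (0, 3, 100 µs) with a
4 µs pulse, i.e. effective times 2, 5, 102 µs. Free parameters per fit are
$k_t R_0$, $T_1$ and the scale; $\gamma$ stays fixed at 2.8. The loss is
unweighted least squares unless per-point uncertainties are supplied (then
inverse-variance weighted). Optimisation is Levenberg–Marquardt
(`minpack.lm`) on $\log k_t R_0$ and $\log T_1$ within positive bounds
(defaults $k_t R_0 \in [10^3, 10^8]$ s$^{-1}$, $T_1 \in [10^{-7}, 10^{-1}]$ s),
multi-started (default 8 starts: the log-space box centre plus seeded
log-uniform draws) because sparse traces have flat directions. Asymptotic
standard errors come from a forward-difference Jacobian at the optimum.

Two lessons from the identifiability analysis are built into the tooling:

* A **single 3-point trace determines $T_1$ poorly once $T_1$ exceeds the
  100 µs kinetic window** — `profile_identifiability()` shows an essentially
  flat residual profile over a tenfold $T_1$ range. For a relaxation time
  five times the window (500 µs), the least-squares estimator at the
  three-delay design is bimodal — an interior mode near 130 µs and a
  runaway mode at the bound — and its median converges roughly 50% above
  the truth: no replicate count fixes that. Such a value is only
  identifiable from a dense design; the ten-delay (0–100 µs, 2 µs pulse)
  protocol recovers it with median error under 10%. The recovery studies in
  `scripts/acceptance.R` therefore refit each dyad at the design its data
  were actually acquired with: ten delays for the short-linker butylated
  dyad whose dense measurement anchors the 500 µs group value, three delays
  elsewhere.
* The study's own analysis treats the termination rate as common to all
  protons of a dyad. The package reproduces this as a **global fit**: shared
  `kt_R0`, per-trace $T_1$ and scale (`kinetic_fit_spec(shared = "kt_R0")`;
  partial sharing via `share_groups`). Pooling the dyad's two tryptophan
  traces and the flavin trace markedly stabilises all estimates. Each
  replicate reports the geometric mean of the two W-proton $T_1$ fits (the
  published W value is one number for the pair; averaging in log space
  roughly halves the spread and outperforms tying $T_1$ across the pair
  inside the fit). Replicate counts (700–1200 per dyad) are set from the
  measured spread of each median so its sampling error sits at a few
  percent; per-fit multi-start is reduced to 2 there (the centre start finds
  the 8-start optimum in ≥95% of replicates, and the median is insensitive
  to the remainder), keeping the whole recovery run in minutes on one CPU.

## Sign rules, level anticrossing and the field-regime taxonomy

Polarization signs follow the radical-pair sign rules. In the high-field
$\Delta g$-dominated regime
$\Gamma = \mathrm{sgn}(\Delta g)\,\mathrm{sgn}(a)\,\mu\,\varepsilon$
(nucleus-specific through $\mathrm{sgn}(a)$), while at the exchange-dominated
level anticrossing $\Gamma = \mathrm{sgn}(J_\mathrm{ex})\,\mu\,\varepsilon$,
independent of the hyperfine sign — every nucleus of a biradical acquires
the same sign. Here $\mu = \pm 1$ for triplet/singlet precursor and
$\varepsilon = \pm 1$ for geminate/escape products. The level-anticrossing
condition is $B_\mathrm{LAC} \approx |J_\mathrm{ex}| / (g \mu_B)$, with
frequency-unit input converted through Planck's constant
(`lac_field(280.2e6, unit = "Hz")` ≈ 10 mT) and `j_from_field()` its exact
inverse.

`classify_field_regime()` quantifies the verbal comparisons: "comparable"
($\sim$) means within a factor 3, "much greater" ($\gg$) at least a factor
10, and the $\Delta g$ regime additionally requires $B \ge 1$ T; fields
between the exchange band and 1 T map to `GAP`, matching the observation
that neither mechanism is effective between roughly 0.1 and 1 T. All three
constants are arguments.

## The mechanism classifier

`classify_mechanism()` applies the biradical criteria to a set of per-proton
field profiles: (i) one polarization sign for all significant nuclei,
(ii) an interior extremum of $|I|$ inside the J-resonance window (default
5–20 mT, where the compact cis-containing conformers' anticrossing falls),
(iii) weak **or absent** high-field response. All three give `J_BIRADICAL`;
significant mixed-sign response at $B \ge 1$ T without a coherent mid-field
extremum gives `DG_INTERMOLECULAR`; mixed signs confined below the hyperfine
field scale (default 4 mT) give `LOWFIELD_HFC`; otherwise `NONE`.

Numerical choices that matter:

* **Noise floor.** Each profile's noise σ is estimated robustly from its
  own grid: the smaller of a low quantile (0.30) of absolute first
  differences and the median of absolute second differences, each calibrated
  for Gaussian noise, floored at half the profile MAD. Tail-based estimators
  fail here because a 5 mT peak's shoulder contaminates the low-field tail
  of a 30-point logarithmic grid, and first differences alone are inflated
  by a sigmoidal onset. Features "present" must exceed 5σ; protons enter
  the sign-uniformity count above 3σ.
* **Window membership** of the detected extremum is tested with a one-grid-
  step tolerance in $\log_{10} B$ (the grid step, 0.137 dex, is the field
  resolution of the design).
* **Criterion (iii)** passes outright when no significant high-field signal
  exists; when one exists, the mid-field extremum must exceed it threefold
  (`highfield_ratio`). A pure ratio test against the maximum of ~32
  high-field noise samples would reject several percent of genuine
  J-biradical sets at signal-to-noise 10.
* **Set-level evidence** always requires at least two profiles, including
  the veto of `DG_INTERMOLECULAR` by a mid-field extremum.

With these defaults the classifier labels seeded synthetic sets at
signal-to-noise 10 without error (0/1600 in the package's validation runs;
the test suite asserts 200/200).

`normalize_profiles()` implements the concentration-series convention of
dividing each profile by the magnitude of its (log-field-interpolated)
intensity at a reference field, default the J-dominated 10 mT feature; the
operation is idempotent and scale-invariant.

## Conformer-ensemble geometry

Frames carry index masks for the flavin ring system and the tryptophan
indole, donor quadruples (N, H, O, C) for candidate hydrogen bonds, and one
atom quadruple per proline defining the peptide-bond dihedral ω.

* **cis/trans**: a bond is cis iff $|\omega| < 90°$; the boundary goes to
  trans (symmetric cut, far from both basins at ~0° and ~180°). Labels are
  strings like `"CTT"`, position 1 nearest the flavin.
* **Centres and planes**: moiety centres are unweighted centroids of the
  masks; plane normals come from total least squares (smallest principal
  direction of the centred mask coordinates); the inter-plane angle is
  folded to [0°, 180°] and the stacking rule treats θ and 180° − θ
  symmetrically.
* **π-stacking**: centre distance within [3.0, 6.5] Å (inclusive) and
  θ < 45° or θ > 135° (strict, per the wording "smaller than"/"greater
  than").
* **Hydrogen bond**: H···O < 3.0 Å and both N–H···O and H···O–C angles
  > 130° (strict).
* **Distributions**: per-label histograms use Freedman–Diaconis bins on a
  break set common to all labels, so the pooled "Sum" distribution is
  exactly the label-population-weighted mixture of the per-label densities.

`per_atom_energy_difference()` normalises a conformer-energy gap by the atom
count (e.g. 26 kcal/mol over 108 atoms ≈ 0.24 kcal/mol per atom), the scale
on which coexistence of all proline configurations is judged.

## Diffusion

`stejskal_tanner_fit()` fits the monoexponential attenuation
$I(g) = I_0 \exp\!\big(-D \gamma^2 g^2 \delta^2 (\Delta - \delta/3)\big)$
by Levenberg–Marquardt started from the log-linear regression, with
gradients accepted in T/m or G/cm. `compare_species()` forms
$D_\text{minor}/D_\text{major}$ with first-order error propagation; a ratio
above one flags the first species as more compact, the DOSY argument for the
cis-containing minor conformer.

## What the synthetic generator emulates — and what it does not

`gen_kinetic_trace()` evaluates the kinetic model at either experimental
design (three delays/4 µs pulse, or ten delays/2 µs pulse) and adds Gaussian
noise, default 5% relative — the level used throughout validation.
`gen_field_profiles()` draws the J-resonance peak log-uniformly in the
observed 5–20 mT window as a log-normal line of width 0.25 dex, the
$\Delta g$ onset as a sigmoid centred at 2 T, and low-field hyperfine
signatures as signed peaks at 1.2–3 mT, on the experimental 30-point
logarithmic grid from 1 mT to 9.4 T; per-proton amplitudes are mildly
log-normal and the per-proton signal-to-noise is the `snr` argument
(default 10). These line shapes are modelling inventions for classifier
validation — the study provides no functional forms — and are labelled as
such in the truth metadata. `gen_conformer_ensemble()` builds surrogate
planar six-ring moieties with an in-plane carbonyl acceptor and N–H donor
and places them so each frame satisfies exactly one class — stacked
(d ∈ band, near-parallel, verified not hydrogen-bonded), hydrogen-bonded
(linear N–H···O at 1.9 Å, 150° at the acceptor, centre distance ~8 Å so
never stacked), or extended (9–14 Å) — with ω angles drawn near 0°/180° per
the requested label distribution; default motif fractions are the reported
MD-scale figures, 20% stacked and 5% hydrogen-bonded.
`gen_diffusion_decay()` uses the experimental gradient design (16 linear
steps over 2–95% of 50 G/cm, Δ = 50 ms, δ = 2 ms) with 1% relative noise.

Passing tests on these synthetics therefore demonstrate correctness of the
*operators* (model evaluation, fitting, classification, geometry counting)
under known ground truth. They do not demonstrate robustness to features of
real data the generator omits: baseline and phase artefacts, conformer
cross-talk from overlapping NMR lines, force-field-realistic ring
geometries, exchange between conformers, or aggregation.

All generators draw from private seeded streams (the global RNG state is
saved and restored), so identical arguments and seed give bit-identical
output and no call perturbs the caller's reproducibility.

## Known limitations

* The kinetic model omits the triplet-quenching step itself,
  diffusion-controlled rate theory and relaxation in diamagnetic products;
  absolute radical concentrations enter only through $k_t R_0$.
* No quantum spin-Hamiltonian dynamics: field profiles are classified by
  algebraic rules and robust features, not simulated amplitudes.
* The problem sizes used by the validation suite (400–1200 simulate-and-
  refit replicates per dyad, 200 classifier sets, ensembles of 1000–5000
  frames) were chosen so every stochastic assertion has comfortable
  statistical margin; they are analysis choices, not physical statements.
* Coordinate input is limited to multi-frame XYZ and PDB `MODEL` blocks;
  trajectory binary formats are out of scope.
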