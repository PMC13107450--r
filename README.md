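# cidnpdyad

Analysis toolkit for photo-CIDNP (photochemically induced dynamic nuclear
polarization) studies of flavin–tryptophan (F–W) dyads linked by
oligoproline chains, for spin-chemistry and structural-NMR groups working
with time-resolved and field-cycling CIDNP, MD conformer ensembles, and
pulsed-field-gradient (DOSY) diffusion data.

Such dyads are conformationally heterogeneous: slow cis/trans isomerization
of the peptidyl–prolyl amide bonds leaves a static mixture of extended
(all-trans, PPII-like) and compact cis-containing conformers in solution.
The package implements the quantitative machinery needed to tell how each
subpopulation generates nuclear polarization:

* **Cyclic-photoreaction kinetics** (time-resolved CIDNP). Radicals created
  by triplet quenching decay by second-order termination,
  R(t) = R₀/(1 + k_t R₀ t), while nuclear polarization in radicals (P_R) and
  products (P) obeys

      dP_R/dt = −k_t P_R R − k_t β R² − P_R/T₁
      dP/dt   = +k_t P_R R + k_t β R²

  with spin sorting in F-pair encounters (β R₀ = γ P_G, default γ = 2.8)
  and nuclear paramagnetic relaxation T₁. `fit_kinetics()` recovers
  k_t R₀, T₁ and the detector scale from sparse delay designs, including
  global fits with parameters shared across a dyad's protons;
  `profile_identifiability()` exposes which parameters the design actually
  constrains.
* **Radical-pair sign rules and level anticrossing** (field-cycling CIDNP).
  Γ = sgn(Δg)·sgn(a)·μ·ε at high field, Γ = sgn(J_ex)·μ·ε at the
  exchange-dominated level anticrossing, B_LAC ≈ |J_ex|/(g μ_B).
  `classify_mechanism()` turns a set of per-proton field profiles into a
  verdict — `J_BIRADICAL` (uniform sign, mid-field maximum, weak/absent
  high-field response), `DG_INTERMOLECULAR`, `LOWFIELD_HFC` or `NONE` —
  with the evidence attached.
* **Conformer-ensemble geometry.** Cis/trans labelling from ω dihedrals
  (|ω| < 90° = cis), F–W centroid distances and total-least-squares
  inter-plane angles, π-stacking (3–6.5 Å, θ < 45° or > 135°) and
  hydrogen-bond (H···O < 3 Å, both angles > 130°) classification, and
  per-label conditional probabilities with pooled distributions.
* **Stejskal–Tanner diffusion fits** for the DOSY compactness argument.
* **A seeded synthetic-data generator** for every input above, with ground
  truth attached, so the whole pipeline is testable end to end.

## Worked example

Simulate one dyad's three kinetic traces (two tryptophan protons with
T₁ = 150 µs, the flavin methyl with T₁ = 27 µs, k_t R₀ = 10⁵ s⁻¹) at the
experimental three-delay design and refit them globally:

```r
library(cidnpdyad)
pulse <- pulse_timing(4e-6)                       # effective offset 2 us
truth_w <- kinetic_parameters(kt_R0 = 1e5, T1 = 150e-6)
truth_f <- kinetic_parameters(kt_R0 = 1e5, T1 = 27e-6)
traces <- list(
  gen_kinetic_trace(truth_w, seed = 1, proton_label = "W6"),
  gen_kinetic_trace(truth_w, seed = 2, proton_label = "W2"),
  gen_kinetic_trace(truth_f, seed = 3, proton_label = "F8p"))
fit_kinetics(traces, pulse, kinetic_fit_spec(shared = "kt_R0", seed = 1))
#> Kinetic fit: 9 points, 7 free parameters, RSS = 0.004455
#>     trace parameter      value   stderr
#>  (shared)     kt_R0 8.3055e+04 2.57e+05
#>        W6        T1 2.8109e-04 2.89e-03
#>        W2        T1 1.5674e-04 1.05e-03
#>       F8p        T1 2.9535e-05 1.09e-04
#>        W6     scale 1.0164e+00 4.24e-01
#>        W2     scale 1.0092e+00 4.25e-01
#>       F8p     scale 9.9654e-01 4.71e-01
```

One noisy replicate scatters around the truth (the termination rate within
~17%, the flavin T₁ within ~9% here), and the asymptotic standard errors
honestly report how weakly a three-delay design constrains a relaxation
time longer than the 102 µs window — which is why recovery studies report
medians over many replicates.

Classify a minor-conformer field-profile set and check where the level
anticrossing sits for an exchange interaction of 280.2 MHz:

```r
prof <- gen_field_profiles("J_BIRADICAL", peak_field = 13e-3, snr = 10,
                           seed = 7, conformer_class = "minor")
classify_mechanism(prof)
#> Mechanism call: J_BIRADICAL
#>   peak field      : 0.0125 T
#>   sign uniformity : 1.00
#>   high-field ratio: 8.87
#>   evidence        : uniform sign (uniformity 1.00), mid-field extremum
#>                     at 0.0125 T, high-field response 8.87 x weaker
lac_field(280.2e6, unit = "Hz") * 1e3
#> [1] 10.00  # mT
```

The 13 mT truth peak is located to the nearest grid point (12.5 mT) of the
30-point logarithmic field grid, all protons are emissive, and the
high-field response is ~9× weaker — the three biradical criteria.

Count structural motifs in a synthetic conformer ensemble generated with
20% stacked and 5% hydrogen-bonded frames:

```r
ens <- gen_conformer_ensemble(2000, stacked_fraction = 0.20,
                              hbond_fraction = 0.05, seed = 3)
ensemble_statistics(ens)
#> Ensemble statistics over 2000 frames
#>  label   n weight p_stacked p_hbond
#>    CCC 230 0.1150    0.1696  0.0522
#>    ...
#> Pooled: P(stacked) = 0.1940, P(hbond) = 0.0465
```

And fit a pulsed-field-gradient decay on the experimental gradient design:

```r
stejskal_tanner_fit(gen_diffusion_decay(D = 5e-10, seed = 5))
#> Stejskal-Tanner fit: D = 5.017e-10 +/- 4.4e-12 m^2/s, I0 = 1, RSS = 0.000752
```

`run_pipeline(pipeline_config(seed = 1))` chains all four stages
(synthesize → fit → classify → geometry → diffusion) into one JSON-able
report.

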