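# triadspin

Spin-dynamics simulation of magnetic field effects on radical reaction
yields in a **radical triad**: a flavin semiquinone (FH•), superoxide
(O₂•⁻) and a scavenger radical (the ascorbyl radical A•⁻). The package is
aimed at spin chemists and quantum biologists studying how hypomagnetic
field (HMF) exposure — the near-absence of the geomagnetic field (GMF) —
could reduce cellular superoxide levels via the radical pair mechanism,
even though free superoxide relaxes far too fast to be magnetosensitive
on its own.

## The model

Superoxide's electron spin is assumed to relax instantaneously, so it is
traced out of the three-radical quantum master equation exactly. What
remains is a two-radical equation of motion for the FH•/A•⁻ density
operator σ̂(t) on their joint electron–nuclear spin space:

    dσ̂/dt = −i[Ĥ′, σ̂] − (k_X/2){P̂⁽ˢ⁾, σ̂} − k_Σ σ̂ + R̂′σ̂ ,    σ̂(0) = Ê/Tr(Ê)

* Ĥ′: Zeeman (ω = gμ_B B/ħ) plus hyperfine (Ŝ·A·Î) terms of the two
  surviving radicals; free radicals keep only isotropic couplings,
  protein-bound flavin keeps full tensors with orientation averaging.
* k_X: spin-selective (Haberkorn, singlet-channel) scavenging of FH• by
  A•⁻.
* k_Σ = k_E + k_E′ + k_F/4 + k_X′/4: composite depopulation by escape and
  by the reactions of the traced-out superoxide.
* R̂′: optional random-field relaxation (T₁ = T₂ = 1/γ) per electron.

Observables: the singlet scavenging yield Φ_X = k_X ∫ Tr(P̂⁽ˢ⁾σ̂) dt, the
superoxide escape yield Y = (1−φ)Φ_X + φ, and the field-effect ratio
χ(B) = Y(B)/Y(GMF) with GMF = 55.26 µT and HMF = 0.29 µT. A small-system
solver for the *full* three-radical model verifies the partial-trace
reduction numerically.

## Worked example

```r
library(triadspin)

model <- reduced_pair_model("flavin_3N", "ascorbyl_H4",
                            rate_set(k_X = 1, k_Sigma = 0.1))
model$space$dim
#> [1] 144

# superoxide escape yield in the geomagnetic field
superoxide_yield(scavenging_yield(model, GMF_uT), phi = 0)
#> [1] 0.6777058

# hypomagnetic field effect for this rate pair
chi <- mfe_ratio(model, HMF_uT, GMF_uT)
attr(chi, "effect_pct")
#> [1] -9.264606

# MARY curve around the geomagnetic condition
field_sweep(model, c(0, 0.29, 1, 10, 55.26))
#> # A tibble: 5 × 6
#>    B_uT phi_X     Y   chi effect_pct orientation_policy
#>   <dbl> <dbl> <dbl> <dbl>      <dbl> <chr>
#> 1  0    0.614 0.614 0.907     -9.34  single
#> 2  0.29 0.615 0.615 0.907     -9.26  single
#> 3  1    0.619 0.619 0.913     -8.67  single
#> 4 10    0.663 0.663 0.978     -2.15  single
#> 5 55.3  0.678 0.678 1          0     single
```

The yield *rises* toward the GMF and falls as the field is removed
(negative effect percentages): the model predicts reduced superoxide
release under hypomagnetic conditions, the sign observed in HMF exposure
experiments. The recovery is steep in the first tens of µT (−9.3% at
zero field, −2.2% already at 10 µT): the low-field effect that makes this
system sensitive to µT-scale field changes.

Rate maps over (k_X, k_Σ) and the inverse problem ("what field gives a 1%
effect?") follow the same pattern:

```r
map <- rate_map(model)          # defaults: HMF vs GMF, log grids
max_mfe(map)                    # most negative effect and where it occurs
autoplot(map)

field_for_effect(reduced_pair_model("flavin_3N", "ascorbyl_H4",
                                    rate_set(k_X = 10, k_Sigma = 1)),
                 target_effect = 1, B_ref = 0, bracket = c(1, 40))
#> [1] 12.01399
```

A thin CLI over the same functions lives at `inst/scripts/triadspin.R`
(`sweep|map|mfe|validate`, YAML/JSON configs; see `?load_config`).

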