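---
title: "The reduced radical-triad model of hypomagnetic field effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The reduced radical-triad model of hypomagnetic field effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadspin)
```

## The physical problem

Weak magnetic fields — including the *absence* of the geomagnetic field
(GMF, here 55.26 µT) in so-called hypomagnetic field (HMF, 0.29 µT)
exposure — can alter the yields of radical recombination reactions through
the radical pair mechanism: coherent singlet–triplet interconversion of
two unpaired electron spins, driven by hyperfine and Zeeman interactions,
competes with spin-selective chemistry. A flavin-semiquinone/superoxide
pair (FH•/O₂•⁻) is an attractive candidate for linking this physics to
reactive-oxygen-species (ROS) levels in cells, but it suffers from two
well-known objections: the pair is triplet-born (molecular oxygen is a
ground-state triplet), which predicts the wrong sign of the effect, and
free superoxide relaxes on nanosecond timescales, which abolishes
low-field magnetosensitivity altogether.

The model implemented here escapes both objections with a **radical
triad**: FH• (radical 1), O₂•⁻ (radical 2) and a scavenger radical —
the ascorbyl radical A•⁻ (radical 3) — that removes FH• through a
spin-selective (singlet-channel) reaction with rate constant $k_X$. If
the superoxide spin relaxes infinitely fast, it can be traced out of the
three-spin master equation exactly, leaving a two-radical problem for
$\hat\sigma(t)$ on the (1,3) spin space:

$$
\frac{d\hat\sigma}{dt} = -i[\hat H', \hat\sigma]
 - \frac{k_X}{2}\{\hat P^{(S)}_{1,3}, \hat\sigma\}
 - k_\Sigma \hat\sigma + \hat{\hat R}'\hat\sigma ,
\qquad
\hat\sigma(0) = \frac{\hat E}{\mathrm{Tr}\,\hat E},
$$

with the composite depopulation rate
$k_\Sigma = k_E + k_E' + k_F/4 + k_{X'}/4$. The factors 1/4 are the
fingerprint of the traced-out superoxide: its pairings with the other
radicals are in effectively random spin states, of which one quarter is
singlet. Because the initial state is maximally mixed regardless of
whether the primary FH•/O₂•⁻ pair was born triplet, singlet or as an
F-pair, the predictions are independent of that contested assumption —
the package asserts this bit-for-bit in its tests.

The observable is the singlet scavenging quantum yield
$\Phi_X = k_X \int_0^\infty \mathrm{Tr}\left(\hat P^{(S)}_{1,3}
\hat\sigma(t)\right) dt$, the superoxide escape yield
$Y = (1-\varphi)\Phi_X + \varphi$, and the field-effect ratio
$\chi(B) = Y(B)/Y(\mathrm{GMF})$, reported as a signed percentage
$100(\chi - 1)$.

## Spin systems and parameters

Each `radical()` carries a g-factor (default 2.0023 for both electrons;
µT-scale g differences are negligible), a mobility flag and a list of
nuclei with 3×3 hyperfine tensors in MHz. Tensors are interpreted in a
common molecular frame; orientation dependence is implemented by rotating
the *field*, not the tensors, which is equivalent and cheaper. For a
`free` (rotationally averaged) radical only the isotropic part
$a_\mathrm{iso} = \mathrm{Tr}(\mathbf{A})/3$ enters the Hamiltonian; a
`bound` radical retains the full tensor and its yields are averaged over
field directions (deterministic Fibonacci sphere, default 72 nodes;
convergence is asserted by doubling in the tests).

The built-in presets encode the magnetically dominant nuclei:

* `flavin_3N` — the flavin semiquinone with N5, N10 (¹⁴N, strongly axial
  tensors) and the H5 proton. The tensors are the standard DFT/ENDOR
  values for the *neutral* flavin semiquinone used throughout the
  radical-pair magnetosensitivity literature
  ($a_\mathrm{iso}$(N5) ≈ 0.53 mT, $a_\mathrm{iso}$(N10) ≈ 0.33 mT,
  $a_\mathrm{iso}$(H5) ≈ −0.52 mT, with the usual axial nitrogen
  anisotropy). Reported coupling sets for flavin radicals vary at the
  ten-percent level between studies, and the headline percentages below
  are sensitive to that variation at the level of roughly one percentage
  point; see "Sensitivity" below.
* `flavin_5N` — adds H6 and Hβ1. Enlarging the spin system leaves the
  qualitative picture unchanged, which the literature reports and the
  package reproduces.
* `ascorbyl_H4` — a single isotropic proton with
  $a_\mathrm{iso} = 4.94$ MHz. The uniquely small hyperfine interaction
  of the ascorbyl radical opposite the hyperfine-rich flavin (a
  "reference–probe" topology) is what makes the pair unusually sensitive
  at low fields.
* `superoxide` — no magnetic nuclei (¹⁶O); ¹⁷O isotopologues are
  neglected at natural abundance.

Units: fields in µT, rates in µs⁻¹, time in µs; Hamiltonians in rad µs⁻¹.
Hyperfine couplings are supplied in MHz (linear frequency) and multiplied
by 2π internally. `larmor_frequency_MHz(50)` returns 1.4 MHz, the
precession frequency that sets the ~0.7 µs coherence time needed for
geomagnetic-scale sensitivity.

## Solvers

Two independent routes compute $\Phi_X$:

* **Algebraic (default).** Without relaxation the dynamics are generated
  by the non-Hermitian effective Hamiltonian
  $\hat A = \hat H' - i(k_X/2)\hat P^{(S)}$, and the yield integral has a
  closed form in its eigenbasis with denominators
  $k_\Sigma + i(\lambda_j - \bar\lambda_k)$. Because $k_\Sigma$ enters
  only as a uniform shift, one eigendecomposition serves an entire
  $k_\Sigma$ grid axis — this is what makes the (k_X, k_Σ) rate maps
  cheap. Decoupled stationary modes (zero numerator and zero denominator)
  are excluded explicitly. With relaxation ($\gamma > 0$) the package
  instead solves the stationary Liouville-space linear problem
  $\mathcal{L}\,\mathrm{vec}(X) = -\mathrm{vec}(\sigma_0)$ with a sparse
  real-block representation.
* **ODE oracle.** Adaptive time integration (deSolve/lsoda) of the master
  equation with the yield integrals carried as auxiliary states, horizon
  $20/(k_X/4 + k_\Sigma)$ extended until the residual trace — an upper
  bound on the truncated yield contribution — falls below $10^{-7}$.

The tests require the two routes to agree to $10^{-6}$ on randomized
small models, and every evaluation to satisfy the exit-probability ledger
$\Phi_X + k_\Sigma \int \mathrm{Tr}\,\hat\sigma\,dt = 1$ to $10^{-6}$.

Random-field relaxation is a Lindblad dissipator with jump operators
$\sqrt{\gamma} S_{x,y,z}$ per electron, normalized so that longitudinal
and transverse relaxation rates both equal $\gamma$ (T₁ = T₂ = 1/γ). The
exact Lindblad prefactor is a stated convention of this implementation;
the single-parameter isotropic choice is documented rather than asserted
against external numbers. Relaxation is applied to electron spins only.

## Verifying the partial-trace reduction

The `triad_system()` module solves the *full* three-radical model (dense
Liouville-space resolvent in the eigenbasis, with trapped stationary
subspaces excluded — they carry no reaction flux; or time integration)
for desk-scale spin systems (Hilbert dimension capped at 512, in practice
electrons-only or one nucleus). `reduction_convergence()` shows
$|\Phi_X^\mathrm{full}(\gamma_2) - \Phi_X^\mathrm{reduced}|$ falling
monotonically below $10^{-2}$ as the superoxide relaxation rate
$\gamma_2$ climbs to $10^3$ µs⁻¹, which is the numerical demonstration
that the $k_F/4$ and $k_{X'}/4$ terms of $k_\Sigma$ emerge in the
fast-relaxation limit. With $\gamma_2 = 0$ the reduction fails and
singlet- versus triplet-born initial conditions give visibly different
yields (the negative control). The escape channels are treated as
spin-independent (identity terms in the Haberkorn operator); any spin
selectivity of escape is outside the model.

```{r, eval = FALSE}
sys <- triad_system("superoxide", "superoxide", "superoxide",
                    k_F = 1, k_X = 1)
reduction_convergence(sys, field_vector(55.26),
                      gamma2_ladder = c(10, 100, 1000))
```

## Numerical choices

* $\varphi$ defaults to 0 (efficient oxidation: superoxide is released
  only by productive scavenging of FH•). It is an independent input, not
  derived from the component rates, because which of the $k_\Sigma$
  processes release superoxide depends on chemistry the spin model does
  not resolve.
* Rate maps default to log grids $k_X \in [10^{-2}, 10^3]$,
  $k_\Sigma \in [10^{-2}, 10^2]$ µs⁻¹ at 10 points per decade — wide
  enough to contain both sensitivity branches (moderate scavenging with
  $k_X \sim 10 k_\Sigma$, and fast scavenging with long lifetimes). The
  orientation-averaged (bound-flavin) map uses 5 points per decade and 72
  directions; at these sizes the free map takes seconds and the bound map
  a few minutes on one CPU.
* "Maximal effect" means the most negative signed percentage; argmin ties
  break to the lexicographically smallest $(k_X, k_\Sigma)$ (arbitrary,
  documented).
* The inverse problem (`field_for_effect()`) validates monotonicity of
  the effect magnitude across its bracket by sampling, then uses
  bracketed root finding to ~1% relative tolerance.
* Degenerate inputs: $k_X = k_\Sigma = 0$ raises a divergence error;
  $k_X = 0$ returns $\Phi_X = 0$; zero-magnitude fields are valid and the
  $B \to 0$ limit is continuous (asserted).

## What the toy systems do and do not show

The test fixtures are built in code: a zero-nucleus pair (exact closed
form $\Phi_X = \tfrac14 k_X/(k_X + k_\Sigma)$, the no-mixing limit), a
one-proton pair solved by the ODE oracle, and electrons-only triads.
They exercise every code path at machine-checkable precision, but they
are *not* miniatures of flavin chemistry: real flavin radicals carry a
dozen further weakly coupled nuclei, exchange and dipolar couplings are
neglected by model assumption (at least one member of each pair is
mobile), nuclear Zeeman terms are negligible at µT fields, and relaxation
in FH• and A•⁻ is ignored in headline runs (available via `gamma1`,
`gamma3` for sensitivity studies). Passing tests demonstrate fidelity to
the stated model, not validity of the model for any particular cell.

## Sensitivity of the headline numbers

The qualitative structure of the predictions is robust: every rate-map
entry of the free-flavin HMF/GMF comparison lies at or below unity, the
low-field response is anti-phase to the high-field (>10 mT) response,
~12 µT are needed for a 1% effect at $(k_X, k_\Sigma) = (10, 1)$ µs⁻¹,
and 1 µT suffices for an effect of order 1% at $(1, 0.1)$ µs⁻¹. The
headline *magnitudes* (free-flavin map minimum ≈ −9.5% with the default
tensor set; bound ≈ −8.9%; GMF yield level ≈ 0.68 for the example rate
pairs) shift by up to about a percentage point when the flavin couplings
are varied within their literature spread, with the orientation-averaged
(bound-flavin) results the most sensitive because they depend on the
anisotropic tensor components. The GMF yield level, by contrast, is
nearly invariant (0.65–0.69 across anion/neutral coupling sets, three to
five flavin nuclei, bound or free). `scripts/acceptance.R` recomputes
and reports exactly what the package produces under its default presets.
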