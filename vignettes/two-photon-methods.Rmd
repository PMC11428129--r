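---
title: "Two-photon absorption of retinal chromophore models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-photon absorption of retinal chromophore models: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpsb2pa)
library(dplyr)
```

## The problem

Rhodopsin's chromophore, the retinal protonated Schiff base (RPSB), is a
quasi-linear polyene with strong charge-transfer character in its lowest
singlet excitation: the S0 → S1 transition moves charge along the conjugated
chain, so the permanent dipole moment changes substantially on excitation.
That combination — a large transition dipole $\mu_{01}$ and a large dipole
change $\Delta\mu = \mu_{11} - \mu_{00}$ (a *vector* difference) — is exactly
what makes a molecule bright in two-photon absorption (2PA). This package
implements the analysis layer for studying how chemical edits (methylation
pattern, backbone twist) and the choice of electronic-structure method move
the 2PA response of five-double-bond RPSB models (RPSB5): few-state
sum-over-states (SOS) construction of the two-photon transition moment,
rotational averaging, microscopic-to-macroscopic conversion, the two-state
model, and a method-benchmarking layer. The electronic-structure numbers
themselves (coupled-cluster and TD-DFT response calculations) are inputs,
consumed from the packaged table or from user-supplied files in the same
schema — the package never recomputes them.

## The microscopic quantity and its rotational average

For a degenerate two-photon $|0\rangle \to |f\rangle$ transition at photon
energy $\omega = \omega_f/2$, the second-order transition moment is built by
summation over intermediate states:

$$S_{\alpha\beta}^{f\leftarrow 0}
 = \sum_n \frac{\langle f|\bar\mu_\alpha|n\rangle\langle n|\bar\mu_\beta|0\rangle
        + \langle f|\bar\mu_\beta|n\rangle\langle n|\bar\mu_\alpha|0\rangle}
        {\omega_n - \omega_f/2}$$

Two conventions in `sos_moment()` deserve note:

* **Fluctuation dipoles.** The dipole operators enter with the ground-state
  expectation subtracted ($\bar\mu = \mu - \langle 0|\mu|0\rangle$). This
  makes the $n = 0$ term vanish, renders the tensor independent of the
  coordinate origin (tested by shifting every diagonal dipole by a constant
  vector), and is what makes the familiar two-state model emerge as the
  two-state truncation. Without the subtraction both properties fail.
* **Real wavefunctions.** The dipole matrix is required to be symmetric, so
  the few-state engine is Hermitian and `left = t(right)` by construction.
  Genuinely non-Hermitian left/right pairs — the situation in
  coupled-cluster response, where the asymmetry is a property of the
  response solver and not reconstructible from a dipole matrix — are
  exercised through `tpa_tensor()` directly and through synthetic
  perturbations in the tests.

The rotationally averaged strength for two identical photons with parallel
linear polarisation is the isotropic fourth-rank average

$$\delta^{\mathrm{2PA}} = \tfrac{1}{15}\Big(
   \mathrm{Tr}\,S^L\,\mathrm{Tr}\,S^R
 + \textstyle\sum_{\alpha\beta} S^L_{\alpha\beta} S^R_{\alpha\beta}
 + \sum_{\alpha\beta} S^L_{\alpha\beta} S^R_{\beta\alpha}\Big),$$

implemented in `average_hermitian()` / `average_nonhermitian()` (the two
coincide exactly when `left = t(right)`; the Hermitian route refuses
asymmetric input beyond a relative Frobenius asymmetry of $10^{-8}$ and
redirects the caller). `average_numerical()` keeps an independent Monte-Carlo
check alive: it rotates the tensor by quaternion-uniform random rotations and
averages $(\mathbf{e}\cdot S^L\mathbf{e})(\mathbf{e}\cdot S^R\mathbf{e})$
directly; the closed form must sit within three standard errors of the
estimate. Negative averages, possible for pathological non-Hermitian pairs,
are returned unclipped with a warning — clipping would hide the pathology.

## The two-state model

Truncating the SOS to the ground and final state gives, for parallel
linearly polarised degenerate photons,

$$\delta^{\mathrm{2PA}}_{\mathrm{2S}}
  = \frac{16\,|\mu_{01}|^2|\Delta\mu|^2\,(1 + 2\cos^2\theta)}{15\,\omega_f^2},$$

with $\theta$ the angle between $\mu_{01}$ and $\Delta\mu$. The angle factor
is derived once by specialising the averaging convention above to the
rank-one-pair tensor $S_{\alpha\beta} = 2(\Delta\mu_\alpha\mu_{01,\beta} +
\Delta\mu_\beta\mu_{01,\alpha})/\omega_f$ and frozen in
`two_state_delta()`; exact equality with `sos_delta()` on any two-state
manifold is the defining contract and is tested to floating-point tolerance.
For the quasi-linear RPSB5 chromophores $\mu_{01}$ and $\Delta\mu$ are nearly
collinear, so the collinear form $|\mu_{01}|^2|\Delta\mu|^2/(\Delta E/2)^2$
built from tabulated *magnitudes* is an excellent predictor:

```{r}
tab <- builtin_table1()
build_report(tab)$correlations
```

The collinearity assumption in `two_state_correlation()` is an assumption —
the table stores only magnitudes, not orientations — but the correlation
above (≥ 0.999 in every method block) shows it is the operative regime.

## Microscopic to macroscopic conversion

`cross_section()` converts a strength $\delta$ (au) and excitation energy
$\Delta E$ (eV) to the peak cross section in GM
($1\,\mathrm{GM} = 10^{-50}\,\mathrm{cm^4\,s/photon}$):

$$\sigma^{\mathrm{2PA}} = N\pi^3\alpha^2\,\omega^2\,g_{\mathrm{peak}}\,
  \delta \times \frac{a_0^4 t_{\mathrm{au}}}{10^{-50}},
  \qquad \omega = \Delta E/2,$$

with everything inside the first product in atomic units. Conventions:

* **Photon energy** is always $\Delta E/2$ (degenerate photons), and the
  reported $\sigma$ is the *peak* of the Lorentzian band, not an integral, so
  $\sigma \propto \delta$, $\sigma \propto \omega^2$ and
  $\sigma \propto 1/\Gamma$.
* **Lineshape.** $g$ is the area-normalised Lorentzian with half-width at
  half-maximum $\Gamma$, whose peak value is $1/(\pi\Gamma)$. The published
  conversion conventions in this area differ by factors of two in exactly
  this spot; the package fixes the choice by requiring that the packaged
  table's 35 $(\delta, \Delta E) \to \sigma$ triples be reproduced, which the
  $1/(\pi\Gamma)$ peak does to within 1% of each printed value plus its
  0.05 GM print quantisation (the alternative $2/(\pi\Gamma)$ is off by a
  factor of two). One tabulated row (M11, 9,10-dimethyl (twist), 6.4 GM) is
  internally inconsistent with its own printed inputs by one printed ulp —
  the computed value is 6.33 GM under worst-case input rounding — and is
  covered by the quantisation term.
* **Defaults** $\Gamma = 0.1$ eV and $N = 4$ are the values under which the
  packaged table was produced; $N$ is treated as an opaque integer
  multiplier. Both are configurable through `lineshape_params()`.
* **Units.** All internal arithmetic is in atomic units; eV, Debye and GM
  appear only at the I/O boundary (`convert_units()`, CODATA 2018 constants,
  audit copy in `inst/extdata/physical_constants.tsv`).

```{r}
cross_section(21307, 2.720) # native model at the reference level: ~58 GM
```

## Resonance diagnostics

The SOS denominators diverge when an intermediate state approaches
$\omega_f/2$ — the one-photon resonance that in practice contaminates the 2PA
of higher excited states of these chromophores. `resonance_check()` flags
every intermediate within a guard (default 0.0095 au ≈ 0.26 eV) of
$\omega_f/2$, and `sos_moment()` refuses to evaluate inside the guard with a
hard error carrying the flag list, rather than a warning: near-resonance SOS
values are numerically meaningless and silently returning them invites
misuse. The guard is configurable for deliberate studies of the divergence
(the test suite verifies $|\delta|$ grows monotonically as an intermediate
approaches $\omega_f/2$ from either side).

## The benchmark layer

`build_report()` reproduces the method-comparison analysis against a
reference method (default RI-CC2): unweighted per-property mean absolute
errors over the seven structures, reference/method ratio ranges for the
strength and cross section (reported at 1 decimal, raw values retained),
structure orderings per property (ties broken alphabetically with a
message), percent changes against the native 9,13-dimethyl model, and the
two-state correlation per block. Notable reproduction details:

* The MAE is an unweighted mean — verified to reproduce the tabulated
  0.182 eV for M11 excitation energies. Because the package computes MAEs
  from the *printed* table while the original rows were formed from
  unrounded data, three of the 28 tabulated MAE values land one printed ulp
  away (e.g. 1.297 vs 1.298 D); the tests assert one-ulp agreement for all
  28 and exact rounding for at least 25.
* The dipole triangle inequality $|\,|\mu_{00}| - |\mu_{11}|\,| \le
  |\Delta\mu| \le |\mu_{00}| + |\mu_{11}|$ must hold for vector-consistent
  records; `validate_records()` allows half-ulp slack on the 3-decimal
  magnitudes, without which one printed row fails by 0.001 D.

```{r}
rep <- build_report(tab)
tidy(rep) |> filter(method == "M11")
glance(rep)
```

## The synthetic generator

`generate_manifold()` / `generate_recordset()` exist so that every pipeline
stage is testable with known ground truth. The defaults emulate the RPSB5
charge-transfer regime as read off the reference block of the packaged
table: S1 energies 2.5–3.1 eV, $|\mu_{01}|$ 10–12.5 D, $|\mu_{00}|$
5.5–8.5 D, $|\mu_{11}|$ 1–6 D, $\Delta\mu$ within 15° of $\mu_{01}$,
and seven structures per record set. Directions are drawn uniformly on the
sphere (cone-constrained for the collinearity), rotations
quaternion-uniform on SO(3). Higher-state couplings decay geometrically
(factor 0.3 per state) so the SOS stays dominated by the two-state term —
the regime the near-perfect two-state correlation above certifies for the
real chromophores. Method biases (energy shift up, $\Delta\mu$ shrink)
mimic the observed TD-DFT-vs-coupled-cluster pattern — DFT underestimates
ground-state dipoles, TD-DFT overestimates excited-state dipoles, so
$\Delta\mu$ shrinks — and are stored as a ground-truth sidecar so the
benchmark layer's recovery can be asserted exactly at zero noise.

What the generator does *not* emulate: electronic-structure theory itself
(no orbitals or basis sets), genuinely non-Hermitian response (its dipole
matrices are symmetric, so CC2-like left/right asymmetry is injected only
at the tensor level in tests), vibronic structure, or correlated
noise between properties. Passing tests on synthetic data therefore certify
the *analysis machinery* — averaging conventions, unit chains, bias
recovery — not the accuracy of any electronic-structure method on real
retinals; the latter is exactly what the packaged table is for.

## Numerical choices and problem sizes

* Hermitian symmetry tolerance: relative Frobenius asymmetry $10^{-8}$.
* Rotation-invariance assertions at $10^{-10}$ relative; two-state
  equivalence at $10^{-12}$.
* Monte-Carlo averaging checks use 20,000–40,000 orientations per tensor
  (standard error well under 1% of the value) on ~20 tensors per run.
* Synthetic record sets use 7 structures × 2–3 methods with 2–4 states,
  which keeps the full suite fast while exercising every code path.
* Degenerate inputs: zero tensors average to zero; zero $\Delta\mu$ gives
  zero two-state strength; empty record files convert to empty outputs;
  single-method sets produce a report with no comparisons and a warning.

## Known limitations

* Only degenerate (one-colour) 2PA with parallel linear polarisation; no
  two-colour beams, circular polarisation, or vibronic lineshapes.
* The S1-focused workflow: higher final states are supported by
  `sos_moment(m, f)` but real higher states of these chromophores sit near
  one-photon resonances, which is precisely what the guard refuses.
* Cross sections assume the Lorentzian peak convention above; comparing
  against literature using FWHM-$\Gamma$ or integrated band conventions
  requires rescaling.
* The fixture stores printed (rounded) values; derived quantities can
  differ from originally published derived values by one unit in the last
  printed digit, as quantified above.
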