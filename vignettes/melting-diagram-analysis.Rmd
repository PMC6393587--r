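---
title: "Melting-diagram analysis of protein hydration: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-diagram analysis of protein hydration: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydromelt)
```

## The measurement model

Wide-line ¹H-NMR of a frozen protein solution records a free induction
decay (FID) that is a sum of components distinguished by relaxation rate,
not frequency — chemical shifts are buried by the line width. Ice and
protein protons relax fast (T₂ below 50–100 μs); rotationally mobile
hydration water decays slowly and dominates the 200 μs – 1 ms window.
The equilibrium magnetization behind each component follows the Curie law,
so its zero-time amplitude is proportional to the number of contributing
protons divided by the absolute temperature:

> A_i(0) ∝ N_i / T.

`hydromelt` models both components as Gaussian decays
A·exp(−(t/τ)²). For the mobile component this is the physically motivated
choice: in a frozen, heterogeneous sample the decay is dominated by static
field inhomogeneity, which produces a Gaussian-like envelope rather than an
exponential. For the solid component the exact shape is irrelevant — with
τ ≤ 25 μs its contribution at 200 μs is exp(−64) ≈ 10⁻²⁸, far below
anything the analysis window can see — so the same functional form is used
for simplicity. A fixed fraction of the proton budget (default 5 %)
represents protein protons and relaxes with the solid component.

### Fitting the slow component

`fit_slow_component()` fits A·exp(−(t/τ)²) on the window by *variable
projection*: for fixed τ the amplitude is a linear least-squares solution,
leaving a smooth one-dimensional problem in τ solved by `optimize()`. Two
numerical choices matter:

* **Zero-residual robustness.** Generic nonlinear least squares (`nls`)
  fails on noise-free data (zero residual), but the round-trip contract —
  synthesize with known (A, τ), recover to 1 × 10⁻⁶ relative — demands
  exactly that regime. Variable projection has no such failure mode.
* **τ is bounded below at 120 μs.** Mobile water has T₂* > 100 μs. If τ
  may approach the window edge from below, a noise-only tail can be "fitted"
  by an enormous amplitude hiding under exp(−(200/τ)²) ≈ 0 — a textbook
  identifiability failure that produced spurious mobile-water spikes below
  the thaw onset in early testing.

### Sharing τ across temperatures

`build_melting_diagram()` fits τ freely on the fully liquid reference
record (highest signal-to-noise) and, by default (`share_tau = TRUE`),
reuses it for every sub-zero record, fitting only the amplitude. The decay
constant is dominated by the static field inhomogeneity of the magnet, not
by the sample temperature, so a shared τ is physically appropriate; it
makes each per-record fit linear, unbiased even when the true mobile
fraction is zero, and roughly five times faster. Setting
`share_tau = FALSE` restores fully independent two-parameter fits.

### Normalization and the Curie correction

The mobile fraction is
n = (A₀·T) / (A₀_ref·T_ref) — the 1/T Curie factor is undone before
normalizing against the above-zero reference. The correction follows
directly from M₀ = n·B₀/T; because the source protocol never spells the
step out, it is config-switchable (`curie_correction`). Values n > 1 are
flagged with a warning but never clipped downward — they indicate a
calibration problem that silent clipping would hide. The lower bound is
clipped at 0 (amplitudes are magnitudes); as a consequence the estimator at
exactly n = 0 is one-sided and slightly positively biased (≈ 0.4 σ of the
amplitude noise), which the test suite accounts for by checking
unbiasedness above the thaw onset.

## Temperature scales

* Fundamental temperature: T_fn = (T_C + 273.15)/273.15, exactly affine.
* Activation energy: E_a = 6.01 kJ/mol × T_fn — a linear barrier scale
  anchored at the melting heat of ice at 0 °C, so E_a/T_fn = 6.01 for
  every row by construction.

## Derivative and plateau detection

`derivative_melting()` computes d*n*/d*T*_fn by windowed quadratic
regression (Savitzky–Golay equivalent, default 5 points, one-sided
stencils at the ends). It is exact for locally quadratic series; a
constant diagram differentiates to numerical zero.

`detect_plateau()` then:

1. finds the **first-thaw onset** — the first row where *n* exceeds 10 %
   (`onset_frac`) of its value near −20 °C (a temperature safely above
   every plateau but below the steep final rise);
2. sets the slope threshold to `slope_frac` (default 5 %) of the **peak
   melting slope**, taken as the maximum derivative over all post-onset
   sub-zero rows (this includes the final rise; including it only raises
   the threshold, and the folded/disordered archetypes remain separated by
   a factor of about three in threshold units);
3. collects maximal contiguous runs with |d*n*/d*T*_fn| ≤ threshold and
   T_fn-width ≥ `min_width_Tfn` (default 0.02 ≈ 5.5 °C), returning the
   longest (ties go to the **colder** run — the first thaw precedes any
   plateau). An absolute floor (`zero_tol = 1e-9`) on the threshold keeps
   an everywhere-constant diagram detectable even though its "peak slope"
   is rounding noise.

Neither `slope_frac` nor `min_width_Tfn` comes from the source protocol;
they were chosen once so that the folded and disordered archetypes are
cleanly separated, and both are exposed in the configuration. Bound
uncertainties use a uniform-error model, grid spacing/√12 on the T_fn
scale.

HeR = (1 − T_fne)/(1 − T_fno) with first-order (delta-method) error
propagation; no plateau, and a degenerate plateau T_fno = T_fne, both give
HeR = 1. Published per-protein HeR uncertainties are not reproducible by
standard propagation from the printed bound uncertainties, so no attempt is
made to match them. Classification thresholds (F ≤ 0.6 < I < 0.95 ≤ U) are
package choices anchored on the exemplar values ≈ 0.54 / 0.69 / 1.

## What the synthetic generator emulates — and what it does not

`make_melting_profile()` states the ground truth as a piecewise curve:
clamped-cubic first thaw (reaching n_first exactly at the plateau start),
an *exactly* flat plateau, and a monotone linear-plus-quadratic rise
reaching 1 at 0 °C. Defaults are the stated archetype conditions: folded —
onset −53 °C, plateau −48…−26 °C; intermediate — extended thaw −53…−40 °C,
plateau to −25 °C; disordered — onset −50 °C, strictly increasing
throughout. n_first defaults to 0.1, i.e. ~50 first-shell waters out of a
nominal 500 waters per protein in the sample; the proton budget is a
concentration choice that the generator exposes rather than fixes.
`synthesize_fid()` adds Curie scaling (c = 278.15 amplitude·K, so the +5 °C
reference has unit amplitude and `noise_sd = 0.01` is exactly 1 % of the
reference), a 7 μs dead time, and Gaussian noise; the grid default is 1 °C,
matching the ±1 °C experimental temperature uncertainty.

A green round-trip test therefore establishes that the analysis chain
inverts *this* stated world — two Gaussian components, temperature-independent
τ, additive white noise. It does not establish robustness to
instrument non-idealities the generator omits: receiver baseline drift,
T₁-dependent recycle effects, radiation damping, or a temperature-dependent
inhomogeneity envelope.

Toy structural ensembles are similarly stated worlds: an ideal α-helix
backbone with 0.05 Å jitter (pairwise RMSD ≈ 0.1 Å ≪ the 1.0 Å clustering
cutoff) versus self-avoiding random coils (typical pairwise RMSD > 3 Å);
waters on a 3.1 Å cubic lattice, clash-filtered, nearest-first. They
exercise the geometry code exactly; they are not decoys of real
trajectories, and published cluster counts from unavailable trajectories
are used only as qualitative ordering (compact → few clusters,
extended → many).

## Structural-analysis conventions

* "Main-chain" selection for clustering is N, CA, C (carbonyl O excluded).
* Shell membership: any water atom within the cutoff of any protein atom,
  each water counted once (`oxygen_only` switches to O-only). The cell-list
  grid implementation is verified against an O(N²) oracle.
* H-bond criteria: donor–acceptor ≤ 3.5 Å, D–H…A ≥ 150° when hydrogens
  exist, distance-only otherwise — standard geometric defaults, since the
  source states counts but not criteria.
* SASA: Shrake–Rupley with a deterministic golden-spiral lattice (960
  points) and Bondi-type radii, so results are bit-reproducible; the fixed
  lattice means rotation invariance holds only to the quadrature error
  (tested at 2 %), unlike Rg/distances/counts which are exactly invariant.
* Kabsch superposition excludes reflections (smallest singular direction
  flipped when det < 0).

## Degenerate inputs and tie-breaks

Unordered plateau bounds, plateaus requested for the disordered archetype,
empty grids, missing reference records, too-few fit samples and unknown
config keys are all hard errors, never silent repairs. Duplicate
temperatures are inverse-variance averaged with a message. Equal-length
plateau runs resolve to the colder run; GROMOS center ties resolve to the
lowest model index.

## Known limitations

* Single mobile component: bound-water populations with intermediate τ are
  not resolved (matching the two-pool reading of the experiment).
* No T₁/CPMG analysis; the FID path alone is implemented.
* The PDB reader is deliberately minimal (fixed columns, MODEL/ENDMDL,
  HOH/WAT/SOL waters) — it targets the ensembles this package writes and
  well-formed multi-model files, not the full PDB format zoo.
* Binary trajectory formats (XTC/DCD) are out of scope; convert to
  multi-model PDB upstream.
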