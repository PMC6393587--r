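# hydromelt

Melting-diagram analysis of protein hydration by wide-line ¹H-NMR, with
companion conformer-ensemble analyses.

## The problem

When a protein solution is frozen and slowly heated from −80 °C toward
0 °C, a thin shell of hydration water around the protein becomes
rotationally mobile long before bulk ice melts. Wide-line ¹H-NMR separates
this mobile water from ice and protein protons by relaxation rate: in the
free induction decay (FID) the solid fraction relaxes fast
(T₂ < 50–100 μs) while mobile water decays slowly and is read in the
200 μs – 1 ms window. Tracking the mobile fraction *n*(*T*) — normalized so
*n* = 1 for the fully liquid sample — yields a **melting diagram** whose
shape discriminates protein fold classes:

- **Folded** proteins: after the first hydration layer thaws (≈ −50 °C), a
  temperature range follows where d*n*/d*T* = 0 — no additional water can
  be mobilized (a *plateau*).
- **Disordered** proteins (IDPs): melting is continuous; new conformers keep
  exposing new surface, so *n* rises monotonically with no plateau.

The diagram is mapped onto the normalized fundamental temperature
*T*_fn = *T*/273.15 K and the activation-energy scale
*E*_a = 6.01 kJ/mol · *T*_fn (anchored by the melting heat of ice at 0 °C).
With *T*_fno and *T*_fne the fundamental temperatures at the plateau's
beginning and end, the **heterogeneity ratio**

    HeR = (1 − T_fne) / (1 − T_fno)

quantifies the heterogeneous share of the binding interface: HeR ≪ 1 for a
folded protein, HeR = 1 (by definition) when no plateau exists. Typical
exemplar values are ≈ 0.54 (folded miniprotein), ≈ 0.69 (partially folded,
acid-destabilized) and 1 (disordered point mutant).

The package implements the full chain — two-component FID decomposition with
Curie-law (1/*T*) amplitude normalization, diagram construction, smoothed
d*n*/d*T*_fn, plateau detection, HeR and F/I/U-state classification —
plus a synthetic-data module (parametric ground-truth melting profiles,
FID synthesis, toy conformer ensembles) so everything is testable without
instrument data, and the structural-ensemble measures used to interpret the
NMR results: Kabsch superposition, GROMOS-style RMSD clustering at 1.0 Å,
hydration-shell water counts (2.6/2.8 Å), radius of gyration, Shrake–Rupley
SASA, hydrogen-bond counts, residue distances and per-residue shell-water
fluctuation, on multi-model PDB files.

## Worked example

```r
library(hydromelt)

profile <- make_melting_profile("folded")          # plateau −48..−26 °C
series  <- synthesize_series(profile, seed = 42)   # 80 FIDs + reference, 1 % noise
diagram <- build_melting_diagram(series$signals, series$reference)
diagram <- derivative_melting(diagram)
plateau <- heterogeneity_ratio(detect_plateau(diagram))
plateau
#> Plateau: T_fno = 0.828 (-47.0 C) .. T_fne = 0.901 (-27.0 C)
#> HeR = 0.574 +- 0.007
classify_state(plateau)
#> [1] "F_state"
```

The detected bounds sit one 1 °C grid step inside the ground-truth plateau
(−48…−26 °C), and HeR < 0.6 classifies the series as folded. Rows of the
diagram carry the underlying per-temperature table:

```r
head(diagram[diagram$T_C >= -50, c("T_C","T_fn","E_a_kJ_mol","n","n_se")], 4)
#>    T_C  T_fn E_a_kJ_mol      n    n_se
#> 31 -50 0.817       4.91 0.0650 0.00126
#> 32 -49 0.821       4.93 0.0885 0.00136
#> 33 -48 0.824       4.95 0.1003 0.00128
#> 34 -47 0.828       4.98 0.1000 0.00131
```

i.e. at −50 °C (*E*_a = 4.91 kJ/mol) the first hydration layer is mid-thaw,
and by −48 °C the mobile fraction has reached the first-layer level
(*n* = 0.10, ~50 waters for a 2.2 kDa miniprotein; see
`waters_per_protein()`).

A disordered profile run the same way gives `found = FALSE`, `HeR = 1`,
`"U_state"`. `run_pipeline(default_config(...))` composes all stages and
writes a versioned TSV/JSON report; a thin CLI wrapper lives in
`inst/cli/hydromelt.R` (`simulate`, `analyze-fid`, `melting`, `run`).

## Structural ensembles

```r
ens <- make_toy_ensemble("compact", n_models = 10, n_waters = 40)
gromos_cluster(ens, cutoff = 1.0)        # 1 cluster, population 100%
count_shell_waters(ens$models[[1]], 2.8) # first-shell waters
radius_of_gyration(ens$models[[1]]); sasa(ens$models[[1]])
```

## Acceptance script

`scripts/acceptance.R` recomputes, at run time from the installed package,
the scale anchors (activation energy at 0, −25, −26, −35, −40, −50 °C and
the fundamental temperature at −41 °C), the HeR worked examples from
tabulated plateau bounds, and the end-to-end HeR of a seeded synthetic
disordered series, then writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
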