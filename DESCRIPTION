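Package: hydromelt
Title: Melting-Diagram Analysis of Protein Hydration by Wide-Line NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the hydration shell of proteins in frozen
    solution from wide-line 1H-NMR free-induction-decay (FID) records.
    Decomposes multicomponent FIDs into fast (ice/protein) and slow (mobile
    water) fractions, builds melting diagrams of the mobile-water fraction n
    and mass-normalized hydration h against temperature, maps them onto the
    normalized fundamental-temperature and activation-energy scales, detects
    the zero-derivative plateau characteristic of folded proteins, and
    computes the heterogeneity ratio HeR = (1 - T_fne)/(1 - T_fno) that
    separates folded, intermediate and disordered states. A synthetic-data
    module generates FID series from parametric ground-truth melting profiles
    and toy conformer ensembles, so the full pipeline is testable without
    instrument data. Companion structural analyses for multi-model PDB
    ensembles are included: Kabsch superposition, GROMOS-style RMSD
    clustering, hydration-shell water counting, radius of gyration,
    Shrake-Rupley solvent-accessible surface area, hydrogen-bond counting
    and per-residue shell-water fluctuation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
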