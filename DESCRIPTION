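Package: ubistab
Title: Quantifying Protein Fold Destabilization by Ubiquitylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for measuring how covalent ubiquitylation
    destabilizes the fold of substrate proteins. Implements tryptophan
    fluorescence melting-curve analysis (barycentric mean emission
    wavelengths, Boltzmann sigmoid midpoint fitting for thermal and
    chemical denaturation, replicate statistics and Student's t tests),
    differential scanning calorimetry thermogram analysis (baseline
    correction, transition-peak detection, folding-reversibility indices
    from reheating scans), and 15N backbone relaxation analysis
    (exponential T1/T2 fitting with Monte Carlo errors, steady-state
    heteronuclear NOE, reduced spectral density mapping to J(0), J(wN)
    and J(0.87wH) with first-order error propagation, isotropic
    rotational correlation time estimation, and J(0)-ratio
    destabilization profiles). A synthetic-data generator emulates all
    three experiment types (two-state melting spectra, van't Hoff DSC
    endotherms with partial reversibility, Lipari-Szabo model-free
    relaxation data) so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
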