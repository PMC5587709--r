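Package: qprm
Title: Quantum Probe Relaxation Microscopy of Electronic Spins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for wide-field nitrogen-vacancy (NV) diamond
    relaxometry of electronic spin species in solution. Simulates per-pixel
    fluorescence decay stacks over a magnetic-field sweep, fits stretched
    exponential spin-lattice relaxation (T1) maps, assembles and subtracts
    relaxation-rate spectra, fits Lorentzian spectral-density models to
    extract target-spin g-factors, linewidths and probe depth, converts
    on-resonance rates to spin concentrations and detection limits per
    sensing voxel, and tracks redox kinetics through a two-point relaxation
    scheme.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    deSolve,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'spin-physics.R'
    'synthetic-mask.R'
    'synthetic-stack.R'
    'synthetic-kinetics.R'
    'relaxometry.R'
    'spectroscopy.R'
    'quantification.R'
    'kinetics.R'
    'resolution.R'
    'io.R'
    'pipeline.R'
    'qprm-package.R'
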