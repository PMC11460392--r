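Package: ptypine
Title: Ptychographic Phase Retrieval with a Nonexpansive Denoising Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint object/probe phase retrieval for scanning coherent
    diffraction imaging (ptychography). Implements the PINE iteration --
    stochastic projection-gradient sweeps over diffraction patterns
    interleaved with a hybrid-steepest-descent relaxation toward the fixed
    points of a spectrally normalized residual denoiser -- together with the
    ePIE and rPIE baselines, a forward simulator (synthetic particle
    phantoms, bump probes, grid and Fermat-spiral scans, Poisson photon
    noise), a formula-driven dead-leaves training corpus and trainer for the
    nonexpansive denoiser, and Fourier ring correlation evaluation with
    gauge correction and phase-only-correlation subpixel registration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
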