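Package: toffer
Title: Lossless Integer-Lattice Storage and Random Access for DIA
    Mass Spectrometry Raw Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stores profile-mode data-independent acquisition (DIA/SWATH)
    mass spectrometry runs as sparse integer matrices in HDF5 ("toffee"
    files). A time-of-flight transfer function maps m/z values onto an
    integer lattice, m/z = [alpha*(i + gamma) + beta]^2, whose
    coefficients are estimated per scan so that profile mzML data round
    trips through the compressed form without loss. On top of the store
    the package provides random spectrum, chromatogram (XIC) and 2D
    region extraction, construction of in-silico dilution series by
    injecting scaled peptide signal into background runs, 2D analytic
    peak fitting (log-normal in retention time, Gaussian in m/z index)
    for peptide re-quantification with cohort outlier flagging,
    multi-channel isotope-trace image rendering, and a deterministic
    synthetic-run generator with full ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rhdf5,
    mzR,
    minpack.lm,
    stats,
    utils
Suggests:
    png,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
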