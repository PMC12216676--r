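Package: crossmesh
Title: Crystal Identification and 3D Centring from Double X-Ray Mesh Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of double X-ray mesh (raster) scans for multi-crystal
    macromolecular crystallography. Segments per-cell diffraction spot lists
    into individual-crystal regions, reconstructs reciprocal-lattice subsets
    from spot positions via the Ewald sphere construction, detects lattice
    periodicity with an isotropic direction scan and FFT scores calibrated
    against a Rayleigh null, validates crystal identity across two scan
    orientations, and triangulates 3D centring coordinates. Includes a
    synthetic multi-crystal diffraction simulator that provides exact ground
    truth for every stage, plus readers and writers for the package's
    plain-text scan, map and report formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
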