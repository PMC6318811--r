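Package: pwstherm
Title: Photothermal Simulation of Port-Wine Stain Laser Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation of pulsed-laser treatment of port-wine
    stain (PWS) birthmarks, including vessels loaded with indocyanine-green
    doped erythrocyte-derived particles. Provides wavelength-dependent
    optical-property models for pigmented skin and blood, a voxelized
    Monte Carlo model of photon transport and volumetric energy deposition,
    an implicit finite-difference solver for the bioheat equation under
    cryogen-spray-cooling boundary conditions, Arrhenius rate-process
    quantification of thermal damage, a threshold-dosage search for
    epidermal injury, an OCT-style angiography preprocessing chain, and a
    synthetic vascular-plexus generator for exercising the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    tiff,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
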