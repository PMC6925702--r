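Package: piliconduct
Title: Helical Pilus Assembly, Aromatic Pathway Geometry and Marcus-Theory
    Charge Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds helically symmetric type IV pilus assemblies from a
    single pilin subunit, scores them against flat-harmonic and ambiguous
    distance restraints, clusters candidate models by rotation angle and
    structural similarity, extracts the aromatic pi-stacking electron
    transfer pathway with its smallest symmetric unit, and converts
    electronic-structure scalars (dimer orbital splittings, four-point
    reorganization energies) into Marcus-theory transport quantities:
    rate upper bound, diffusion coefficient, Einstein mobility, carrier
    density, conductivity and conductance. Includes synthetic generators
    for idealized aromatic-bearing pilins and planted-parameter
    assemblies used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
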