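Package: memreflect
Title: Specular Neutron Reflectometry Modelling of Peptide-Membrane Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and co-refinement of specular neutron
    reflectivity from solid-supported phospholipid bilayers, aimed at
    locating membrane-active peptides. Implements scattering-length-density
    bookkeeping with deuteration schemes and labile-hydrogen exchange, an
    Abeles transfer-matrix reflectivity kernel with Nevot-Croce interfacial
    roughness and Gaussian resolution smearing, parameterised slab models of
    supported bilayers, simultaneous multi-contrast refinement by
    differential evolution with Monte-Carlo resampling uncertainties, and
    volume-fraction decomposition of fitted layer densities including
    orientation inference from asymmetrically deuterated peptides. Also
    provides circular-dichroism mean-residue-ellipticity conversion,
    paramagnetic-titration normalisation, and a synthetic-data generator
    for two-contrast bilayer experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
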