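Package: vsaxs
Title: Virtual SAXS Profiles and Fast Shape Retrieval for Single-Particle
    X-Ray Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to turn stacks of single-particle X-ray scattering
    patterns into a merged one-dimensional "virtual SAXS" profile and to
    retrieve low-resolution shape models that match it. Includes a
    synthetic-data simulator (monodisperse bead models at uniform random
    orientations on the Ewald sphere, Poisson photon noise, beam-center
    jitter, false-positive injection), beam-center refinement by Friedel
    symmetry in the flat region of the Ewald sphere, azimuthal integration
    and profile merging with Pearson-correlation convergence monitoring,
    Debye-formula profile computation for bead models, a size-rescalable
    shape database keyed by the dimensionless variable s = q*R, and a
    database search ranked by a least-squares-scaled chi score with the
    optimal model radius located by golden-section search. Retrieved models
    are clustered, averaged and written as CCP4 density maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
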