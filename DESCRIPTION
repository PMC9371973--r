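Package: xlgeom
Title: Crosslink Restraint Validation, Domain-Motion Geometry and
    Exchange Kinetics for Integrative Structural Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for validating integrative structural models of
    multi-domain proteins, built around the autoinhibition analysis of
    the Rac exchanger P-Rex1.  Maps lysine-lysine crosslinking mass
    spectrometry identifications onto atomic models as C-beta distance
    restraints and scores models with a frequency-weighted model false
    discovery rate; quantifies conformational transitions with Kabsch
    superposition, axis-angle rotation decomposition and helix
    kink/hinge angles; computes Shrake-Rupley solvent-accessible and
    buried surface areas and geometric hydrogen bonds; and fits
    plateau-followed-by-one-phase-association rate constants to
    mant-GDP nucleotide-exchange fluorescence time courses.  Includes a
    synthetic-data generator (ideal and kinked helices, two-domain toys
    with planted rigid transforms, crosslink sets with planted violated
    fractions, noisy exchange traces) so every stage is testable
    without downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
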