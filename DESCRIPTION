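Package: glycofinger
Title: MALDI-TOF N-Glycan Mass Calculus, Annotation and Glyco-Group
    Fingerprinting for Chlorella Microalgae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting MALDI-TOF mass spectra of underivatized,
    sodiated, reducing N-glycans from Chlorella-like microalgae. Implements
    exact monoisotopic mass arithmetic over glycan compositions (hexose,
    N-acetylhexosamine, pentose, methyl, deoxyhexose) and the four-digit "os"
    composition shorthand; internal recalibration on oligomannosidic glycans;
    bounded enumeration of compositions matching a peak within tolerance;
    detection of 14-Da methylation ladders; b/y fragment enumeration for
    MS/MS (LIFT) spectra with rule-based inference of chitobiose-core
    substitution, including the core alpha-1,3-fucose release logic of
    PNGase A versus PNGase F; rule-based classification of spectra into 13
    named glyco-groups with mixture and orphan flagging; a labelled synthetic
    spectrum generator for both MS levels; and a monophyly-based concordance
    statistic between glyco-group labels and a supplied phylogenetic tree.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
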