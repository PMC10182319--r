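Package: labileMS
Title: Labile-Mode Database Search for Modified Peptides in Tandem Mass Spectrometry
Version: 0.1.0
Authors@R: person("labileMS", "Maintainers", email = "labilems@example.org", role = c("aut", "cre"))
Description: A peptide-spectrum-match search engine for labile
    post-translational and chemical modifications. Spectra are gated on
    modification-specific diagnostic ions, candidate peptides are retrieved by
    precursor mass offsets, and hyperscores incorporate peptide- and
    fragment-remainder ions produced when a modification fragments during
    collisional activation. Nonlabile (variable-modification), labile
    (mass-offset) and hybrid candidates compete per spectrum; fragment
    remainder ions localize the modification; identifications are filtered by
    target-decoy false discovery rate. Includes MGF/mzML readers, in-silico
    tryptic digestion with decoy generation, a synthetic-spectrum simulator
    with ground truth for end-to-end validation, and command-line style entry
    points with workflow templates for phosphorylation, RNA-crosslink and
    ADP-ribosylation searches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
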