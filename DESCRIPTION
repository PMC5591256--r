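Package: lnahelix
Title: Structural Analysis of LNA-Modified DNA Duplexes and Triplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how locked nucleic acid (LNA) substitutions
    shape DNA duplex and parallel pyrimidine-motif triplex structures.
    Parses mixmer oligonucleotide notation (lowercase DNA, uppercase LNA,
    TINA intercalators, fluorophore labels), derives Watson-Crick and
    parallel Hoogsteen complements and locates triplex-forming
    oligonucleotide binding sites; builds idealized fiber models of B- and
    A-form duplexes and major-groove triplexes with per-residue control of
    sugar pucker; computes glycosidic torsions, sugar pseudorotation
    phases, hydrogen-bond persistence under a heavy-atom distance
    criterion, and base-pair-step helical parameters including the
    low-inclination-and-roll A-like (LirA) duplex classification; and
    generates seeded synthetic multi-model trajectories with two-state
    sugar repuckering and end-biased base-pair opening for validating
    every analysis stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
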