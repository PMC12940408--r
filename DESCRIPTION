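Package: mechvar
Title: Multi-State Structural Mechanism Classification of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic interpretation of protein missense variants from
    multi-state structural models. Annotates residue context (domains,
    nucleotide-binding motifs, binding pockets, membrane exposure, regulatory
    and post-translational-modification proximity) over three conformational
    states, detects 3D variant hotspots with permutation-derived empirical
    p-values, classifies variants into six mechanistic categories from
    state-specific folding free-energy changes and substitution biochemistry,
    and assigns and combines ACMG-2015 evidence lines (PM1, PM2, PM5, PP3,
    PP4) with reclassification gap analysis. Includes a synthetic-data
    generator producing toy multi-state structures, variant cohorts and
    stability tables with known ground truth. Developed around ABCC6, the
    ATP-binding cassette transporter whose loss of function causes
    pseudoxanthoma elasticum and generalized arterial calcification of
    infancy, but applicable to any protein with analogous inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    Matrix,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
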