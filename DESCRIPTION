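Package: strwash
Title: Forensic STR Profile Comparison for Hand-Swab Touch DNA Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing evidence short tandem repeat (STR) profiles
    from hand swabs against single-source reference profiles: expected and
    detected allele counting, drop-in and drop-out accounting, allele
    recovery percentages, per-locus detection scores, and profile-level
    interpretation (inconclusive, single-source, mixture, and the 3:1
    major-contributor rule). Includes group summaries and two-sample tests
    for pre- versus post-handwashing study designs, a bundled 12-subject
    hand-swab washing dataset at the published count level, and a seeded
    simulator of reference genotypes, condition-dependent allele dropout,
    sporadic drop-in, and peak-height mixtures over the 27-locus Fusion 6C
    panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
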