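Package: asokinetics
Title: Kinetics of RNase H1-Dependent Antisense Oligonucleotide RNA Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for kinetic analysis of tetracycline-inducible minigene
    reporter systems used to measure antisense oligonucleotide (ASO)
    pharmacodynamics. Provides absolute qRT/PCR quantification (standard-curve
    calibration and the unit-conversion chain from femtograms per reaction to
    per-cell, per-molecule, per-gene-copy and polymerase-velocity rates),
    windowed linear-regression rate estimation with onset-time detection for
    treated versus control time courses, a two-compartment kinetic model of
    transcription, splicing/export and RNase H1-mediated cleavage with delayed
    ASO action (exact piecewise-analytic solution, closed-form steady states
    and least-squares parameter recovery), and a seeded synthetic-data
    generator emulating induction, washout, RNase H1 titration, repeat-site
    and pre-load experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
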