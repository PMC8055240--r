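Package: GammaBED
Title: Biologically Effective Dose Modelling for Multi-Iso-Centre Gamma
    Knife Radiosurgery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-voxel biologically effective dose (BED) calculation for
    multi-iso-centre Gamma Knife treatments under the linear-quadratic
    model with bi-exponential (fast/slow partition) sublethal-damage
    repair. Each iso-centre is treated as a sub-fraction and beam-off
    periods as incomplete-repair intervals, so the BED of a plan depends
    on per-voxel dose rates, beam-on times and the delivery timeline.
    Includes prescription-isosurface extraction and summaries, simulation
    of unscheduled treatment gaps at every inter-iso-centre position,
    exhaustive and heuristic optimisation of the iso-centre delivery
    order with cohort-level statistics, and a synthetic treatment-plan
    generator emulating clinical plan exports for fully reproducible
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
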