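Package: hbquat
Title: Quaternary and Tertiary Transition Analysis for Hemoglobin-Like Tetramers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes quaternary (T-R) and tertiary (t-r)
    conformational transitions of tetrameric proteins such as human
    hemoglobin A. Builds principal-component subspaces from reference
    crystal structures, computes the rotation-sensitive rotRMSD distance,
    defines normalized difference-vector reaction coordinates, quantifies
    rigid-body dimer rotations as axis/angle descriptors, estimates
    conditional tertiary-state populations, and measures the coupling
    between quaternary and tertiary coordinates with a histogram mutual
    information estimator extrapolated to infinite sample size. Includes a
    synthetic morphing-trajectory generator with known ground truth so the
    whole pipeline is testable without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
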