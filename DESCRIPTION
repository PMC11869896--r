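Package: reachfield
Title: Dynamic Neural Field Simulation of Choice Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A closed-loop dynamic neural field (DNF) simulator of the
    colour-oddity choice reaching task. Synthetic three-item displays (one
    odd-colour target, two distractors, with item size as a task-irrelevant
    feature) are parsed by a pre-attentive visual front end into per-item
    saliency levels and a proximity-based movement-onset scaling factor.
    Winner-takes-all saliency competition nodes coupled to two-dimensional
    neural fields (target location, hand-target displacement, and a
    two-layer velocity field) drive a planar end effector, producing curved
    reach trajectories with bell-shaped speed profiles. Tools are included
    to measure initiation latency and maximum trajectory deviation, to
    aggregate them over factorial experiments, and to compare normalised
    condition profiles against user-supplied reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
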