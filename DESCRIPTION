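Package: speckleRPU
Title: Relative Perfusion Units from Laser Speckle Contrast Imaging
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies tissue perfusion from laser speckle contrast imaging
    (LSCI) as Relative Perfusion Units (RPU): speckle contrast estimation,
    flow-index maps, Hot/Cold reference normalization and region-of-interest
    statistics. Includes a synthetic dynamic-speckle scene generator that
    emulates porcine bowel perfusion experiments (an ischemic bowel gradient
    with mesenteric and antimesenteric arcs, progressive arterial and venous
    occlusion coupled to mean arterial pressure, and paired side-to-side
    anastomoses), a single-exposure speckle renderer, and the statistical
    readouts used to characterize those scenes (segment ANOVA, paired arc
    comparisons, two-piece decline-onset detection, and perfusion-pressure
    regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
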