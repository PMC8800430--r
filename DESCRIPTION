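Package: cellugel
Title: Quantitative Characterization of Cellulose II Gels from Scattering,
    Mass Spectrometry and Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing enzymatically synthesized cellulose II gel
    structures across growth conditions. Implements the two-level unified
    (Beaucage) Guinier/power-law model for small-angle X-ray scattering
    (SAXS) curves, including evaluation, bounded least-squares fitting,
    Kratky transforms, reference subtraction and local power-law slopes;
    Gaussian deconvolution of wide-angle (WAXS) crystalline peaks over a
    smooth solvent background with d-spacing conversion and cellulose II
    reflection assignment; degree-of-polymerization estimation from
    MALDI-ToF cellodextrin peak series via Gaussian envelope fitting; and
    ribbon-width morphometry of electron micrographs by segmentation,
    skeletonization and distance-transform sampling. Seeded synthetic-data
    generators with machine-readable ground truth make every stage testable,
    and a pipeline layer orchestrates per-condition, per-position analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    EBImage,
    png,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
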