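Package: mpscope
Title: Quantification of the Axonal Membrane-Associated Periodic Scaffold
    from Localization Microscopy and Platinum-Replica EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the ~185-190 nm periodic actin-spectrin
    scaffold (MPS) that lines axons. Reads and converts single-molecule
    localization tables (N-STORM text and ThunderSTORM CSV dialects),
    reconstructs super-resolution images at a physical pixel size, extracts
    intensity profiles along traced axons and measures scaffold spacing and
    periodicity amplitude by normalized autocorrelation, performs filament
    morphometry (braid spacing, width, length) on platinum-replica EM views
    using a five-line averaging protocol, registers localization data onto
    EM views with control-point affine transforms, and compares experimental
    groups with non-parametric statistics. A synthetic-scene generator with
    known ground truth (periodic ring localizations, braid-like ridge
    images, correlative pairs) makes every stage testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
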