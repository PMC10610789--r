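Package: petu
Title: Parallel-Encoded Texture Units and Texture Spectra for Binary Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Texture analysis of binary images with parallel-encoded texture
    units, an LBP-family descriptor in which each row of an I x J observation
    window is read as a binary number and the row codes are summed into a
    single texture unit. Provides sliding-window texture spectra (normalized
    texture-unit histograms), Shannon-entropy texture-information measures,
    an arithmetic operation-count cost model, a multi-class minimum-distance
    classifier built on per-class prototype spectra from randomly sampled
    subimages, seeded synthetic binary-texture generators, global-threshold
    binarization (Otsu or fixed), portable anymap (PBM/PGM/PPM) image input
    and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
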