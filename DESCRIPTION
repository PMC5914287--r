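Package: dasypop
Title: Dasymetric Downscaling of Decadal Census Populations to a 1-km Grid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing high-resolution (1-km) decadal
    population surfaces from administrative-unit census counts using
    dasymetric areal interpolation. Implements five nested allocation
    models of increasing complexity (uniform county allocation through
    full suitability weighting), division-level urban area-population
    power-law scaling with its derived intra-urban density gradient,
    historical urban-extent reconstruction by concentric shrinking of
    baseline footprints, inhabitability masking, elevation-based
    topographic suitability, a gravity model of rural market potential,
    grid-search calibration of the weighting exponents, and validation
    against finer census units via the mean absolute relative error.
    A seeded synthetic-world generator produces complete fake study
    regions with known ground truth so the whole pipeline can be
    exercised and tested without any census download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
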