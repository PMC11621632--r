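Package: driftgain
Title: Diffusion Statistics of Fixational Drift and Retina-Contingent
    Stimulus Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing the random-walk statistics of fixational
    eye drift and of gaze-contingent ("retina-contingent") stimuli whose
    world motion is a gain multiple of eye motion. Computes mean square
    displacement over nonoverlapping lags, fits the diffusion constant and
    scaling exponent of anomalous diffusion, applies delivery-accuracy and
    microsaccade quality-control filters, generates synthetic drift with
    tunable diffusion and persistence via exact fractional Gaussian noise,
    builds Brownian random-walk stimulus libraries, and implements an
    MSD-matching model observer that predicts perceived-to-world
    diffusion-constant ratios as a function of the world-motion scaling
    exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
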