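Package: circtone
Title: Circular Shepard-Tone Spaces, Perceptual Circularity, and Mixture
    Models of Auditory Reproduction Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for auditory working-memory research with circular
    stimulus spaces. Synthesizes Shepard tone complexes on a 360-degree
    log-frequency circle and writes standard WAV audio; quantifies the
    perceptual circularity of a stimulus space from pairwise similarity
    judgments via metric multidimensional scaling, anchor-based affine
    alignment, periodic spline closure, and the isoperimetric circularity
    quotient C = 4*pi*Area/Perimeter^2; and fits standard and swap
    von Mises mixture models to circular reproduction errors by maximum
    likelihood. Includes seeded generators for synthetic similarity-rating
    and reproduction-trial datasets so the full analysis pipeline can be
    exercised without human participants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
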