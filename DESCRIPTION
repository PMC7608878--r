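Package: echoscape
Title: Simulation of Bat-Inspired Sonar Foliage Echoes in Random Forest Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified simulation framework for computational bioacoustics:
    generates random natural-looking trees from Lindenmayer-system grammars
    with procedural mesh templates, places them in a field by sampling an
    inhomogeneous Poisson process with a mixture-of-squared-exponential
    intensity, and synthesizes monostatic bat-like sonar foliage echoes by
    frequency-domain superposition of circular-disc leaf reflectors inside a
    Gaussian mainlobe beampattern, followed by inverse FFT to time-domain
    impulse responses. Supports static-sonar and moving-sonar (circular and
    figure-eight trajectory) sensing scenarios, STL mesh import/export, and
    tidy tabular outputs throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
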