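Package: riccsurf
Title: Hill-Type Response Surfaces for Drug-Mixture Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Null- and full-interaction Hill-type response surfaces for
    n-component drug mixtures, obtained as closed-form solutions of the
    underlying Riccati-type partial differential equation. Provides
    constrained nonlinear estimation of perturbation and interaction
    parameters from dose-effect tables, AIC-guided backward parameter
    elimination, classical reference models (generalized concentration
    addition, Chou-Talalay, implicit Loewe concentration addition), and
    synergy-surface analysis that locates dose combinations of peak
    synergism or antagonism and extracts iso-effect and iso-synergy level
    sets. Ships the anesthetic hypnosis dataset (midazolam, propofol,
    alfentanil) and a synthetic dose-response generator with known ground
    truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
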