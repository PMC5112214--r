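Package: moctmc
Title: Cochlear Gain and Compression from Temporal Masking Curves with
    Contralateral Efferent Elicitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychophysical estimation of cochlear gain and compression from
    temporal masking curves (TMCs), and of the gain reduction caused by a
    contralateral elicitor of the medial olivocochlear (MOC) reflex. Provides
    the piecewise-linear cochlear input-output model with closed-form forward
    predictions of TMCs and growth-of-masking functions, bounded least-squares
    fitting of the six baseline parameters and the single elicitor parameter
    (the gain reduction), dual-roex excitation-pattern simulation, exhaustive
    multinomial-weighted bootstrap statistics with Gaussian and Nakagami
    density fits, a click-evoked otoacoustic emission (CEOAE) suppression
    analysis chain, and a synthetic-data generator that simulates the
    three-alternative forced-choice adaptive tracking procedure used to
    collect TMCs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
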