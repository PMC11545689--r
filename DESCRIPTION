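Package: tsdnorm
Title: Thermal Reaction Norms of Sex Determination and Embryonic Growth in Sea Turtles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to describe temperature-dependent sex determination (TSD) in
    sea turtles, centred on the leatherback (Dermochelys coriacea). Fits the
    asymmetric 'flexit*' sex-ratio curve (pivotal temperature, two limb slopes
    blended by a quasi-binary threshold) to clutch-level sex counts by adaptive
    Metropolis-within-Gibbs MCMC, optionally with nested random effects
    (RMU/study/clutch) on all three curve parameters. Also fits a 4-parameter
    Schoolfield thermal reaction norm of embryonic growth to incubation
    durations, integrates embryo size over fluctuating nest temperature series
    to delineate the thermosensitive period, computes growth-rate-weighted
    constant-temperature equivalents (CTE), and compares models with AICc and
    Akaike weights evaluated per posterior draw. Includes generators of
    synthetic sex-count and nest-temperature data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
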