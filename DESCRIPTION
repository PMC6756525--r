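Package: raftdives
Title: Social Diving Dynamics in Seabird Foraging Rafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying collective diving in surface-foraging seabird
    rafts. Simulates rafts of loosely aligned surface swimmers whose dives
    follow a two-rate social hazard (an intrinsic rate and an elevated rate
    after a conspecific dive within a lag window, detection distance and
    visual arc), renders synthetic overhead video and tracks it back to
    trajectories (frame averaging, blob detection, perspective correction,
    Kalman prediction with auction assignment, dive detection), infers the
    interaction parameters by component-wise Metropolis MCMC, compares model
    variants by WAIC, and computes relative-position, relative-heading and
    dive-following statistics with a permutation null and a wave diagnostic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
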