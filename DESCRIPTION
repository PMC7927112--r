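Package: openmarkov
Title: Open Markov Chain Population Models: Simulation and Exact Moment Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for open Markov chains: systems of non-interacting
    particles hopping on a finite state space according to a sub-stochastic
    jump matrix, with stochastic immigration from a reservoir and
    state-dependent emigration back to it. Provides exact forward simulation
    by multinomial redistribution, a moment-generating-function calculus for
    the occupancy distribution, first- and second-cumulant recursions with
    stationary solutions via a discrete Lyapunov (Stein) equation, outflow
    statistics by binomial thinning, two-time autocovariances, and a
    brute-force probability-table oracle for small systems. Results are
    returned as tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
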