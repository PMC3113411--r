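Package: neuroring
Title: Real-Time Neural-Interface Processing Ring with Simulated ECoG and
    Population-Vector Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless, deterministic implementation of the classic
    three-engine brain-machine-interface architecture: an acquisition engine
    (directionally tuned synthetic ECoG or a raw binary UDP stream), a
    signal-processing engine (autoregressive band-power features, pseudo-Z
    normalization, population-vector and push-pull decoders with
    target-shuffle feature selection), and an application engine (center-out
    cursor task) connected in a closed processing ring. Every frame is
    packet-indexed; sampled variables and parameter changes are streamed to
    an index-keyed run file that supports bit-exact replay and MAT export.
    Includes a scripted end-to-end session workflow (baseline, decoder
    training, closed-loop control) and timing benches for processing time,
    display refresh, and input-to-output latency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
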