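Package: cstrial
Title: Complex-Spike-Linked Single-Trial Plasticity in Cerebellar Purkinje Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of complex-spike (CS) occurrence, CS
    duration, and CS-contingent trial-over-trial plasticity of simple-spike
    firing in cerebellar Purkinje cells during smooth-pursuit direction
    learning, together with the measurement and statistical pipeline used to
    analyse such recordings: trial pairing, analysis-window means,
    reciprocal-interval firing-rate estimation, 10-trial binning, binned
    duration-probability correlations, temporal correlations of CS duration
    with a random-pair control, partial correlations of plasticity against CS
    probability and duration, and parameter sweeps over the underlying
    duration-probability correlation and the temporal correlation imposed by
    a sort-and-swap procedure. A synthetic-session generator emulates the
    three instruction paradigms (repeated, random, alternating) so the whole
    pipeline is testable end to end without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
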