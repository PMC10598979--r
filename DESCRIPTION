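Package: ventasync
Title: Detection and Typing of Patient-Ventilator Asynchrony from
    Pressure-Volume Loop Hysteresis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection and classification of patient-ventilator
    asynchrony from ventilator airway-pressure and flow waveforms. Each
    breath's pressure-volume loop is split at peak volume into inspiratory
    and expiratory half-cycles, each half-cycle is approximated by an
    r-segment piecewise linear regression found by exhaustive breakpoint
    search (dynamic programming over prefix segment costs), and the segment
    count is selected by an F-ratio hypothesis cascade against a model
    variance calibrated from non-asynchronous breaths. Sign patterns of the
    fitted segment slopes (local elastances), breakpoint volumes and
    pressures map each breath to one of seven asynchrony types: flow
    asynchrony, reverse triggering, premature cycling, double triggering,
    delayed cycling, ineffective effort and auto triggering. Includes a
    single-compartment ventilated-breath simulator that generates
    ground-truth-labelled waveforms for all seven archetypes, plus
    sensitivity/specificity/accuracy scoring and windowed incidence
    reporting for monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
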