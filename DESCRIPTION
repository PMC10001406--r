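Package: meaflow
Title: Microelectrode-Array Spike-Train Analysis for Neural Culture Maturation and Neuroinflammation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multichannel extracellular recordings from
    in vitro neural cultures on microelectrode arrays (MEAs): zero-phase
    high-pass filtering and threshold spike detection, active-channel census,
    max-interval burst detection, SPIKE-distance spike-train synchrony,
    trough-to-peak waveform width classification of putative excitatory and
    inhibitory units, and longitudinal B-spline mixed-model statistics with
    marginal-mean contrasts and Holm-Bonferroni adjustment. Includes a
    ground-truthed synthetic-recording generator emulating culture maturation
    over days in vitro and lipopolysaccharide-induced neuroinflammatory
    decline, used to validate every stage of the pipeline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    splines,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
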