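Package: crabloom
Title: Looming Spatial Localization with an MLG1-Inspired Panoramic Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational model of the looming-sensitive MLG1 neuron ensemble
    of the crab Neohelice granulata. A panoramic visual field is divided into
    16 overlapping azimuthal sectors, each served by a layered motion-detecting
    network (photoreceptor, lateral inhibition, grouping, and a sigmoidal unit
    with spike-frequency adaptation and feed-forward inhibition). A
    winner-take-all layer weighted toward early alarms reports the azimuthal
    sector of an approaching object, and a global feed-forward-inhibition vote
    vetoes spikes during whole-field self-rotation. Includes a deterministic
    synthetic panoramic stimulus generator (looming, receding, rotating,
    passing-by and static scenes) so every behaviour is testable without
    recorded video, plus readers and writers for frame stacks, tidy
    time-series output and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
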