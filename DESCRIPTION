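Package: elbownms
Title: EMG-Driven Neuromusculoskeletal Model of Elbow Muscle Torque
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Planar Hill-type neuromusculoskeletal model of the human elbow
    for flexion-extension muscle torque estimation. Six muscles (long and
    short heads of biceps brachii, brachialis, and the three heads of triceps
    brachii) are modelled with Thelen-style force-length, force-velocity and
    passive-force curves, triangular flexor path geometry and a trochlea-arc
    extensor path, and assembled into a resultant elbow torque. Includes the
    classic two-muscle baseline model, a generator for planned joint-angle
    trajectories and computed-muscle-control-like activation traces,
    model-agreement statistics (Pearson correlation, one-way ANOVA with
    correlation-strength labels), and readers and writers for CSV and
    OpenSim-style .sto/.mot time-series files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
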