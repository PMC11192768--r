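Package: lochip
Title: Valve-Control Scripting, Digital-Twin Simulation and Fluorescence
    Detection for Lifting-Gate Lab-on-a-Chip Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale control stack for pneumatically actuated
    polydimethylsiloxane (PDMS) lab-on-a-chip devices. Provides a minimal
    valve-control scripting language (open/close/wait plus user-defined
    functions) with a parser, static validator and interpreter; a digital-twin
    simulator of a 15-valve lifting-gate optofluidic chip that tracks nanoliter
    fluid parcels and reagent composition through actuation sequences; a
    synthetic fluorescence video generator and single-particle burst detector
    (region-of-interest integration, median/MAD thresholding, per-event
    confirmation windows); and an in-process publish/subscribe service with
    MQTT-style topics for remote valve commands, script upload and execution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
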