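Package: strikepath
Title: Two-Phase Probability Model of Animal-Vehicle Collisions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the outcome of an encounter between an escaping animal
    and a vehicle approaching on a fixed linear trajectory. Phase one decides,
    from escape speed, escape angle, sensory-motor delay and flight-initiation
    distance, whether the animal clears the vehicle's swept trajectory in time;
    phase two converts the animal's position within the trajectory into a
    collision probability by integrating the vehicle's pixelized frontal
    silhouette over a body-length-wide collision window. Ships a parametric
    generator for airliner-like frontal silhouettes, stochastic behavioral
    scenarios for onboard-lighting interventions (escape-angle mixtures and
    light-extended flight-initiation distances), a seeded Monte-Carlo
    parameter-sweep engine with streaming aggregation, and a command-line
    interface. The bundled application estimates collision probabilities for a
    Canada goose in the path of a Boeing-737-class aircraft with and without
    onboard lights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
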