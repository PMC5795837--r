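Package: ebiketrainer
Title: Personalized Assist-Level Training for Pedal-Assist Electric Bicycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans and evaluates training rides on pedal-assist (PAS) electric
    bicycles. Routes read from GPX or CSV tracks are segmented by slope
    magnitude, the cycling power equation (rolling, aerodynamic and gravity
    terms) is evaluated and inverted to find the power needed to hold a target
    speed on each segment, and the shortfall between that power and a constant
    rider contribution is quantized onto the bike's discrete motor assist
    levels. Completed rides are scored by the energy the rider supplied, with
    scores accruing toward an ability-level ladder that raises the target
    speed over time. Includes age-predicted maximum heart rate, training-zone
    classification with a safety override, a ride-telemetry simulator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    optparse,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
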