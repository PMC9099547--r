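Package: frailtykit
Title: Ambient-Sensor Frailty Indicators and Concurrent-Validity Statistics
Version: 0.1.0
Authors@R:
    person("FrailtyKit", "Developers", email = "frailtykit@example.org",
           role = c("aut", "cre"))
Description: Derives frailty indicators from heterogeneous ambient-sensor
    event streams recorded in a single-occupant home: sedentary bouts from a
    pressure mat, stair-climbing times from paired ultrasonic distance
    sensors, room-presence durations from passive-infrared motion sensors,
    and confirmed outings from a door contact.  A deterministic smart-speaker
    dialogue models self-report exhaustion, and per-criterion flags aggregate
    into a Fried-phenotype frailty state.  Concurrent validity against
    ground-truth activity logs is assessed with Cohen's kappa, Bland-Altman
    limits of agreement with a 20-percent outside rule, detection rates,
    Pearson correlation, and proportional-bias regression.  A HomeLab
    activity simulator replays a three-run test protocol through per-sensor
    observation models (missed detections, latency jitter, occupancy
    flicker) so the whole derivation-plus-validation pipeline runs with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
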