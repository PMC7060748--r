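Package: nursekin
Title: Nursing Kinematics from Whale-Borne Motion Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of nursing behavior in baleen whale mother-calf pairs
    from suction-cup video and motion tags. Reads multichannel tag records
    and behavioral event logs, decimates and rotates raw accelerometer
    streams into the whale frame, computes overall dynamic body acceleration
    (ODBA), orientation angles and fluke-stroke rates, partitions dives into
    descending, horizontal and ascending phases, draws randomized
    phase-matched non-nursing baseline segments, fits mixed-effects
    nursing-versus-baseline comparisons, and summarizes nursing, proximity
    and foraging time budgets. Ships a seeded generator of synthetic mother
    and calf deployments with ground-truth event logs for end-to-end
    validation, plus in-package fixture tables of published deployment
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    nlme,
    signal,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
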