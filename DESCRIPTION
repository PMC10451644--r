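Package: lorawalk
Title: Daily Distance Walked from LoRa-WAN Livestock Tracker Telemetry
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for low-power wide-area-network (LoRa-WAN)
    livestock trackers that report GPS positions every 15 minutes and
    accelerometer motion counts every minute. Provides transverse-Mercator
    (UTM) projection of fixes, per tracker-day z-score screening of erroneous
    positions, fusion of GPS fixes with cumulative Motion Index counts, three
    daily distance-walked algorithms (RawDist, CorrectedDist,
    CorrectedDist_Act), mixed-model comparison of tracker placements with
    least-squares means and compact letter displays, and a synthetic-data
    generator that emulates a deployment of static indoor/outdoor reference
    trackers alongside collared grazing cattle, so the whole pipeline can be
    exercised and validated without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
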