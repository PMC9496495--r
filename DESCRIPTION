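Package: actisleep
Title: Sleep Scoring and Device Agreement for Minute-Level Wearable Epoch Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores minute-by-minute wearable epoch streams (a lying-down
    indicator plus a binary sleep/wake indicator) into nightly indices of
    sleep quantity, timing, and quality: bedtime, sleep onset, sleep offset,
    waketime, time in bed, total sleep time, sleep efficiency, sleep onset
    latency, wake after sleep onset, sleep fragmentations, sleep regularity,
    and midpoint of sleep. Days run noon to noon so a night is never split.
    Includes weekly per-subject summaries, a two-device agreement battery
    (paired equivalence tests by TOST, repeated-measures Bland-Altman limits
    of agreement with variance components, Shrout-Fleiss intraclass
    correlations, and epoch-level sensitivity/specificity with likelihood
    ratios), and a seeded synthetic two-device study simulator for end-to-end
    validation without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
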