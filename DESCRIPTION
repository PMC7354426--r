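Package: spiderstat
Title: Static Force Modelling for Elastic-Cord Body-Weight Support Cages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for cage-and-elastic-cord body-weight support devices
    used in rehabilitation. Fits three-term sum-of-sines tension models to
    bench force-elongation measurements of elastic cords (expanders), resolves
    the tensions of a set of installed cords together with gravity into a
    resultant force at the body's centre of gravity and ground reactions at
    the two foot contacts, reports unweighting (or loading) as a fraction of
    body weight with per-foot heel and toe load classification, and solves the
    inverse problem of finding the cord elongation or anchor height that
    achieves a prescribed unweighting. Includes a seeded synthetic bench-data
    generator and calibrated reference cord characteristics so every analysis
    is reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
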