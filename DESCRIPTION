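Package: tierscreen
Title: Three-Tier Screening for Falsified Artemether-Lumefantrine Tablets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a tiered screening pipeline for detecting falsified
    artemether-lumefantrine (AMLF) tablets: Tier I compares tablet weight and
    dimensions against specification ranges; Tier II screens nondestructive
    photometric readings (fluorescence gray values against an authentic
    reference band, and the laser-transmission W statistic against an
    authentic reference range, with an exact Mann-Whitney group test); Tier
    III quantifies lumefantrine and artemether from RGB images of 96-well
    plates via the normalized channel ratios RvsB and RvsG, linear
    calibration, and percent-API relative to an authentic reference tablet.
    Includes a fully seeded synthetic-data generator (measurement tables,
    plate and tablet-fluorescence images, laser readings) so the whole
    pipeline is testable offline, and report writers that integrate the tiers
    into a per-sample verdict table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
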