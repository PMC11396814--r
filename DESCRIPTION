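Package: windfirm
Title: Mechanistic Assessment of Conifer Resistance to Wind-Induced Uprooting
Version: 1.0.0
Authors@R:
    person("Forest", "Biomechanics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a static mechanistic model of coniferous-tree
    resistance to wind-induced uprooting. The wind overturning moment on a
    conical crown is compared against the resistive moments of the stem and
    of the root plate, modelled as a half-ellipsoid of coarse roots and
    enclosed soil. The wind-independent resistance index Delta-prime is
    calibrated against uprooted-tree reference data to yield three-level
    hazard classifications (High/Moderate/Low). Also provides
    ground-penetrating-radar coarse-root density summaries with one-way
    ANOVA and Tukey HSD compact letter displays, soil physical property
    calculations, CSV readers/writers with packaged reference tables, a
    command-line pipeline, and a synthetic stand generator for end-to-end
    testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
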