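Package: evdrift
Title: Buoyant-Density Equilibrium Profiling of Extracellular Vesicle Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Determines equilibrium buoyant densities of extracellular-vesicle
    (EV) proteins from bidirectional density-gradient fractionation combined
    with label-free mass-spectrometric quantification. Per-unit (specimen x
    direction) log10 abundance profiles are normalized by their maximum, the
    peak fraction density (PFD) of each protein is located on the measured
    density ladder of each tube, and agreement of the peak density between the
    downward (spin-down) and upward (float-up) separations defines attainment
    of equilibrium. Proteins at equilibrium in every specimen are partitioned
    into drift-pattern subgroups (specimen-specific PFD tuples) and a
    constant-density subgroup; proteins that equilibrate in no specimen form a
    separate class. Includes strict TSV ingest/export, an SVG heat-map renderer
    on a common measured-density axis, a seeded synthetic-data generator with
    planted ground truth, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
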