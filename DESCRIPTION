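Package: nestshare
Title: Communal Nursing Decisions and Partner Choice in Wild House Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for analysing female communal
    nursing decisions in free-living house mouse colonies monitored with RFID
    antennas at nest boxes. From an antenna event log, a litter table,
    multilocus microsatellite genotypes, a pedigree and a nest-box layout, the
    package derives per-female home areas and dyadic association times,
    constructs choice sets of potential nursing partners, estimates pairwise
    relatedness (Wang and Queller-Goodnight moment estimators with a
    pedigree-based calibration procedure), quantifies spatial genetic
    autocorrelation across nest-box distance classes with permutation and
    bootstrap inference, and fits the nest-availability power model y ~ P^a
    together with discrete-choice models of the decision to nurse communally
    and of partner choice. A seeded agent-based colony simulator emulating the
    barn study design (kin-clustered settlement, Mendelian genotype
    transmission, configurable decision rules) provides ground truth for every
    downstream inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
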