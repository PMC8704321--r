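Package: ternact
Title: Ternary Ligand-Target Activity Relations, Data Completeness, and
    Polypharmacology Bounds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Represents thresholded ligand-target bioactivity datasets as
    ternary relations in which every ligand-target pair is exactly one of
    active, inactive, or null (never measured), and treats the null state as
    first-class information rather than lumping it with the inactives.
    Provides set-theoretic projections to per-ligand and per-target activity
    profiles, global and local data-completeness measures with their
    distribution summaries, and interval-valued estimates of simple and joint
    polypharmacology: lower bounds from known actives, upper bounds from null
    pairs, urn-model probability estimates of the active fraction among null
    pairs, Jeffreys confidence intervals, and Monte Carlo propagation for
    joint estimates over ligand pairs. Includes readers and writers for
    raw-measurement and status-table formats with Kd/Ki thresholding and
    conflict resolution, a synthetic-data generator with known ground truth
    for estimator validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
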