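Package: scmixstr
Title: Single-Cell STR Profile Simulation and DNA Mixture Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting forensic DNA mixtures at single-cell
    resolution. Simulates single-cell short tandem repeat (STR) profiles from
    related or unrelated contributors under explicit allele drop-out and
    drop-in models, estimates the number of contributors by model-based
    clustering with silhouette selection or identity-by-state thresholding,
    builds per-contributor consensus profiles by majority vote, and attributes
    sources via identity-by-state counts and likelihood ratios that account
    for drop-out, drop-in and population substructure. Includes a scenario
    runner that evaluates number-of-contributors and consensus accuracy over
    replicated simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    foreign,
    jsonlite,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
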