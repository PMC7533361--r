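Package: glutenPRM
Title: Targeted Parallel-Reaction-Monitoring Quantification of Immunogenic
    Gluten Peptides
Version: 0.1.0
Authors@R:
    person("Theo", "Mercer", email = "theo.mercer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for targeted parallel-reaction-monitoring (PRM) mass
    spectrometry of immunogenic gluten peptides released during simulated
    gastrointestinal digestion of food. Computes peptide and b/y/a fragment-ion
    monoisotopic m/z (including a single stable-isotope label), scans sequences
    for celiac epitope core motifs, builds and validates scheduled PRM
    inclusion lists, plans modified INFOGEST digestion experiments (simulated
    fluid recipes, phase volumes, TFA quench volumes), simulates extracted-ion
    chromatograms with known ground truth, and quantifies peptides against
    external calibration curves with ICH residual-based limits of detection
    and quantification, matrix-effect and day-to-day replicability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
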