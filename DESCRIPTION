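Package: oxSelMS
Title: Selective Ionization Analysis of Oxidized Triacylglycerols in
    Flow-Injection ESI-MS
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and optimizing the selective ionization of
    oxidized triacylglycerols (oxTAGs) relative to their non-oxidized
    precursors in positive-mode flow-injection ESI-MS. Implements a
    combinatorial model that converts NMR-measured oxidation-group
    concentrations (aldehyde, epoxide, hydroperoxide) into a TAG
    oxidation-degree distribution, theoretical adduct m/z targeting and
    mass-window definitions, a composition-normalized selectivity factor
    computed from mass windows or extracted-ion signals, a regular three-level
    fractional factorial design over five ionization factors, ANOVA with
    Tukey comparisons for selecting optimal ionization conditions, and a
    seeded synthetic-spectrum generator with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    mzR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: MassSpectrometry, Lipidomics, Metabolomics, ExperimentalDesign
RoxygenNote: 7.3.3
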