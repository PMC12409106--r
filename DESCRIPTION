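Package: spectevol
Title: Adaptive Divergence Inference from Leaf Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer adaptive divergence among plant species and
    populations from dried-leaf reflectance spectra and neutral molecular
    markers. Provides spectral preprocessing (splice correction, resampling,
    summed Mexican-hat continuous wavelet transform, region slicing,
    vegetation indices), PLSR trait prediction and PLS-DA classification with
    VIP band selection, Weir-Cockerham F_ST with locus bootstrap confidence
    intervals and hierarchical AMOVA on microsatellite genotypes, P_ST-F_ST
    divergence testing over a c/h2 sensitivity grid, partial redundancy
    analysis partitioning of phenotypic variance into isolation-by-environment
    and isolation-by-distance fractions, Blomberg's K phylogenetic signal
    mapping across the spectrum with white-noise and Brownian-motion nulls,
    phylogenetic generalized least squares trait-climate models, and a
    synthetic-data generator with known ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    mixOmics
Config/testthat/edition: 3
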