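Package: qkforest
Title: Association Mapping with Structure Correction, Kinship and Random
    Forests for Dominant Marker Collections
Version: 0.1.0
Authors@R: person("qkforest", "maintainers", email = "qkforest@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for single-marker association studies in
    admixed germplasm collections genotyped with dominant binary markers
    (AFLP-type bands, binarized SSR alleles). Infers population structure by
    principal coordinate analysis with kernel-density mode clustering and by
    a haploid Bayesian admixture Gibbs sampler; computes marker-based
    kinship; fits four association models of increasing complexity (naive,
    structure covariates Q, kinship random effect K via spectral REML, and
    the combined Q+K mixed model); corrects for multiple testing by
    Benjamini-Hochberg FDR and step-down maxT resampling; ranks markers with
    a bagged regression-forest importance measure tested against a per-marker
    permutation null; and summarises correlated metabolite-style traits as a
    full-order partial-correlation network with Pajek export. Includes a
    synthetic-data generator with known ground truth for admixed populations,
    confounded phenotypes and polygenic covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
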