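Package: ornrbe
Title: Empirical Proton RBE Estimation for Mandible Osteoradionecrosis
Version: 0.1.0
Authors@R: person("ORN-RBE", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to derive empirical proton relative biological
    effectiveness (RBE) for mandible osteoradionecrosis (ORN) from
    head-and-neck radiotherapy cohorts. Computes dose-volume histograms
    (DVH), DVH indices and dose-LET volume histograms (DLVH) from voxel
    samples; constructs 1:1 propensity-matched photon/proton cohorts by
    greedy nearest-neighbor matching; derives dose-volume constraints at
    the ROC optimal operating point with bootstrap confidence intervals;
    and converts modality-specific volume tolerance curves into photon
    equivalent constraint doses and empirical RBE values. A calibrated
    synthetic-cohort generator with a configurable LET-dependent
    ground-truth RBE supports end-to-end validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
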