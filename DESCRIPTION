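Package: motility3d
Title: Quantitative Analysis of 3D Cell Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-cell motility metrics for 3D cell tracks from intravital
    time-lapse imaging: cell-based and displacement speeds, turning angles
    and speed-angle coupling, speed persistence likelihood, anomalous
    diffusion exponents from mean-squared-displacement regression,
    meandering ratio, confinement detection, and voxelized patrolled-volume
    rates. Includes time-step normalization with phase-complete
    subsampling, a nonparametric group-comparison layer (Mann-Whitney and
    Kolmogorov-Smirnov tests with Bonferroni correction, one-way ANOVA
    across imaging fields with greedy outlier-frame reduction), and
    seedable 3D random-walk generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
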