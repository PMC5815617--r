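Package: gaitterrain
Title: Cross-Slope Terrain Classification from Residual-Limb Gait Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Offline pipeline for predicting cross-slope terrain (eversion,
    flush, inversion) from multichannel residual-limb gait recordings of
    transtibial prosthesis users. Provides signal conditioning (zero-phase
    Butterworth low-pass filtering, body-weight normalization,
    swing-referenced ankle angles, numerical differentiation),
    heel-strike-anchored sliding-window feature extraction, a pooled-covariance
    linear discriminant classifier with optional shrinkage, sequential
    forward/backward wrapper selection over input signals, leave-one-trial-out
    and train/test evaluation with confusion matrices, and a synthetic stride
    generator for end-to-end testing without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    signal,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
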