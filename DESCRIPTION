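Package: cnparcel
Title: Microstructural Parcellation of the Caudate Nucleus from Diffusion MRI
Version: 0.1.0
Authors@R: person("cnparcel", "developers", role = c("aut", "cre"),
    email = "cnparcel@example.org")
Description: Tested pipeline for parcellating an arc-shaped gray-matter
    nucleus (the caudate) from diffusion-weighted MRI: diffusion-tensor
    fitting with FA and direction-coded colour maps, a longitudinal
    smoothing-spline axis parameterised by the angle about the anterior
    commissure, a radiality-index profile along that axis, detection of the
    two microstructural boundaries (45-degree crossing and near-head local
    minimum) that define an anterior/middle/posterior tri-partition,
    constrained streamline tractography with declarative inclusion/exclusion
    bundle rules and per-subregion endpoint target maps, and a
    polarized-light-imaging forward/inverse module for histological
    validation. A multi-compartment phantom generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
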