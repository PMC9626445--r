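Package: gliomech
Title: Biphasic Poroelastic Simulation of Brain Tumour Growth with Fibre Reorientation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulator for the mechanically coupled growth of a
    brain tumour inside the skull-confined brain. Both tumour and host tissue are
    treated as saturated biphasic mixtures of a Mooney-Rivlin hyperelastic cell
    phase and an interstitial fluid obeying Darcy's law with a Holmes-Mow,
    deformation-dependent permeability. Growth enters through a multiplicative
    elastic/growth decomposition of the deformation gradient with an isotropic,
    nutrient-driven and optionally stress-inhibited growth law. Diffusion and
    permeability tensors built from (synthetic) diffusion-tensor-imaging voxel
    grids are reoriented by the computed deformation, and the package reports
    tumour volume dynamics (doubling time, specific growth rate, radial expansion
    velocity), solid stress and pressure maps, and fractional-anisotropy change
    maps. Includes a synthetic "brain phantom" generator (ball meshes, smooth
    tumour indicators, controllable-anisotropy DTI grids) so the full pipeline
    runs without clinical data. Units are fixed as mm / day / MPa.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
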