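Package: fibremech
Title: Diffusion-MRI Fibre Architecture to Finite-Element Muscle Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for building fibre-annotated finite-element
    models of skeletal muscle from diffusion-weighted MRI and exercising them
    mechanically. Covers mosaic-to-volume assembly, acquisition averaging and
    local-PCA Rician denoising, diffusion-tensor fitting and deterministic
    streamline tractography, bundling of fibre strands by cropping boxes,
    tetrahedral mesh handling with rigid ICP registration and binary-mask
    smoothing, mapping of numbered fibre strands onto element-wise fibre
    directions with Gaussian radial-basis smoothing, a transversely isotropic
    hyperelastic muscle constitutive law with active and passive fibre
    stress, a strain-time deep-tissue-injury threshold model, and a minimal
    static total-Lagrangian tetrahedral Newton solver with material-point
    protocols. Synthetic phantom generators make every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
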