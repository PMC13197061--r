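Package: cortexdiff
Title: Conditional Spherical Diffusion Models for Cortical Surface Normative Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for normative modeling of cortical surface morphometry with
    anatomy-conditioned denoising diffusion probabilistic models on icosahedral
    spherical meshes. Provides hierarchical icosphere construction with
    prefix-ordered subdivision, 1-ring spherical convolution and order-prefix
    pooling, a conditional spherical UNet denoiser trained with
    v-parameterization and a cosine noise schedule, pseudo-healthy
    partial-noise reconstruction, ROI-level abnormality z-scores against
    generated reference sets, a synthetic cortical cohort generator with
    mask-correlated features and injected atrophy, surface map metrics
    (MSE, spherical SSIM, Frechet distance), and FreeSurfer curv/annot/surface
    file readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
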