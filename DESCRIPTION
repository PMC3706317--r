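Package: mapprofile
Title: Multiscale Comparison Map Profiles for Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing gridded species distribution model outputs
    at multiple spatial scales using the Comparison Map Profile (CMP)
    method: circular moving-window Cohen's kappa, absolute distance and
    cross-correlation, per-scale index profiles and multiscale maps.
    Includes ROC-based model validation (AUC, species presence threshold,
    global kappa), a bioclimatic-limit nesting decomposition for hybrid
    growth models, a random-pattern null baseline, and synthetic climate
    and toy model generators so the whole workflow runs without external
    datasets. Raster I/O covers ESRI ASCII grids and single-band float
    TIFF with world files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
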