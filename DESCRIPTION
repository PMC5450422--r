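Package: leafletkit
Title: Quantification and Classification of Blade and Serration Features
    of Compound Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated morphometrics for scanned compound (trifoliate)
    leaves. Segments leaf tissue from dark or gray scanner backgrounds,
    removes trichomes by YCbCr chroma analysis or spectral low-pass
    filtering, separates terminal and lateral leaflets at blade-stalk
    junctions found from centroid radial profiles, and measures blade
    (length, width, area, symmetry, compactness) and serration (tooth and
    sinus) geometry from every boundary pixel. Computes elliptic Fourier
    descriptors (120 harmonics) with Delta/Alpha/Beta band powers, the
    half-power frequency, and band-limited shape reconstruction. Includes
    group statistics (ANOVA, Kruskal-Wallis, confidence-interval
    comparisons), k-means and feedforward neural-network classification of
    leaflet groups with genetic-algorithm feature-subset selection, 3D
    morphospace ellipsoids, a seeded synthetic trifoliate-leaf generator
    with full ground truth, and a batch pipeline with CSV export and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    nnet,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
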