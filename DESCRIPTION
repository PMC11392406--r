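Package: lumenfit
Title: Contour-Based Reconstruction of Tubular Vessel Surfaces and Cell Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the apico-luminal surface of approximately straight
    blood vessels (such as the zebrafish dorsal aorta) from manually annotated
    3D endothelial cell junction contours alone. Cross-sections are modelled as
    two joined half-superellipses with independent dorsal and ventral exponents,
    fitted locally along the vessel axis by constrained weighted least squares
    with truncated Gaussian weights, smoothed, and sampled into an organized
    point cloud. Cell contours are projected onto this grid and triangulated
    into per-cell surface meshes from which vessel geometry (luminal area,
    diameter) and 3D cell morphology (surface area, perimeter, compactness,
    elongation, sector classification) are quantified. Includes a synthetic
    vessel generator, goodness-of-fit measures, plane slicing for validation
    against angiogram outlines, and VTK mesh export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
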