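Package: lvspline
Title: Trivariate B-Spline Solid Models and Isogeometric Strain Analysis of the Left Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds smooth solid models of the left-ventricular myocardium from
    slice-stacked endocardial and epicardial wall point clouds, such as contours
    segmented from short-axis cine MRI. Wall surfaces are fitted as periodic
    tensor-product B-spline surfaces, swept into a hexahedral control mesh, and
    assembled into a trivariate B-spline solid. Displacements between cardiac
    phases are carried on the control mesh and differentiated isogeometrically
    (the geometry's own spline basis is the displacement basis) to yield
    continuously distributed infinitesimal strain and, through an isotropic
    linear-elastic constitutive matrix in Voigt notation, stress, with principal
    values and directions. Includes a synthetic ventricle generator (truncated
    prolate-spheroid walls with prescribed deformations and known ground-truth
    strain), a cylindrical-coordinate model representation, Jacobian-based
    volume quadrature, and VTK/CSV field export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    splines,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
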