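Package: sedsphere
Title: Unsteady Sedimentation of a Single Sphere with Basset History Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for planning and interpreting gravimetric sedimentation
    assays on single spherical particles whose density is close to that of the
    suspending fluid (e.g. water-swollen pharmaceutical microspheres). Solves
    the transient equation of motion including quasi-steady drag, added mass
    and the windowed Basset history force; provides a registry of standard
    drag-curve correlations (Schiller-Naumann, Clift-Grace-Weber, Brown-Lawler,
    Flemmer-Banks, Terfous-Hazzab-Ghenaim); computes terminal velocity and
    inverts it for density contrast; evaluates the closed-form Laplace-domain
    solution of the linearized settling equation via the Faddeeva function; and
    supplies a-priori estimates of the settling time and settling distance
    needed to measure terminal velocity to a prescribed accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
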