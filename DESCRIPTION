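Package: fetsim
Title: Structural and Haemodynamic Simulation of Frozen Elephant Trunk Elastic Recoil
Version: 0.1.0
Authors@R:
    person("fetsim", "developers", email = "fetsim@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation pipeline for the mechanical environment at the
    distal edge of a frozen elephant trunk (FET) prosthesis in an idealized aorta.
    Generates parametric aortic and device geometry, solves the two-stage
    deploy-then-release elastic-recoil problem with frictionless penalty contact
    (planar co-rotational beam finite elements plus axisymmetric thick-wall and
    shell theory), couples a pulsatile incompressible Navier-Stokes solver
    (streamfunction-vorticity, planar and axisymmetric modes) to three-element
    Windkessel outlet models, and post-processes wall shear stress, oscillatory
    shear index, wall shear stress divergence, circumferential-stress path
    profiles, bending angle, and notch geometry over a sweep of device
    oversizing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
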