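Package: mempeel
Title: Peeling Dynamics of Fluid Membranes Bridged by Mobile Molecular Bonds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechano-chemical simulation of forced peeling of two adhered
    fluid membranes bridged by mobile, transient molecular bonds. Couples a
    quasi-static vesicle-scale capillary model (Young-Dupre / Young-Laplace),
    a micro-mechanical model of the adhesion patch (membrane bending on a
    bond elastic foundation), and reaction-diffusion transport of bonds and
    free binders on a moving domain with Stefan-type interface conditions.
    Includes the closed-form similarity solution of the diffusion-dominated
    (Stefan) regime, Bell slip-bond kinetics, Flory-Huggins crowding
    thermodynamics, travelling-front speed estimation, and failure-time
    strength analysis with power-law fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
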