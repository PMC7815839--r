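Package: nqemd
Title: Nuclear Quantum Effects in Molecular Interactions via Machine-Learned
    Force Fields and Path-Integral Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for studying how nuclear quantum effects
    (zero-point motion, tunnelling, delocalization) strengthen covalent and
    non-covalent molecular interactions. Provides symmetrized gradient-domain
    kernel regression of molecular force fields trained on forces and
    energies, classical Langevin and path-integral (ring-polymer) molecular
    dynamics with primitive and centroid-virial quantum kinetic-energy
    estimators, a family of analytic model potentials (bond-coupled methyl
    rotor, steep power-law attraction, partial-charge electrostatics, Morse
    dimer with damped dispersion tail) together with a Boltzmann sampler for
    generating training sets, and the post-processing operators used to
    characterise quantum strengthening: free-energy surfaces from
    trajectories, rotor-localization detection, log-log power-law interaction
    fits, and Casimir-Polder C6 dispersion coefficients from Drude-oscillator
    polarizabilities. Reads and writes extended-XYZ configurations and
    named-array (z/R/E/F) force-field dataset archives.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, pracma, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
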