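Package: mpsdyn
Title: Coarse-Grained Langevin Dynamics of Magnetic Polymersomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a magnetic polymersome: a vesicle whose membrane is
    modelled as two concentric triangulated elastic shells confining a
    monolayer of dipolar magnetic nanoparticles. The shells are spring
    networks (neo-Hookean edges, local-area constraints, radial tethers)
    built on Fibonacci-lattice sphere meshes; nanoparticles carry permanent
    magnetic moments and interact through dipole-dipole, Zeeman and
    Weeks-Chandler-Andersen excluded-volume couplings. The coupled
    translational and rotational Langevin equations are integrated with a
    stochastic velocity-Verlet (BAOAB) scheme. Includes mappings between
    physical material parameters and reduced simulation units, a
    preparation protocol (thermalisation, ground state, quasi-static field
    ramp), and observables: mean-square displacement, cluster statistics,
    magnetization, and the field dependence of the vesicle aspect ratio
    with sigmoid fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
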