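Package: minimm
Title: A Desk-Scale Extensible Molecular Dynamics Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A compact molecular dynamics engine built around extensibility:
    algebraic energy expressions are parsed and differentiated analytically to
    obtain forces; integration algorithms are written as small programs in a
    per-degree-of-freedom computation language; virtual interaction sites
    follow a generalized three-parent construction with analytic force
    redistribution; periodic boundaries support arbitrary triclinic cells
    (including rhombic dodecahedron and truncated octahedron); forces can be
    accumulated in deterministic 64-bit fixed point under single, mixed, or
    double precision modes. Reads Amber prmtop/inpcrd topologies, supports
    OBC1 generalized Born implicit solvent, SHAKE/RATTLE constraints,
    hydrogen mass repartitioning, energy minimization, and per-category
    energy decomposition reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), bio3d, jsonlite, yaml, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
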