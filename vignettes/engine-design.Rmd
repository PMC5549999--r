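---
title: "minimm: design and numerical choices of a desk-scale MD engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{minimm: design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimm)
```

## What this package is

`minimm` is a small molecular dynamics engine organized around
extensibility rather than raw speed: interactions are defined by algebraic
energy expressions that the engine differentiates analytically to obtain
forces, and integration algorithms are written as short programs in a
per-degree-of-freedom computation language. Around that core sit the
pieces a working engine needs: triclinic periodic cells, SHAKE/RATTLE
constraints, generalized three-parent virtual sites, an OBC1 implicit
solvent, an Amber prmtop/inpcrd input pipeline with per-category energy
decomposition, and a force dispatcher with single/mixed/double precision
modes and deterministic 64-bit fixed-point force accumulation.

All quantities use one internal unit system: nm, ps, amu, kJ/mol,
elementary charge, kelvin. In these units the Boltzmann constant is
`r format(KB)` kJ/mol/K and the Coulomb prefactor is 138.935456
kJ mol^-1 nm e^-2; file readers convert on input (Amber topologies store
kcal, Angstrom, and charges scaled by 18.2223).

## Energy expressions and analytic forces

An expression such as `"k*(theta-theta0)^2"` is parsed into an AST,
differentiated symbolically with respect to its geometric variable, and
both energy and derivative are compiled into vectorized R closures (R's
byte-code JIT compiles them on first use). A force term then applies the
chain rule through the geometry: bond terms through the pair distance,
angle terms through the standard three-atom angle gradient with
`sin(theta)` clamped at 1e-8 near collinearity, torsion terms through the
signed IUPAC dihedral, and compound/centroid terms through any mixture of
`distance()`, `angle()`, `dihedral()` and raw coordinates.

The function vocabulary is fixed: sin, cos, tan, asin, acos, atan, sinh,
cosh, tanh, exp, log (natural), sqrt, abs, floor, ceil, min, max, step,
delta, and select(cond, a, b). `step(x)` is 1 for x >= 0, `delta(x)` is 1
only at exactly 0, and both differentiate to 0 everywhere, so piecewise
potentials remain usable inside differentiated expressions; min, max and
select differentiate through the active branch. `0^0` evaluates to 1;
division by zero and log of a non-positive number are evaluation-time
errors rather than silent NaNs. Trailing semicolon definitions
(`"E; sig=0.5*(sig1+sig2)"`) provide the combination-rule idiom for pair
potentials; definitions may reference each other in either textual order
and are topologically sorted at parse time, with cycles rejected.

Two independent evaluation paths exist on purpose: compiled closures and
a direct AST interpreter. The test suite holds them to 1e-12 relative
agreement on random expressions, and holds analytic derivatives to 1e-5
against central finite differences (h = 1e-6) away from singularities.

```{r}
pe <- parse_expression("4*eps*((sig/r)^12-(sig/r)^6);
                        sig=0.5*(sig1+sig2); eps=sqrt(eps1*eps2)")
f <- compile_expression(pe, c("r", "sig1", "sig2", "eps1", "eps2"))
f(2^(1/6), 1, 1, 1, 1)     # the Lennard-Jones minimum
```

## The integrator language

A time step is an ordered program of operations over the builtins `x`,
`v`, `f`, `m`, `dt` plus user variables: per-DOF computations evaluated
elementwise on the 3N Cartesian components, global computations, sums
over DOFs, constraint projections, and if/while blocks. Any write to `x`
invalidates the forces, which are recomputed lazily (with virtual sites
repositioned) before the next read of `f` — so a five-line leapfrog costs
exactly one force evaluation per step. `gaussian` and `uniform` draw
fresh values per component per evaluation from a stream keyed by
(seed, step index, evaluation index), which makes trajectories
bit-reproducible without global RNG state. While-loops are capped at 1000
iterations per step to catch non-terminating programs.

The built-in leapfrog is the canonical five-step program (save `x0`,
kick, drift, constrain positions, recompute `v = (x-x0)/dt`); velocities
therefore live at half steps and kinetic-energy reports use them as-is,
with no half-step averaging. The Langevin program uses the per-DOF update
`v <- a v + (1-a) f/(m gamma) + sqrt(kB T (1-a^2)/m) gaussian` with
`a = exp(-gamma dt)`, which reduces exactly to the leapfrog kick-drift at
zero friction. This discretization is validated through its own stated
properties (equipartition on a free particle, determinism, the
zero-friction limit) rather than against any external implementation.

Constraints use one solver for everything: iterative SHAKE on positions
(corrections along reference-geometry directions, inverse-mass weighted,
default tolerance 1e-8, 150 iterations) and RATTLE on velocities. Rigid
water is three distance constraints; there is no analytic SETTLE path —
one solver keeps the correctness surface small at desk scale.

Virtual sites follow the generalized three-parent rule: an origin and two
axis vectors are weighted averages of the parent positions (weights
summing to 1 and 0 respectively, enforced at construction), an
orthonormal frame is built from them, and the site sits at a fixed local
offset. Forces on the massless site are pushed to the parents through the
exact transpose Jacobian of that construction, including the derivatives
of the normalizations and the cross product — required for forces to
remain the exact negative gradient, which the tests verify by finite
differences and by rigid-motion equivariance.

## Periodic cells

Boxes are stored in reduced triclinic form (first vector along x, second
in the xy-plane, off-diagonal components bounded by half the diagonals).
`reduce_box()` canonicalizes arbitrary right-handed lattice vectors
without changing the lattice; constructors provide the cube, rhombic
dodecahedron (volume `width^3/sqrt(2)`, about 71% of the cube at equal
image distance) and truncated octahedron (`4*sqrt(3)/9`, about 77%).
Minimum-image displacements apply a rounding reduction and then search
neighboring images; the search radius is bounded exactly using the
lattice plane spacings, so the result is the true minimum even for skewed
(but valid) cells — for well-conditioned cells this is the usual 27-image
neighborhood. A brute-force enumeration over [-3,3]^3 images guards this
in the tests. Pair terms refuse cutoffs larger than half the smallest box
height.

## Precision modes and deterministic accumulation

R computes in doubles; the 32-bit paths are emulated by rounding values
through IEEE binary32. In `"mixed"` mode the positions and every term's
energy and forces are rounded to binary32 (forces in single precision)
while accumulation and integration stay double; `"single"` additionally
rounds the accumulation and every integrator assignment. This reproduces
the error structure of a genuinely single-precision engine closely enough
to show the qualitative behavior that matters: single-precision energy
drift orders of magnitude above double.

Fixed-point accumulation quantizes each term's force components to
integer counts at 2^32 counts per kJ/mol/nm and sums them in a two-limb
base-2^32 representation — exact signed 64-bit integer arithmetic carried
in doubles. Integer addition is associative, so totals are bit-identical
under any summation order; quantization perturbs each contribution by at
most 2^-33 kJ/mol/nm. Contributions at or beyond 2^21 kJ/mol/nm (where a
count would no longer be exactly representable) and accumulated totals
beyond the 64-bit range raise overflow errors.

## Energy drift protocol

Drift is estimated as the ordinary least-squares slope of total energy
versus time, with its standard error. The reference measurement in the
tests and the acceptance script uses the N = 100 Lennard-Jones fluid
fixture (argon-like: sigma 0.34 nm, epsilon 0.996 kJ/mol, mass 39.948
amu, 2.5 nm cubic box, 120 K start) with leapfrog at dt = 0.001 ps: 5 ps
of equilibration from the jittered lattice, then 10 ps of measurement
with the total energy recorded every 0.1 ps. The equilibration and the
0.1 ps sampling are part of the protocol definition: a lattice-melt
transient or a handful of samples would otherwise dominate the slope
estimate with sampling noise of order 5e-3 (kJ/mol)/ps, an order of
magnitude above the double-precision drift being measured. Problem sizes
throughout (100 particles, 10 ps) are chosen so the whole suite runs
comfortably on a single CPU; they are small compared to production MD,
which is exactly why the single/double comparison is reported as an
ordering and a ratio rather than as absolute drift magnitudes comparable
to large solvated-protein benchmarks.

## Amber input pipeline

`read_prmtop()` parses every `%FLAG` section by its `%FORMAT` record and
resolves the Amber conventions: charges divided by 18.2223, bonded index
arrays divided by 3 with sign-carried markers (negative third index for
1-4-excluded duplicate torsion paths, negative fourth for impropers),
per-atom Lennard-Jones sigma/epsilon recovered from the diagonal A/B
coefficients. 1-4 pairs are materialized as explicit exception entries
scaled by 1/SCEE and 1/SCNB (1.2 and 2.0 when those sections are absent),
each unique pair counted once; exceptions replace the default pair
interaction entirely, which keeps the decomposition categories clean.
Explicit-solvent PME is out of scope and requesting it is an error, not
an approximation.

The OBC1 implicit solvent computes Born radii by pairwise descreening
with the tanh rescaling (alpha = 0.8, beta = 0, gamma = 2.909125) and the
customary 0.009 nm dielectric offset, then the smoothed generalized Born
pair energy with solute/solvent dielectrics 1 and 78.5; the optional ACE
surface-area term (28.3919551 kJ/mol/nm^2, 0.14 nm probe) is off by
default, matching the bare-OBC convention of topology cross-validation
comparisons. Forces are the exact analytic gradient chained through the
Born radii. The descreening uses O(N^2) dense matrices, as does the pair
loop generally — there is no neighbor list; correctness first, at the few
hundred to few thousand atom scale this engine targets.

A note on the single-particle limit: with the dielectric offset, a lone
ion of intrinsic radius R has Born radius R - 0.009 nm, so its self
energy is `-138.935456 (1 - 1/78.5) q^2 / (2 (R - 0.009))`. The
`dielectric_offset` argument exists (set it to 0) for the textbook
closed form without the offset; both limits are asserted in the tests.

## The synthetic fixtures, and what tests do not show

The fixtures module generates everything the suite needs at run time:
LJ fluids on jittered lattices, harmonic chains and diatomics, flexible
or rigid three-site water boxes, and syntactically valid toy prmtop/
inpcrd files that exercise the full input pipeline. An independent
reference implementation (scalar loops, explicit formulas, exclusions
re-derived from the bond graph, finite-difference forces) provides the
oracle: the engine must reproduce it to 1e-10 relative on the toy
systems, and an external topology parser (MDAnalysis) cross-checks the
prmtop writer/reader pair.

These fixtures emulate the *mechanics* of real data — section layouts,
unit conventions, index encodings, exclusion topologies — but not its
scale or chemistry: no realistic force-field parameterization, no
solvated proteins, no PME electrostatics, and system sizes of tens to a
hundred particles. Passing tests therefore demonstrate that the
machinery (parsing, differentiation, geometry, constraint projection,
accumulation, unit conversion) is correct, not that production-scale
simulations are fast or that any particular force field is well
reproduced beyond the functional forms implemented here.

## Known limitations

- O(N^2) pair interactions and dense OBC matrices bound practical system
  size to a few thousand atoms.
- No PME/Ewald reciprocal-space electrostatics, reaction field, neighbor
  lists, barostats, or multiple-time-step integration.
- Virtual sites support the general three-parent rule only; sites with
  four or more parents are out of scope (two-parent averages are
  degenerate parameterizations of the general rule).
- 32-bit behavior is emulated by rounding; it mirrors the error structure
  of true single-precision arithmetic, not its exact bit patterns.
- The minimizer (L-BFGS-B with SHAKE re-projection at exit) treats
  constraints as a post-processing step, which is adequate for clash
  relief but not for strict constrained optimization.
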