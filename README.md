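# minimm

A desk-scale molecular dynamics engine for R, built around extensibility:
new interactions are defined by algebraic energy expressions and new
integration algorithms by short per-degree-of-freedom programs, with the
engine deriving forces by analytic differentiation. It is aimed at people
who develop and teach simulation methods — anyone who wants to prototype a
novel pair potential, a restraint, a thermostat variant, or a constraint
scheme in a few lines and have the forces, conservation properties, and
reproducibility handled correctly — not at production-scale sampling.

## What it implements

- **Custom forces.** An expression such as `k*(theta-theta0)^2` (energy as
  a function of a bond length r, angle theta, signed dihedral, particle
  coordinates, pair distance, or centroid geometry) is parsed,
  differentiated symbolically, and compiled to vectorized closures. Forces
  are exactly −∇E by construction; combination rules use trailing
  definitions (`...; sig=0.5*(sig1+sig2); eps=sqrt(eps1*eps2)`).
- **Custom integrators.** A time step is an ordered program of per-DOF
  computations (`v <- v + dt*f/m`), global computations, sums over DOFs,
  SHAKE/RATTLE constraint projections, and if/while blocks, over builtins
  x, v, f, m, dt and counter-keyed `gaussian`/`uniform` streams. Leapfrog
  Verlet and a Langevin integrator ship as five-step programs in this
  language.
- **Standard terms.** Amber-form harmonic bonds/angles, periodic torsions,
  Lennard-Jones + Coulomb with exclusions and 1-4 exceptions, and OBC1
  generalized Born implicit solvent (tanh-rescaled pairwise descreening,
  α = 0.8, β = 0, γ = 2.909125) with exact analytic gradients.
- **Geometry.** Arbitrary triclinic periodic cells in reduced form, with
  exact minimum-image displacement, molecule wrapping, and constructors
  for the cube, rhombic dodecahedron (71% of the cube's volume at equal
  image distance) and truncated octahedron.
- **Virtual sites.** The generalized three-parent rule (weighted origin
  and axis vectors, orthonormal frame, fixed local offset) with force
  redistribution by the exact transpose Jacobian.
- **Precision and determinism.** Single/mixed/double force dispatch
  (32-bit emulated by binary32 rounding) and 64-bit fixed-point force
  accumulation (2^32 counts per kJ/mol/nm) that is bit-identical under
  any summation order.
- **Input/output.** Amber prmtop/inpcrd readers (fixed-width %FLAG
  sections, all unit conventions resolved), a minimal PDB subset, CSV
  state reporters, DCD trajectory output, per-category energy
  decomposition, an L-BFGS minimizer, and an OLS energy-drift estimator.

## A worked example

A harmonic angle restraint as a custom force, and two steps of the
leapfrog program on a unit-mass particle under constant unit force
(dt = 1, starting from rest):

```r
library(minimm)

# custom angle term: E = k (theta - theta0)^2, one right-angle triplet
term <- custom_angle_term("k*(theta-theta0)^2", matrix(1:3, 1),
                          c("k", "theta0"), matrix(c(1, 0), 1))
pos <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
evaluate_force_term(term, pos)$energy
#> [1] 2.467401            # (pi/2)^2 — a 90 degree angle costs k (pi/2)^2

# the five-step leapfrog program, exact integer arithmetic
sys <- mm_system(masses = 1,
                 force_terms = list(custom_external_term("0-x", 1L)))
st  <- run_simulation(sys, leapfrog_program(1), mm_state(matrix(0, 1, 3)), 2)
c(v = st$velocities[1, 1], x = st$positions[1, 1])
#> v x
#> 2 3                    # v: 0 -> 1 -> 2;  x: 0 -> 1 -> 3

# energy decomposition of a synthetic Amber topology
desc <- list(masses = c(12, 12), charges = c(0, 0),
             sigma = c(0.3, 0.3), epsilon = c(0, 0),
             bonds = data.frame(i = 1, j = 2, k = 25000, r0 = 0.12))
f <- tempfile(); write_toy_prmtop(desc, f)
sysA <- system_from_prmtop(read_prmtop(f))
energy_decomposition(sysA, rbind(c(0, 0, 0), c(0.13, 0, 0)))
#>      Bond     Angle  Dihedral Nonbonded     Total
#>       2.5       0.0       0.0       0.0       2.5   # 25000 * 0.01^2 kJ/mol
```

A command-line front end (`inst/cli/minimm`) wraps the same functions:
`minimm energy --prmtop F --inpcrd F --implicit obc1` prints the
decomposition table, `minimm run config.yaml` runs a simulation with CSV
and DCD reporters, `minimm drift --log F` fits the drift slope, and
`minimm compare-forces --ref A.csv --test B.csv` prints the normalized
force projection.

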