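test_that("toy prmtop round-trips exactly through the reader", {
  desc <- toy_molecule_desc()
  f <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc, f)
  p <- read_prmtop(f)
  expect_equal(p$natom, 5)
  expect_equal(nrow(p$bonds_h) + nrow(p$bonds_a), 4)
  expect_identical(p$masses, desc$masses)
  expect_equal(p$charges, desc$charges, tolerance = 1e-12)
  expect_equal(p$atom_names, desc$names)
  # charge unscaling: a stored value of 18.2223 is one elementary charge
  desc1 <- list(masses = 12, charges = 1, sigma = 0.3, epsilon = 0.1)
  f1 <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc1, f1)
  raw <- readLines(f1)
  chg_line <- raw[grep("%FLAG CHARGE", raw) + 2]
  expect_equal(as.numeric(chg_line), 18.2223, tolerance = 1e-6)
  expect_equal(read_prmtop(f1)$charges, 1, tolerance = 1e-12)
  expect_error(suppressWarnings(read_prmtop(tempfile())))
})

test_that("negative dihedral indices decode to their atom and markers", {
  desc <- toy_molecule_desc()
  # add a second dihedral over the same 1-4 pair plus an improper
  desc$dihedrals <- rbind(desc$dihedrals,
                          data.frame(i = 1, j = 2, k = 3, l = 4, kf = 1.1,
                                     n = 2, gamma = pi),
                          data.frame(i = 2, j = 3, k = 1, l = 4, kf = 0.5,
                                     n = 2, gamma = pi))
  desc$dihedrals$improper <- c(FALSE, FALSE, FALSE, TRUE)
  f <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc, f)
  p <- read_prmtop(f)
  d <- rbind(p$dihedrals_h, p$dihedrals_a)
  expect_equal(nrow(d), 4)
  # duplicate 1-4 pair and improper have negative third index markers
  expect_equal(sum(d[, 3] < 0), 2)
  expect_equal(sum(d[, 4] < 0), 1)
  # markers preserve the atom identity (the improper is reversed because
  # its third atom is atom 1, which the sign encoding cannot mark)
  expect_setequal(abs(d[, 3]), c(2, 3))
  # exactly one exception per unique 1-4 pair
  sys <- system_from_prmtop(p)
  ex <- minimm:::prmtop_exceptions(p, p$charges, rep(0.3, 5), rep(0.1, 5))
  expect_equal(nrow(ex), 2)   # pairs (1,4) and (5,3)
})

test_that("bonded unit conversions land in kJ, nm, radians", {
  # diatomic with one bond: E(r0 + 0.01 nm) must equal the hand conversion
  desc <- list(masses = c(12, 12), charges = c(0, 0),
               sigma = c(0.3, 0.3), epsilon = c(0, 0),
               bonds = data.frame(i = 1, j = 2, k = 25000, r0 = 0.12))
  f <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc, f)
  sys <- system_from_prmtop(read_prmtop(f))
  pos <- rbind(c(0, 0, 0), c(0.13, 0, 0))
  dec <- energy_decomposition(sys, pos)
  expect_equal(dec[["Bond"]], 25000 * 0.01^2, tolerance = 1e-9)
})

test_that("constraint options replace the selected harmonic bonds", {
  desc <- toy_molecule_desc()
  f <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc, f)
  p <- read_prmtop(f)
  sys_h <- system_from_prmtop(p, constraints = "h_bonds")
  expect_length(sys_h$constraints, 1)           # the single C-H bond
  expect_equal(sys_h$constraints[[1]]$distance, 0.109, tolerance = 1e-9)
  dec <- energy_decomposition(sys_h, toy_molecule_positions())
  dec_all <- energy_decomposition(system_from_prmtop(p),
                                  toy_molecule_positions())
  expect_lt(dec[["Bond"]], dec_all[["Bond"]])   # H-bond term removed
  sys_all <- system_from_prmtop(p, constraints = "all_bonds")
  expect_length(sys_all$constraints, 4)
  expect_equal(energy_decomposition(sys_all,
                                    toy_molecule_positions())[["Bond"]], 0)
})

test_that("the built system reproduces the independent reference energies", {
  desc <- toy_molecule_desc()
  f <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc, f)
  p <- read_prmtop(f)
  pos <- toy_molecule_positions()
  sys <- system_from_prmtop(p, solvent = "obc1")
  dec <- energy_decomposition(sys, pos)
  ref <- reference_energy(desc, pos, obc = TRUE, forces = TRUE)
  for (cat in c("Bond", "Angle", "Dihedral", "Nonbonded", "OBC", "Total"))
    expect_lt(abs(dec[[cat]] - ref$energies[[cat]]) /
                max(1e-10, abs(ref$energies[[cat]])), 1e-10)
  # decomposition categories are additive
  expect_lt(abs(sum(dec[names(dec) != "Total"]) - dec[["Total"]]), 1e-9)
  # engine forces agree with the reference finite differences
  fr <- compute_forces(sys, pos)
  expect_lt(max(abs(fr$forces - ref$forces)) / max(abs(fr$forces)), 1e-7)
  # surface-area variant also agrees
  sys_sa <- system_from_prmtop(p, solvent = "obc1", sa_term = TRUE)
  ref_sa <- reference_energy(desc, pos, obc = TRUE, sa = TRUE)
  expect_lt(abs(energy_decomposition(sys_sa, pos)[["Total"]] -
                  ref_sa$energies[["Total"]]) /
              abs(ref_sa$energies[["Total"]]), 1e-10)
  # obc1 without GB sections is an error
  desc2 <- desc; desc2$radii <- NULL
  f2 <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc2, f2)   # writer fills defaults, so drop sections
  lines <- readLines(f2)
  drop <- grep("%FLAG (RADII|SCREEN)", lines)
  keep <- setdiff(seq_along(lines),
                  unlist(lapply(drop, function(d) d + 0:2)))
  writeLines(lines[keep], f2)
  expect_error(system_from_prmtop(read_prmtop(f2), solvent = "obc1"),
               "RADII")
  expect_error(system_from_prmtop(p, solvent = "pme"), "PME")
})

test_that("an independent topology parser agrees with the reader", {
  # MDAnalysis (via the system python) as the external parsing oracle
  desc <- toy_molecule_desc()
  f <- tempfile(fileext = ".prmtop")
  write_toy_prmtop(desc, f, float_format = "amber")
  script <- sprintf(paste0(
    "import warnings; warnings.filterwarnings('ignore')\n",
    "import MDAnalysis as mda\n",
    "u = mda.Universe('%s')\n",
    "print(len(u.atoms))\n",
    "print(' '.join('%%.6f' %% c for c in u.atoms.charges))\n",
    "print(' '.join('%%.4f' %% m for m in u.atoms.masses))\n",
    "print(len(u.bonds))\n"), f)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- tryCatch(system2("python", sf, stdout = TRUE, stderr = FALSE),
                  error = function(e) character(0))
  if (length(out) >= 4 && !is.na(out[1])) {
    p <- read_prmtop(f)
    expect_equal(as.integer(out[1]), p$natom)
    expect_equal(scan(text = out[2], quiet = TRUE), p$charges,
                 tolerance = 1e-5)
    expect_equal(scan(text = out[3], quiet = TRUE), p$masses,
                 tolerance = 1e-4)
    expect_equal(as.integer(out[4]), nrow(p$bonds_h) + nrow(p$bonds_a))
  } else {
    succeed("external python parser unavailable; covered by round-trip tests")
  }
})

test_that("inpcrd coordinates, velocities and boxes convert correctly", {
  f <- tempfile()
  writeLines(c("one atom", "    1",
               "   1.0000000   2.0000000   3.0000000"), f)
  ic <- read_inpcrd(f)
  expect_equal(ic$positions, matrix(c(0.1, 0.2, 0.3), 1), ignore_attr = TRUE)
  expect_null(ic$box)
  expect_null(ic$velocities)
  # round-trip through the writer, with and without a box
  set.seed(71)
  pos <- matrix(stats::rnorm(15), 5) * 0.4
  f2 <- tempfile()
  write_inpcrd(f2, pos)
  expect_lt(max(abs(read_inpcrd(f2)$positions - pos)), 1e-7)
  f3 <- tempfile()
  write_inpcrd(f3, pos, box_from_geometry("cube", 2))
  ic3 <- read_inpcrd(f3)
  expect_equal(unclass(ic3$box), diag(3) * 2, ignore_attr = TRUE,
               tolerance = 1e-7)
  f4 <- tempfile()
  write_inpcrd(f4, pos, box_from_geometry("truncated_octahedron", 2))
  expect_equal(box_volume(read_inpcrd(f4)$box),
               box_volume(box_from_geometry("truncated_octahedron", 2)),
               tolerance = 1e-6)
  # header/count mismatch is an error
  f5 <- tempfile()
  writeLines(c("bad", "    2", "   1.0000000   2.0000000   3.0000000"), f5)
  expect_error(read_inpcrd(f5), "atom count")
})

test_that("the PDB subset reads and writes at format precision", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  O1  ALA A   1       0.500  -1.250   2.000  1.00  0.00",
    "END"), f)
  p <- read_pdb(f)
  expect_equal(p$positions[1, ], c(0.1, 0.2, 0.3), ignore_attr = TRUE)
  expect_equal(p$elements, c("C", "O"))   # second inferred from the name
  set.seed(72)
  pos <- matrix(stats::rnorm(12), 4) * 0.3
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(f2, pos, names = c("C1", "C2", "O1", "H1"))
  rt <- read_pdb(f2)
  expect_lt(max(abs(rt$positions - pos)), 1e-4 / 2 + 1e-12)
  expect_equal(rt$names, c("C1", "C2", "O1", "H1"))
  # bio3d as the round-trip oracle when available
  if (requireNamespace("bio3d", quietly = TRUE)) {
    bp <- bio3d::read.pdb(f2)
    expect_lt(max(abs(cbind(bp$atom$x, bp$atom$y, bp$atom$z) / 10 - pos)),
              1e-4)
  }
  f3 <- tempfile(fileext = ".pdb")
  writeLines("REMARK empty", f3)
  expect_error(read_pdb(f3), "no ATOM")
})
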