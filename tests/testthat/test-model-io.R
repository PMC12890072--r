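# Domain types, file formats and the selection language.

test_that("a minimal PDB reads back atoms and coordinates exactly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.458   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.010   3.420   3.000  1.00  0.00           C",
    "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), 3)
  expect_equal(st$atoms$atom_name, c("N", "CA", "C"))
  expect_equal(st$atoms$residue_index, rep(1L, 3))
  expect_equal(st$xyz,
               rbind(c(1, 2, 3), c(2.458, 2, 3), c(3.010, 3.420, 3)),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_true(all(st$atoms$role == "backbone"))
  expect_true(all(st$atoms$polarity_class == "nonpolar"))
})

test_that("PDB and GRO encodings of the same coordinates agree to 1e-3 A", {
  p <- gen_toy_peptide(6, "alpha_helix")
  xyz <- round(p$xyz + 5, 2)   # representable exactly in both formats
  pp <- withr::local_tempfile(fileext = ".pdb")
  gg <- withr::local_tempfile(fileext = ".gro")
  write_structure(p$atoms, xyz, pp, "pdb")
  write_structure(p$atoms, xyz, gg, "gro", box = simulation_box(40))
  sp <- read_structure(pp)
  sg <- read_structure(gg)
  expect_equal(sp$xyz, sg$xyz, tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(sp$atoms$atom_name, sg$atoms$atom_name)
  expect_identical(sp$atoms$residue_index, sg$atoms$residue_index)
  expect_identical(sp$atoms$role, sg$atoms$role)
  expect_equal(as.numeric(sg$box), rep(40, 3))
})

test_that("malformed PDB records are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000",
    "ATOM      2  CA  ALA A   1       2.458   2.0"), path)
  expect_error(read_structure(path), "line 2")
})

test_that("unknown residues are kept with polarity n/a and a warning", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  XYZ A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), path)
  expect_warning(st <- read_structure(path), "XYZ")
  expect_equal(st$atoms$polarity_class, "n/a")
})

test_that("XYZ trajectories round-trip through write and read", {
  m <- synthetic_model("ideal_gas", rho = 40 / 20^3, seed = 2)
  sys <- gen_solvent_ensemble(matrix(10, 1, 3), simulation_box(20), m,
                              n_frames = 2)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(sys, path)
  sys2 <- read_trajectory(path, sys, "xyz")
  expect_equal(sys2$n_frames, 2)
  expect_equal(sys2$solvent_xyz[[1]], sys$solvent_xyz[[1]], tolerance = 1e-3)
  expect_equal(sys2$box, sys$box, ignore_attr = TRUE)
})

test_that("atom-count mismatches are reported at frame 0", {
  m <- synthetic_model("ideal_gas", rho = 40 / 20^3, seed = 2)
  sys <- gen_solvent_ensemble(matrix(10, 1, 3), simulation_box(20), m,
                              n_frames = 1)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(sys, path)
  bigger <- gen_solvent_ensemble(matrix(10, 1, 3), simulation_box(20),
                                 synthetic_model("ideal_gas", rho = 60 / 20^3,
                                                 seed = 2), n_frames = 1)
  expect_error(read_trajectory(path, bigger, "xyz"), "frame 0")
})

test_that("XYZ and DCD encodings of one ensemble give identical analyses", {
  m <- synthetic_model("square_well", d = 2, eps = 1, w = 1,
                       rho = 120 / 20^3, seed = 9)
  sys <- gen_solvent_ensemble(matrix(10, 1, 3), simulation_box(20), m,
                              n_frames = 5)
  xp <- withr::local_tempfile(fileext = ".xyz")
  dp <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory_xyz(sys, xp)
  write_trajectory_dcd(sys, dp)
  s1 <- read_trajectory(xp, sys, "xyz")
  s2 <- read_trajectory(dp, sys, "dcd")
  cfg <- analysis_config(r_max = 9, bulk_shell = c(6, 9), seed = 4,
                         n_mc_points = 1e4)
  g1 <- compute_mddf(s1, 1, cfg)$g
  g2 <- compute_mddf(s2, 1, cfg)$g
  expect_lt(max(abs(g1 - g2), na.rm = TRUE), 1e-5)
})

test_that("XTC input is refused with guidance", {
  expect_error(read_trajectory("no.xtc", NULL, "xtc"), "not supported")
})

test_that("fixture directories round-trip a two-species system", {
  sys <- binary_fixture()
  # shrink to 2 frames to keep the text fixture small
  small <- solvation_system(sys$solute_atoms,
                            sys$solute_xyz[, , 1:2, drop = FALSE],
                            sys$species,
                            lapply(sys$solvent_xyz, function(a) a[, , 1:2, drop = FALSE]),
                            sys$box[1:2, , drop = FALSE])
  dir <- withr::local_tempdir()
  write_fixture(small, dir)
  expect_true(all(file.exists(file.path(dir, c("structure.pdb",
                                               "trajectory.xyz",
                                               "manifest.yaml")))))
  back <- suppressWarnings(read_fixture(dir))  # pseudo-residue names warn
  expect_equal(back$n_frames, 2)
  expect_equal(back$solvent_xyz$cosolvent, small$solvent_xyz$cosolvent,
               tolerance = 1e-3)
  expect_equal(names(back$species), names(small$species))
})

test_that("selections pick atoms by role and partition by polarity", {
  p <- gen_toy_peptide(5, "alpha_helix")
  at <- p$atoms
  bb <- select_group(at, role == "backbone")
  expect_setequal(at$atom_name[bb], c("N", "H", "CA", "C", "O"))
  expect_length(bb, nrow(at))   # polyalanine backbone fixture: all backbone
  # polarity classes partition sidechain atoms
  at2 <- atom_table(c("CB", "OG", "NZ", "CD1"), c(1L, 2L, 3L, 4L),
                    c("ALA", "SER", "LYS", "LEU"))
  np <- select_group(at2, polarity_class == "nonpolar" & role == "sidechain")
  pol <- select_group(at2, polarity_class %in% c("polar_charged", "polar_uncharged") &
                        role == "sidechain")
  expect_setequal(c(np, pol), select_group(at2, role == "sidechain"))
  expect_length(intersect(np, pol), 0)
})

test_that("selection is equivariant under residue renumbering", {
  p <- gen_toy_peptide(6, "extended")
  sel <- select_group(p$atoms, residue_index == 3)
  shifted <- p$atoms
  shifted$residue_index <- shifted$residue_index + 120L
  sel2 <- select_group(shifted, residue_index == 123)
  expect_identical(sel, sel2)
})

test_that("selections are idempotent and distribute over union/intersection", {
  p <- gen_toy_peptide(6, "alpha_helix")
  a <- select_group(p$atoms, atom_name == "O")
  b <- select_group(p$atoms, residue_index <= 3)
  ab_union <- select_group(p$atoms, atom_name == "O" | residue_index <= 3)
  ab_inter <- select_group(p$atoms, atom_name == "O" & residue_index <= 3)
  expect_identical(ab_union, sort(union(a, b)))
  expect_identical(ab_inter, sort(intersect(a, b)))
  expect_identical(select_group(p$atoms, atom_name == "O"), a)
})

test_that("selections on unknown fields fail loudly", {
  p <- gen_toy_peptide(5, "extended")
  expect_error(select_group(p$atoms, chain == "A"), "unknown field")
})
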