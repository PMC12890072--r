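# Minimum-distance engine, ideal-gas reference, g(r) and decompositions.

test_that("minimum distances match hand geometry", {
  at <- atom_table("X1", 1L, "GLY")
  sp <- solvent_species("s", atom_table(c("A1", "A2"), c(1L, 1L),
                                        c("SOL", "SOL"), solvent = TRUE), 1L)
  sys <- solvation_system(at, matrix(0, 1, 3), list(s = sp),
                          list(s = rbind(c(5, 0, 0), c(6, 0, 0))),
                          simulation_box(20))
  md <- min_distances(sys, "s", 1)
  expect_equal(md$dmin, 5)
  expect_equal(md$solute_atom, 1L)
  expect_equal(md$solvent_atom, 1L)
})

test_that("minimum image wins over the direct distance across the boundary", {
  at <- atom_table("X1", 1L, "GLY")
  sp <- solvent_species("s", atom_table(c("A1", "A2"), c(1L, 1L),
                                        c("SOL", "SOL"), solvent = TRUE), 1L)
  sv <- rbind(c(18, 0, 0), c(19, 0, 0))
  sys <- solvation_system(at, matrix(0, 1, 3), list(s = sp),
                          list(s = sv), simulation_box(20))
  md <- min_distances(sys, "s", 1)
  expect_equal(md$dmin, 1)           # 19 is 1 A away through the boundary
  expect_equal(md$solvent_atom, 2L)
  bf <- bf_min_distances(matrix(0, 1, 3), sv, 2, simulation_box(20))
  expect_equal(md$dmin, bf$dmin)
})

test_that("min_distances equals the all-pairs all-images brute force", {
  for (seed in 1:50) {
    tiny <- random_tiny_system(seed)
    md <- min_distances(tiny$system, "s", 1)
    bf <- bf_min_distances(tiny$su, tiny$sv, tiny$m, tiny$box)
    expect_identical(md$dmin, bf$dmin)
    expect_equal(md$solute_atom, bf$solute_atom)
    expect_equal(md$solvent_atom, bf$solvent_atom)
  }
})

test_that("reference counts follow the 4 pi r^2 rho shell law", {
  box <- simulation_box(40)
  m <- synthetic_model("ideal_gas", rho = 2000 / 40^3, seed = 3)
  sys <- gen_solvent_ensemble(matrix(20, 1, 3), box, m, n_frames = 1)
  cfg <- analysis_config(nu = 20, seed = 6, n_mc_points = 1e4)
  nref <- reference_counts(sys, 1, 1, cfg)
  r <- (seq_along(nref) - 0.5) * cfg$bin_width
  expected <- 2000 * 4 * pi * r^2 * cfg$bin_width / 40^3
  sel <- r > 3 & r < 10
  expect_equal(mean(nref[sel] / expected[sel]), 1, tolerance = 0.03)
})

test_that("reference oversampling lowers variance without moving the mean", {
  box <- simulation_box(20)
  m <- synthetic_model("ideal_gas", rho = 100 / 20^3, seed = 4)
  sys <- gen_solvent_ensemble(matrix(10, 1, 3), box, m, n_frames = 1)
  total <- function(nu, seed) {
    cfg <- analysis_config(nu = nu, r_max = 8, bulk_shell = c(5, 8), seed = seed)
    sum(reference_counts(sys, 1, 1, cfg, seed = seed)[1:40])  # counts below 4 A
  }
  t1 <- vapply(1:30, function(s) total(1, s), 0)
  t10 <- vapply(1:30, function(s) total(10, s), 0)
  expect_equal(mean(t1), mean(t10), tolerance = 0.2)
  expect_lt(var(t10), var(t1))
})

test_that("the ideal-gas fixture has g close to one across the domain", {
  r <- ideal_gas_kbi()$mddf
  sel <- r$r > 1 & r$r < 10
  expect_equal(mean(r$g[sel]), 1, tolerance = 0.03)
})

test_that("square-well and hard-wall fixtures reproduce their g oracles", {
  rs <- square_well_kbi()$mddf
  expect_equal(mean(rs$g[rs$r > 3 & rs$r < 4]), exp(1), tolerance = 0.05)
  expect_equal(mean(rs$g[rs$r > 5 & rs$r < 10]), 1, tolerance = 0.03)
  rh <- hard_wall_kbi()$mddf
  expect_true(all(rh$g[rh$r < 3] == 0 | is.na(rh$g[rh$r < 3])))
  expect_equal(mean(rh$g[rh$r > 4 & rh$r < 10]), 1, tolerance = 0.03)
})

test_that("g is invariant under rigid rotation plus translation of frames", {
  # box is wide enough (40 vs solute extent + r_max ~ 15) that no counted
  # pair is realized across the boundary, so a global rigid motion about
  # the box center preserves every counted minimum-image distance exactly
  m <- synthetic_model("square_well", d = 2.5, eps = 1, w = 1,
                       rho = 500 / 40^3, seed = 17)
  p <- gen_toy_peptide(5, "alpha_helix")
  ctr <- 20 - colMeans(p$xyz)
  sys <- gen_solvent_ensemble(p$xyz + matrix(ctr, nrow(p$xyz), 3, byrow = TRUE),
                              simulation_box(40), m, n_frames = 30,
                              solute_atoms = p$atoms)
  rigid <- function(sys, R, shift) {
    out <- sys
    for (f in seq_len(sys$n_frames)) {
      mv <- function(x) sweep(sweep(x, 2, rep(20, 3)) %*% t(R), 2,
                              rep(20, 3) + shift, "+")
      out$solute_xyz[, , f] <- mv(matrix(sys$solute_xyz[, , f], ncol = 3))
      out$solvent_xyz[[1]][, , f] <- mv(matrix(sys$solvent_xyz[[1]][, , f],
                                               ncol = 3))
    }
    out
  }
  cfg <- analysis_config(r_max = 10, bulk_shell = c(7, 10), seed = 5,
                         n_mc_points = 1e4)
  a <- compute_mddf(sys, 1, cfg)
  # a lattice symmetry (90 degrees about z) plus translation preserves every
  # minimum-image distance exactly, so the observed histograms are identical
  R90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  b <- compute_mddf(rigid(sys, R90, c(3, -2, 4)), 1, cfg)
  expect_equal(a$obs_mat, b$obs_mat)
  # an arbitrary rotation only fails to preserve distances for corner
  # molecules beyond L/2, whose images can enter the counted range: the
  # histograms may differ by a handful of far-bin events, and g agrees
  # statistically
  theta <- 0.7
  Rz <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
              c(0, 0, 1))
  c_ <- compute_mddf(rigid(sys, Rz, c(3, -2, 4)), 1, cfg)
  # counted events keep their exact distance (their realizing image is the
  # stored representative), so counts can only grow, and only by the few
  # corner entries
  expect_true(all(c_$obs_mat - a$obs_mat >= 0))
  expect_lt(sum(c_$obs_mat - a$obs_mat), 0.01 * sum(a$obs_mat))
  well <- a$r > 2.5 & a$r < 3.5
  expect_equal(mean(c_$g[well]), mean(a$g[well]), tolerance = 0.05)
})

test_that("zero bins in the reference are flagged undefined, not zero", {
  sys <- ideal_gas_fixture()
  r <- ideal_gas_kbi()$mddf
  expect_true(any(r$undefined))            # tiny-r bins are never populated
  expect_true(all(is.na(r$g[r$undefined])))
})

test_that("decomposition attributes the first peak to the protruding site", {
  # deterministic construction: rigid rods pointing their HO site at the
  # solute from inside the well, so every argmin atom is known
  at <- atom_table("X1", 1L, "GLY")
  sp <- solvent_species("c", atom_table(c("C1", "O1", "HO"), rep(1L, 3),
                                        rep("CSL", 3), solvent = TRUE), 6L)
  one_mol <- function(r, u) rbind((r + 2.4) * u, (r + 1.0) * u, r * u)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  sv <- do.call(rbind, lapply(1:6, function(i)
    one_mol(3.2 + 0.1 * i, dirs[i, ]))) + 15
  sys <- solvation_system(at, matrix(15, 1, 3), list(c = sp), list(c = sv),
                          simulation_box(30))
  cfg <- analysis_config(r_max = 10, bulk_shell = c(6, 10), seed = 2,
                         n_mc_points = 1e4)
  md <- compute_mddf(sys, "c", cfg)
  ct <- decompose(md, list(hydroxyl = 3L, rest = c(1L, 2L)), side = "solvent")
  peak <- md$r > 3 & md$r < 4
  expect_equal(sum(ct$counts[peak, "hydroxyl"]), sum(md$n_obs[peak]))
  expect_equal(sum(ct$counts[peak, "rest"]), 0)
})

test_that("exhaustive partitions conserve the observed counts bin by bin", {
  sys <- binary_fixture()
  cfg <- fixture_config(n_mc_points = 2e5)
  md <- binary_kbis()$cosolvent$mddf
  # solvent side: hydroxyl vs rest of the rigid rod
  ct <- decompose(md, list(ho = 3L, rest = 1:2), side = "solvent")
  expect_equal(rowSums(ct$counts), md$n_obs)
  # single group containing every atom reproduces the total exactly
  all_ct <- decompose(md, list(all = 1:3), side = "solvent")
  expect_equal(all_ct$counts[, "all"], md$n_obs)
})

test_that("overlapping groups are refused unless explicitly allowed", {
  md <- binary_kbis()$cosolvent$mddf
  expect_error(decompose(md, list(a = 1:2, b = 2:3), side = "solvent"),
               "overlap")
  ct <- decompose(md, list(a = 1:2, b = 2:3), side = "solvent",
                  allow_overlap = TRUE)
  expect_true(ct$overlap)
})

test_that("the residue map localizes density and conserves counts", {
  # two single-atom residues 12 A apart; molecules placed near residue 1
  at <- atom_table(c("X1", "X2"), c(1L, 2L), c("GLY", "GLY"))
  su <- rbind(c(9, 15, 15), c(21, 15, 15))
  sp <- solvent_species("s", atom_table("A1", 1L, "SOL", solvent = TRUE), 5L)
  sv <- cbind(9 + 2.5 + 0.1 * (1:5), rep(15, 5), rep(15, 5))
  sys <- solvation_system(at, su, list(s = sp), list(s = sv),
                          simulation_box(30))
  cfg <- analysis_config(r_max = 10, bulk_shell = c(6, 10), seed = 2,
                         n_mc_points = 1e4)
  md <- compute_mddf(sys, "s", cfg)
  map <- residue_density_map(md, sys)
  expect_equal(colSums(map$counts), md$n_obs)
  near <- map$r > 2 & map$r < 4
  expect_gt(sum(map$counts[1, near]), 0)
  expect_equal(sum(map$counts[2, near]), 0)
  # permuting residue labels permutes rows identically
  at2 <- at; at2$residue_index <- c(2L, 1L)
  sys2 <- solvation_system(at2, su, list(s = sp), list(s = sv),
                           simulation_box(30))
  md2 <- compute_mddf(sys2, "s", cfg)
  map2 <- residue_density_map(md2, sys2)
  expect_equal(map2$counts[2, ], map$counts[1, ])
  expect_equal(map2$counts[1, ], map$counts[2, ])
})

test_that("empty selections and absent species are rejected", {
  sys <- ideal_gas_fixture()
  expect_error(min_distances(sys, 1, 1, integer(0)), "empty")
  expect_error(compute_mddf(sys, "nope"), "unknown")
})
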