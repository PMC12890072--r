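# Bulk densities, Kirkwood-Buff integrals and preferential parameters.

vx_a3 <- (4 / 3) * pi * 27                    # excluded volume, d = 3 A
vw_a3 <- (4 / 3) * pi * (4^3 - 3^3)           # square well [3, 4] A
to_lmol <- 6.02214076e-4

test_that("the MC shell volume matches the analytic spherical shell", {
  box <- simulation_box(40)
  m <- synthetic_model("ideal_gas", rho = 200 / 40^3, seed = 12)
  sys <- gen_solvent_ensemble(matrix(20, 1, 3), box, m, n_frames = 10)
  bd <- estimate_bulk_density(sys, 1, analysis_config(seed = 9, nu = 40,
                                                      n_mc_points = 1e6))
  expect_equal(bd$shell_volume, (4 / 3) * pi * (15^3 - 10^3), tolerance = 0.01)
  # for a single-site species the molecular shell measure agrees with the
  # geometric volume (80k insertions here, ~1% sampling error)
  expect_equal(bd$shell_measure, bd$shell_volume, tolerance = 0.03)
})

test_that("bulk density recovers the generator density for the ideal gas", {
  bd <- ideal_gas_kbi()$bulk
  set_molar <- per_a3_to_molar(fixture_rho())
  expect_lt(abs(bd$rho_molar - set_molar), 3 * bd$rho_molar_se)
})

test_that("the short-ranged well does not contaminate the bulk shell", {
  bd <- square_well_kbi()$bulk
  # fixed-count placement depletes the bulk by V / V_eff where the well
  # region is enhanced by e^eps and the core excluded
  v <- 31^3
  v_eff <- v - vx_a3 + (exp(1) - 1) * vw_a3
  expected <- per_a3_to_molar(fixture_rho() * v / v_eff)
  expect_lt(abs(bd$rho_molar - expected), 3 * bd$rho_molar_se)
  expect_equal(bd$rho_molar, per_a3_to_molar(fixture_rho()), tolerance = 0.02)
})

test_that("an empty shell is reported as unusable", {
  at <- atom_table("X1", 1L, "GLY")
  sp <- solvent_species("s", atom_table("A1", 1L, "SOL", solvent = TRUE), 2L)
  sys <- solvation_system(at, matrix(15, 1, 3), list(s = sp),
                          list(s = rbind(c(16, 15, 15), c(17, 15, 15))),
                          simulation_box(31))
  expect_error(estimate_bulk_density(sys, 1, analysis_config(seed = 2,
                                                             n_mc_points = 1e4)),
               "bulk shell")
})

test_that("the ideal-gas KBI is statistically zero beyond the near field", {
  k <- ideal_gas_kbi()
  sel <- k$R >= 5
  expect_true(all(abs(k$G[sel]) < 3 * k$G_se[sel]))
})

test_that("the hard-wall KBI equals the analytic excluded volume", {
  k <- hard_wall_kbi()
  cv <- convergence_check(k, window = 3, tol = 0.005)
  expect_true(cv$converged)
  analytic <- -vx_a3 * to_lmol
  expect_equal(k$G[k$R == cv$converged_R], analytic, tolerance = 0.02)
})

test_that("the square-well KBI equals the closed-form shell integral", {
  k <- square_well_kbi()
  cv <- convergence_check(k, window = 3, tol = 0.005)
  expect_true(cv$converged)
  expect_gte(cv$converged_R, 4)         # not before the well edge d + w
  analytic <- ((exp(1) - 1) * vw_a3 - vx_a3) * to_lmol
  expect_equal(k$G[k$R == cv$converged_R], analytic, tolerance = 0.05)
})

test_that("counting and shell-integral KBI routes agree", {
  # independent route: G = sum_b (g_b - 1) v_b with bin volumes from a
  # direct MC point histogram (the iso-surface-area form, integrated).
  # The two routes share the observed counts, so the residual is set by
  # the MC-vs-insertion volume noise: ~0.5% of |G| for the hard wall and
  # ~1.5% for the square well (difference of two larger volume terms).
  set.seed(99)
  box <- 31; n_pts <- 4e6
  pts <- matrix(runif(n_pts * 3, 0, box), ncol = 3)
  d <- sqrt(rowSums(sweep(pts, 2, rep(box / 2, 3))^2))  # point solute at center
  vb <- tabulate(pmin(floor(d / 0.1) + 1, 150), nbins = 150) / n_pts * box^3
  routes <- function(k) {
    g <- k$mddf$g / k$ref_scale       # normalize to the bulk density
    keep <- !is.na(g) & k$R <= 6
    g_shell <- sum((g[keep] - 1) * vb[keep]) - sum(vb[!keep & k$R <= 6])
    c(shell = g_shell * to_lmol, counting = k$G[k$R == 6])
  }
  hw <- routes(hard_wall_kbi())
  expect_equal(hw[["shell"]], hw[["counting"]], tolerance = 0.01)
  sw <- routes(square_well_kbi())
  expect_equal(sw[["shell"]], sw[["counting"]], tolerance = 0.02)
})

test_that("preferential parameters reproduce the worked two-row example", {
  p10 <- preferential_parameters(3.61, -3.58, rho_c = 1.43, rho_w = 50.12)
  expect_equal(p10$Gamma_pc, 10.29, tolerance = 0.1/10.29)
  p40 <- preferential_parameters(1.23, -5.70, rho_c = 5.57, rho_w = 34.27)
  expect_equal(p40$Gamma_pc, 38.67, tolerance = 0.1/38.67)
})

test_that("Gamma_pw = -(rho_w / rho_c) Gamma_pc holds to machine precision", {
  set.seed(7)
  for (i in 1:20) {
    p <- preferential_parameters(runif(1, -5, 5), runif(1, -5, 5),
                                 rho_c = runif(1, 0.5, 10),
                                 rho_w = runif(1, 20, 60))
    expect_equal(p$Gamma_pw, -(p$rho_w / p$rho_c) * p$Gamma_pc,
                 tolerance = 1e-10)
  }
  k <- binary_kbis()
  gam <- preferential_parameters(k$cosolvent, k$water, R = 8)
  expect_equal(gam$Gamma_pw, -(gam$rho_w / gam$rho_c) * gam$Gamma_pc,
               tolerance = 1e-10)
})

test_that("equal KBIs give vanishing preferential parameters", {
  p <- preferential_parameters(1.7, 1.7, rho_c = 2, rho_w = 50)
  expect_identical(p$Gamma_pc, 0)
  expect_identical(p$Gamma_pw, 0)
})

test_that("profiles on mismatched grids are refused", {
  k <- binary_kbis()
  short <- k$water
  short$R <- short$R[-1]; short$G <- short$G[-1]
  expect_error(preferential_parameters(k$cosolvent, short), "grids")
})

test_that("plateau detection converges early for the null model", {
  cv <- convergence_check(ideal_gas_kbi(), window = 3, tol = 0.05)
  expect_true(cv$converged)
  expect_lte(cv$converged_R, 5)
})

test_that("a drifting profile is reported as non-converged", {
  fake <- list(R = seq(0.1, 15, by = 0.1), G = 0.05 * seq(0.1, 15, by = 0.1))
  cv <- convergence_check(fake, window = 3, tol = 0.05)
  expect_false(cv$converged)
  expect_true(is.na(cv$converged_R))
})
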