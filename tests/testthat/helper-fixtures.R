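# Shared fixtures and independent oracles. Heavy ensembles are generated
# once per test run and cached; all seeds are fixed so runs are
# bit-reproducible.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# box / density shared by the point-solute oracle fixtures: 1000 molecules
# in a 31 A cube is a water-like number density (~55.7 mol/L)
fixture_box <- function() simulation_box(31)
fixture_rho <- function() 1000 / 31^3
fixture_center <- function() matrix(31 / 2, 1, 3)

fixture_config <- function(...) {
  args <- utils::modifyList(list(seed = 3, n_mc_points = 1e6), list(...))
  do.call(analysis_config, args)
}

ideal_gas_fixture <- function() cached("ideal_gas", function() {
  m <- synthetic_model("ideal_gas", rho = fixture_rho(), seed = 5)
  gen_solvent_ensemble(fixture_center(), fixture_box(), m, n_frames = 100)
})

hard_wall_fixture <- function() cached("hard_wall", function() {
  m <- synthetic_model("hard_wall", d = 3, rho = fixture_rho(), seed = 7)
  gen_solvent_ensemble(fixture_center(), fixture_box(), m, n_frames = 2000)
})

square_well_fixture <- function() cached("square_well", function() {
  m <- synthetic_model("square_well", d = 3, eps = 1, w = 1,
                       rho = fixture_rho(), seed = 11)
  gen_solvent_ensemble(fixture_center(), fixture_box(), m, n_frames = 2000)
})

ideal_gas_kbi <- function() cached("ideal_gas_kbi", function() {
  compute_kbi(ideal_gas_fixture(), 1, fixture_config())
})

hard_wall_kbi <- function() cached("hard_wall_kbi", function() {
  compute_kbi(hard_wall_fixture(), 1, fixture_config())
})

square_well_kbi <- function() cached("square_well_kbi", function() {
  compute_kbi(square_well_fixture(), 1, fixture_config())
})

# two-species fixture around a point solute: square-well cosolvent
# (3-atom rigid rod with a protruding HO site) + ideal-gas water
binary_fixture <- function() cached("binary", function() {
  models <- list(
    cosolvent = synthetic_model("square_well", d = 3, eps = 1, w = 1,
                                rho = 0.004, seed = 21),
    water = synthetic_model("ideal_gas", rho = fixture_rho(), seed = 22))
  species <- list(
    cosolvent = solvent_species("cosolvent", atom_table(
      c("C1", "O1", "HO"), rep(1L, 3), rep("CSL", 3), solvent = TRUE), 1L),
    water = solvent_species("water", atom_table(
      "OW", 1L, "SOL", solvent = TRUE), 1L))
  templates <- list(cosolvent = rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.4, 0, 0)),
                    water = matrix(0, 1, 3))
  gen_binary_solvent(fixture_center(), fixture_box(), models, n_frames = 400,
                     templates = templates, species = species)
})

binary_kbis <- function() cached("binary_kbis", function() {
  sys <- binary_fixture()
  cfg <- fixture_config(n_mc_points = 2e5)
  md_c <- compute_mddf(sys, "cosolvent", cfg)
  md_w <- compute_mddf(sys, "water", cfg)
  list(cosolvent = compute_kbi(sys, "cosolvent", cfg, mddf = md_c),
       water = compute_kbi(sys, "water", cfg, mddf = md_w))
})

# ---- independent brute-force oracle: all pairs x all 27 periodic images ----

bf_min_distances <- function(solute_xyz, solvent_xyz, m, box) {
  box <- as.numeric(box)
  wrap <- function(x) sweep(x, 2, box, function(v, L) v - floor(v / L) * L)
  su <- wrap(rbind(solute_xyz))
  sv <- wrap(rbind(solvent_xyz))
  n <- nrow(sv) / m
  out <- data.frame(molecule = seq_len(n), dmin = NA_real_,
                    solute_atom = NA_integer_, solvent_atom = NA_integer_)
  for (mol in seq_len(n)) {
    best <- Inf; bs <- NA; ba <- NA
    for (s in seq_len(nrow(su))) {
      for (a in seq_len(m)) {
        p <- sv[(mol - 1) * m + a, ]
        q <- su[s, ]
        for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
          d <- sqrt((q[1] - p[1] + ix * box[1])^2 +
                    (q[2] - p[2] + iy * box[2])^2 +
                    (q[3] - p[3] + iz * box[3])^2)
          if (d < best) { best <- d; bs <- s; ba <- a }
        }
      }
    }
    out$dmin[mol] <- best; out$solute_atom[mol] <- bs; out$solvent_atom[mol] <- ba
  }
  out
}

# random tiny system for oracle comparisons
random_tiny_system <- function(seed) {
  set.seed(seed)
  box <- simulation_box(runif(3, 8, 15))
  n_su <- sample(1:5, 1)
  su <- cbind(runif(n_su, 0, box[1]), runif(n_su, 0, box[2]), runif(n_su, 0, box[3]))
  m <- sample(1:3, 1)
  n_mol <- sample(1:8, 1)
  centers <- cbind(runif(n_mol, 0, box[1]), runif(n_mol, 0, box[2]),
                   runif(n_mol, 0, box[3]))
  sv <- centers[rep(seq_len(n_mol), each = m), , drop = FALSE] +
    matrix(runif(n_mol * m * 3, -1, 1), n_mol * m, 3)
  at_su <- atom_table(paste0("X", seq_len(n_su)), rep(1L, n_su),
                      rep("GLY", n_su))
  sp <- solvent_species("s", atom_table(paste0("A", seq_len(m)), rep(1L, m),
                                        rep("SOL", m), solvent = TRUE), n_mol)
  list(system = solvation_system(at_su, su, list(s = sp), list(s = sv), box),
       su = su, sv = sv, m = m, box = box)
}

# minimal ideal helix / extended peptide wrapped as a 1-frame system with a
# single faraway solvent molecule (the container requires one species)
peptide_system <- function(xyz_list, atoms, box_len = 80) {
  box <- simulation_box(box_len)
  nf <- length(xyz_list)
  su <- array(unlist(xyz_list), c(nrow(atoms), 3, nf))
  sp <- solvent_species("w", atom_table("OW", 1L, "SOL", solvent = TRUE), 1L)
  sv <- array(rep(c(1, 1, 1), nf), c(1, 3, nf))
  solvation_system(atoms, su, list(w = sp), list(w = sv), box)
}
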