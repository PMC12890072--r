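#' Synthetic solvent placement model
#'
#' Defines the solute-solvent interaction model used by the synthetic
#' ensemble generators. Three kinds are available, all with analytically
#' known minimum-distance distribution functions:
#' \describe{
#'   \item{`ideal_gas`}{no interaction; g(r) = 1 everywhere.}
#'   \item{`hard_wall`}{solvent centers excluded wherever the minimum
#'     distance to the solute is below `d`; g = 0 below `d`, 1 beyond.}
#'   \item{`square_well`}{hard wall at `d` plus an attractive well of depth
#'     `eps` (in units of kT) over minimum distances in `[d, d + w]`;
#'     g = exp(eps) in the well, 1 outside.}
#' }
#' Because molecules are placed independently (solvent-solvent ideality),
#' these closed forms are exact expectations, which makes the generators
#' usable as oracles for the MDDF/KBI machinery.
#'
#' @param kind one of `"ideal_gas"`, `"hard_wall"`, `"square_well"`
#' @param d wall distance, Angstrom (minimum distance to any solute atom)
#' @param eps well depth, dimensionless (energy in kT units)
#' @param w well width, Angstrom: the well spans `[d, d + w]`
#' @param rho target number density, molecules/A^3; the generated molecule
#'   count is `round(rho * V_box)` exactly
#' @param seed integer seed
#' @return object of class `synthetic_model`
#' @export
synthetic_model <- function(kind = c("ideal_gas", "hard_wall", "square_well"),
                            d = 0, eps = 0, w = 1, rho, seed = 1L) {
  kind <- match.arg(kind)
  if (d < 0) stop("wall distance d must be >= 0")
  if (kind == "square_well" && w <= 0) stop("well width w must be > 0")
  if (rho <= 0) stop("density rho must be > 0")
  structure(list(kind = kind, d = d, eps = eps, w = w, rho = rho,
                 seed = as.integer(seed)),
            class = "synthetic_model")
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat(sprintf("Synthetic model: %s", x$kind))
  if (x$kind != "ideal_gas") cat(sprintf(", d = %g A", x$d))
  if (x$kind == "square_well")
    cat(sprintf(", well [%g, %g] A, depth %g kT", x$d, x$d + x$w, x$eps))
  cat(sprintf(", rho = %g /A^3 (%.2f mol/L)\n", x$rho, per_a3_to_molar(x$rho)))
  invisible(x)
}

# Uniform random rotation matrices via unit quaternions: returns a
# 3 x 3 x n array. Marsaglia's method (4 normals, normalized).
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q * q))
  a <- q[, 1]; b <- q[, 2]; c <- q[, 3]; d <- q[, 4]
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- a * a + b * b - c * c - d * d
  R[1, 2, ] <- 2 * (b * c - a * d)
  R[1, 3, ] <- 2 * (b * d + a * c)
  R[2, 1, ] <- 2 * (b * c + a * d)
  R[2, 2, ] <- a * a - b * b + c * c - d * d
  R[2, 3, ] <- 2 * (c * d - a * b)
  R[3, 1, ] <- 2 * (b * d - a * c)
  R[3, 2, ] <- 2 * (c * d + a * b)
  R[3, 3, ] <- a * a - b * b - c * c + d * d
  R
}

# Place n rigid copies of `template` (m x 3, centered) at uniform random
# positions/orientations in `box`. Returns (n*m) x 3 molecule-major coords.
# Single-atom templates skip the rotation draw entirely.
place_rigid <- function(template, n, box) {
  m <- nrow(template)
  box <- as.numeric(box)
  centers <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                   stats::runif(n, 0, box[3]))
  if (m == 1) return(centers)
  R <- random_rotations(n)
  out <- matrix(0, n * m, 3)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * m + 1):(i * m)
    out[rows, ] <- template %*% t(R[, , i]) +
      matrix(centers[i, ], m, 3, byrow = TRUE)
  }
  out
}

# Minimum distance from each of n molecules (coords molecule-major,
# (n*m) x 3) to the solute atom set. Returns length-n vector.
# Row-wise pmin reduction keeps everything vectorized.
mol_min_dist <- function(coords, m, solute_xyz, box) {
  D <- min_image_dist(rbind(solute_xyz), coords, box)  # S x (n*m)
  atom_min <- if (nrow(D) == 1) D[1, ] else Reduce(pmin, asplit(D, 1))
  if (m == 1) return(atom_min)
  n <- length(atom_min) / m
  Reduce(pmin, asplit(matrix(atom_min, m, n), 1))
}

# Boltzmann weight of the square-well / hard-wall models, normalized so the
# maximum weight is 1 (well region). Used for rejection sampling.
model_accept_prob <- function(model, dmin) {
  switch(model$kind,
    ideal_gas = rep(1, length(dmin)),
    hard_wall = as.numeric(dmin >= model$d),
    square_well = ifelse(dmin < model$d, 0,
                  ifelse(dmin < model$d + model$w, 1, exp(-model$eps)))
  )
}

#' Generate a synthetic solvent ensemble around a solute
#'
#' Places `round(rho * V_box)` rigid solvent molecules per frame at uniform
#' random positions and orientations, filtered by the model's Boltzmann
#' weight on the molecule's minimum distance to the solute (rejection
#' sampling, so the stationary density profile is exactly
#' `rho_eff * exp(-u(r))` with the square-well potential `u`). The solute is
#' held fixed across frames. Frames are statistically independent.
#'
#' @param solute_xyz solute coordinates, `n x 3` matrix (Angstrom)
#' @param box a [simulation_box()]
#' @param model a [synthetic_model()]
#' @param n_frames number of frames to generate
#' @param species a [solvent_species()] giving the rigid molecule layout;
#'   its `n_molecules` field is ignored and replaced by `round(rho * V)`.
#'   Default: a single-atom species named `"solvent"`.
#' @param template `m x 3` internal geometry of one molecule (centered);
#'   default: a single point, or for multi-atom species an error unless given
#' @param solute_atoms optional atom table for the solute; default: one
#'   `"X"` pseudo-atom per coordinate row, residue `"UNK"`
#' @return a [solvation_system()] with one species
#' @examples
#' box <- simulation_box(31)
#' m <- synthetic_model("hard_wall", d = 3, rho = 0.0336, seed = 7)
#' sys <- gen_solvent_ensemble(matrix(as.numeric(box)/2, 1), box, m, n_frames = 5)
#' @export
gen_solvent_ensemble <- function(solute_xyz, box, model, n_frames,
                                 species = NULL, template = NULL,
                                 solute_atoms = NULL) {
  solute_xyz <- rbind(solute_xyz)
  v <- box_volume(box)
  n_mol <- as.integer(round(model$rho * v))
  if (n_mol < 1) stop("rho * V_box < 0.5: no molecules to place")
  if (is.null(species)) {
    species <- solvent_species(
      "solvent",
      atom_table("X1", 1L, "SOL", element = "X", solvent = TRUE),
      n_mol)
  } else {
    species$n_molecules <- n_mol
  }
  m <- species$atoms_per_molecule
  if (is.null(template)) {
    if (m > 1) stop("multi-atom species need an explicit rigid template")
    template <- matrix(0, 1, 3)
  }
  template <- rbind(template)
  if (nrow(template) != m) stop("template rows must equal atoms_per_molecule")
  template <- template - matrix(colMeans(template), m, 3, byrow = TRUE)
  if (!all(is.finite(solute_xyz))) stop("non-finite solute coordinates")

  xyz <- with_seed(model$seed, {
    arr <- array(0, c(n_mol * m, 3, n_frames))
    for (f in seq_len(n_frames)) {
      placed <- 0L
      acc <- matrix(0, n_mol * m, 3)
      attempts <- 0L
      while (placed < n_mol) {
        batch <- max(64L, ceiling((n_mol - placed) * 1.3))
        cand <- place_rigid(template, batch, box)
        dmin <- mol_min_dist(cand, m, solute_xyz, box)
        keep <- which(stats::runif(batch) < model_accept_prob(model, dmin))
        attempts <- attempts + batch
        if (attempts > 1000L && (placed + length(keep)) / attempts < 1e-3)
          stop("placement acceptance rate < 1e-3; lower rho or eps")
        if (length(keep)) {
          take <- keep[seq_len(min(length(keep), n_mol - placed))]
          rows <- rep((take - 1) * m, each = m) + seq_len(m)
          dst <- (placed * m + 1):((placed + length(take)) * m)
          acc[dst, ] <- cand[rows, , drop = FALSE]
          placed <- placed + length(take)
        }
      }
      arr[, , f] <- acc
    }
    arr
  })

  if (is.null(solute_atoms)) {
    solute_atoms <- atom_table(paste0("X", seq_len(nrow(solute_xyz))),
                               rep(1L, nrow(solute_xyz)),
                               rep("UNK", nrow(solute_xyz)), element = "X",
                               polarity_table = c(UNK = "n/a"))
  }
  su_xyz <- array(rep(as.numeric(solute_xyz), n_frames),
                  c(nrow(solute_xyz), 3, n_frames))
  sp <- stats::setNames(list(species), species$name)
  solvation_system(solute_atoms, su_xyz, sp,
                   stats::setNames(list(xyz), species$name), box)
}

#' Generate a two-species synthetic ensemble
#'
#' Places two solvent species independently around the same fixed solute,
#' each according to its own [synthetic_model()]. The canonical use is a
#' square-well "cosolvent" plus an ideal-gas "water": by construction the
#' cosolvent accumulates near the solute, so the preferential interaction
#' parameter Gamma_pc must come out positive (and Gamma_pw negative).
#'
#' @param solute_xyz solute coordinates, `n x 3`
#' @param box a [simulation_box()]
#' @param models named list of two [synthetic_model()] objects; names become
#'   the species names
#' @param n_frames frames to generate
#' @param templates optional named list of rigid templates (see
#'   [gen_solvent_ensemble()])
#' @param species optional named list of [solvent_species()] layouts
#' @param solute_atoms optional solute atom table
#' @return a [solvation_system()] with two species
#' @export
gen_binary_solvent <- function(solute_xyz, box, models, n_frames,
                               templates = NULL, species = NULL,
                               solute_atoms = NULL) {
  if (length(models) != 2 || is.null(names(models)))
    stop("models must be a named list of two synthetic_model objects")
  parts <- lapply(names(models), function(nm) {
    sp <- if (!is.null(species)) species[[nm]] else {
      solvent_species(nm, atom_table(paste0(toupper(substr(nm, 1, 1)), "1"),
                                     1L, "SOL", solvent = TRUE), 1L)
    }
    gen_solvent_ensemble(solute_xyz, box, models[[nm]], n_frames,
                         species = sp,
                         template = if (!is.null(templates)) templates[[nm]],
                         solute_atoms = solute_atoms)
  })
  names(parts) <- names(models)
  solvation_system(parts[[1]]$solute_atoms, parts[[1]]$solute_xyz,
                   lapply(parts, function(p) p$species[[1]]),
                   lapply(parts, function(p) p$solvent_xyz[[1]]),
                   box)
}
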