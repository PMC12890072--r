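#' Solvent species descriptor
#'
#' Describes one solvent species: its name, rigid per-molecule atom layout
#' and molecule count. Coordinate arrays for the species always have
#' `n_molecules * atoms_per_molecule` rows per frame, molecule-major
#' (all atoms of molecule 1, then molecule 2, ...).
#'
#' @param name species name, e.g. `"water"` or `"cosolvent"`
#' @param atoms atom table for ONE molecule (see [atom_table()]); its row
#'   count defines `atoms_per_molecule`
#' @param n_molecules non-negative molecule count
#' @return object of class `solvent_species`
#' @export
solvent_species <- function(name, atoms, n_molecules) {
  stopifnot(is.character(name), length(name) == 1, nrow(atoms) >= 1)
  n_molecules <- as.integer(n_molecules)
  if (is.na(n_molecules) || n_molecules < 0)
    stop("n_molecules must be a non-negative integer")
  structure(list(
    name = name,
    atoms_per_molecule = nrow(atoms),
    atom_records = atoms,
    n_molecules = n_molecules
  ), class = "solvent_species")
}

#' @export
print.solvent_species <- function(x, ...) {
  cat(sprintf("Solvent species '%s': %d molecules x %d atoms (%s)\n",
              x$name, x$n_molecules, x$atoms_per_molecule,
              paste(x$atom_records$atom_name, collapse = " ")))
  invisible(x)
}

#' Multi-frame solute-solvent ensemble
#'
#' The central container: a solute (atom table plus per-frame coordinates)
#' and one or more solvent species (per-frame coordinates, molecule-major),
#' each frame living in a periodic orthorhombic box. All coordinates are
#' Angstrom.
#'
#' @param solute_atoms atom table of the solute (see [atom_table()])
#' @param solute_xyz array `n_solute_atoms x 3 x n_frames` (a plain
#'   `n x 3` matrix is promoted to a single frame)
#' @param species named list of [solvent_species()] objects
#' @param solvent_xyz named list (same names as `species`) of arrays
#'   `(n_molecules*atoms_per_molecule) x 3 x n_frames`
#' @param box a [simulation_box()] shared by all frames, or an
#'   `n_frames x 3` matrix of per-frame box lengths
#' @return object of class `solvation_system`
#' @export
solvation_system <- function(solute_atoms, solute_xyz, species, solvent_xyz, box) {
  if (is.matrix(solute_xyz)) solute_xyz <- array(solute_xyz, c(dim(solute_xyz), 1))
  n_frames <- dim(solute_xyz)[3]
  if (n_frames < 1) stop("at least one frame required")
  if (dim(solute_xyz)[1] != nrow(solute_atoms))
    stop("solute coordinate rows do not match the atom table")
  if (!all(is.finite(solute_xyz))) stop("non-finite solute coordinates")
  if (is.null(names(species)) || any(!nzchar(names(species))))
    names(species) <- vapply(species, function(s) s$name, "")
  solvent_xyz <- solvent_xyz[names(species)]
  for (nm in names(species)) {
    sp <- species[[nm]]
    xyz <- solvent_xyz[[nm]]
    if (is.matrix(xyz)) xyz <- array(xyz, c(dim(xyz), 1))
    if (dim(xyz)[3] != n_frames)
      stop("species '", nm, "': frame count mismatch")
    if (dim(xyz)[1] != sp$n_molecules * sp$atoms_per_molecule)
      stop("species '", nm, "': coordinate rows != n_molecules * atoms_per_molecule")
    if (!all(is.finite(xyz))) stop("species '", nm, "': non-finite coordinates")
    solvent_xyz[[nm]] <- xyz
  }
  if (inherits(box, "simulation_box"))
    box <- matrix(as.numeric(box), n_frames, 3, byrow = TRUE)
  box <- rbind(box)
  if (nrow(box) == 1) box <- box[rep(1, n_frames), , drop = FALSE]
  if (nrow(box) != n_frames || any(box <= 0))
    stop("box must give 3 positive lengths per frame")
  structure(list(
    solute_atoms = solute_atoms,
    solute_xyz = solute_xyz,
    species = species,
    solvent_xyz = solvent_xyz,
    box = box,
    n_frames = n_frames
  ), class = "solvation_system")
}

#' @export
print.solvation_system <- function(x, ...) {
  cat("Solvation system\n")
  cat(sprintf("  solute : %d atoms, %d residues\n", nrow(x$solute_atoms),
              length(unique(x$solute_atoms$residue_index))))
  for (sp in x$species)
    cat(sprintf("  solvent: %s, %d molecules x %d atoms\n",
                sp$name, sp$n_molecules, sp$atoms_per_molecule))
  cat(sprintf("  frames : %d; box (frame 1): %.2f x %.2f x %.2f A\n",
              x$n_frames, x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' @export
summary.solvation_system <- function(object, ...) {
  print(object)
  v <- box_volume(object$box[1, ])
  for (sp in object$species) {
    rho <- sp$n_molecules / v
    cat(sprintf("  %s number density: %.5g molecules/A^3 (%.2f mol/L)\n",
                sp$name, rho, per_a3_to_molar(rho)))
  }
  invisible(object)
}

# frame accessors (always n x 3 matrices, even for single-atom solutes)
frame_solute <- function(system, frame)
  matrix(system$solute_xyz[, , frame], ncol = 3)
frame_solvent <- function(system, species, frame)
  matrix(system$solvent_xyz[[species]][, , frame], ncol = 3)
frame_box <- function(system, frame) system$box[frame, ]

# resolve a species argument (name or index) to its name
resolve_species <- function(system, species) {
  nm <- if (is.character(species)) species else names(system$species)[species]
  if (is.na(nm) || !nm %in% names(system$species))
    stop("unknown solvent species '", species, "'; have: ",
         paste(names(system$species), collapse = ", "))
  nm
}

#' Analysis configuration
#'
#' Binning and reference parameters shared by MDDF and KBI computations.
#'
#' @param bin_width histogram bin width, Angstrom (default 0.1)
#' @param r_max maximum minimum-distance `R` considered, Angstrom
#'   (default 15): the outer edge of the "protein domain"
#' @param bulk_shell two distances (Angstrom) bounding the open shell, in
#'   minimum distance from the solute surface, used to estimate bulk
#'   solvent densities (default `c(10, 15)`)
#' @param nu oversampling factor for the ideal-gas reference: `nu * n_molecules`
#'   random rigid insertions per frame (default 5)
#' @param n_mc_points Monte-Carlo sample size for shell/excluded volume
#'   estimates (default 1e6)
#' @param seed integer seed controlling the reference insertions and
#'   Monte-Carlo volume sampling
#' @return object of class `analysis_config`
#' @export
analysis_config <- function(bin_width = 0.1, r_max = 15,
                            bulk_shell = c(10, 15), nu = 5,
                            n_mc_points = 1e6, seed = 1L) {
  if (!(bin_width > 0 && bin_width < r_max))
    stop("need 0 < bin_width < r_max")
  if (length(bulk_shell) != 2 || bulk_shell[1] <= 0 || bulk_shell[1] >= bulk_shell[2] ||
      bulk_shell[2] > r_max)
    stop("bulk_shell must satisfy 0 < lower < upper <= r_max")
  if (nu < 1) stop("nu must be >= 1")
  structure(list(bin_width = bin_width, r_max = r_max, bulk_shell = bulk_shell,
                 nu = as.integer(nu), n_mc_points = as.integer(n_mc_points),
                 seed = as.integer(seed)),
            class = "analysis_config")
}
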