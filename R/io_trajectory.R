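# Trajectory atom ordering convention: solute atoms first, then each
# solvent species in declaration order, molecule-major. A solvation_system
# acts as the "structure" that tells readers how to split the columns.

system_atom_names <- function(system) {
  c(system$solute_atoms$atom_name,
    unlist(lapply(system$species, function(sp)
      rep(sp$atom_records$atom_name, sp$n_molecules))))
}

system_total_atoms <- function(system) {
  nrow(system$solute_atoms) +
    sum(vapply(system$species, function(sp)
      sp$n_molecules * sp$atoms_per_molecule, 0))
}

# frame as one (solute + all species) coordinate block
frame_all_coords <- function(system, f) {
  do.call(rbind, c(list(rbind(frame_solute(system, f))),
                   lapply(names(system$species), function(nm)
                     frame_solvent(system, nm, f))))
}

# rebuild a system from a stack of full-frame coordinate blocks
system_from_frames <- function(template, frames, box = NULL) {
  ns <- nrow(template$solute_atoms)
  nf <- length(frames)
  su <- array(0, c(ns, 3, nf))
  sv <- lapply(template$species, function(sp)
    array(0, c(sp$n_molecules * sp$atoms_per_molecule, 3, nf)))
  for (f in seq_len(nf)) {
    blk <- frames[[f]]
    su[, , f] <- blk[seq_len(ns), , drop = FALSE]
    off <- ns
    for (nm in names(template$species)) {
      sp <- template$species[[nm]]
      k <- sp$n_molecules * sp$atoms_per_molecule
      sv[[nm]][, , f] <- blk[off + seq_len(k), , drop = FALSE]
      off <- off + k
    }
  }
  if (is.null(box)) box <- template$box[rep(1, nf), , drop = FALSE]
  solvation_system(template$solute_atoms, su, template$species, sv, box)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Plain-text XYZ with one block per frame: atom count, a comment line
#' carrying the box lengths (`box Lx Ly Lz`, Angstrom), then
#' `name x y z` records at 0.0001 A precision. Atoms are ordered solute
#' first, then each species molecule-major.
#'
#' @param system a [solvation_system()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_xyz <- function(system, path) {
  names <- system_atom_names(system)
  n <- length(names)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(system$n_frames)) {
    xyz <- frame_all_coords(system, f)
    writeLines(c(as.character(n),
                 sprintf("box %.6f %.6f %.6f", system$box[f, 1],
                         system$box[f, 2], system$box[f, 3]),
                 sprintf("%-6s %12.4f %12.4f %12.4f", names, xyz[, 1],
                         xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

read_trajectory_xyz <- function(path, structure, box = NULL) {
  lines <- readLines(path, warn = FALSE)
  n_expect <- system_total_atoms(structure)
  frames <- list(); boxes <- NULL
  i <- 1; f <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom count at line ", i)
    if (n != n_expect)
      stop("atom-count mismatch at frame ", f, ": file has ", n,
           ", structure expects ", n_expect)
    comment <- lines[i + 1]
    bx <- NULL
    if (grepl("^\\s*box\\s", comment)) {
      bv <- suppressWarnings(as.numeric(strsplit(trimws(comment), "\\s+")[[1]][2:4]))
      if (!anyNA(bv)) bx <- bv
    }
    rec <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(rec), "\\s+"))
    xyz <- suppressWarnings(matrix(as.numeric(parts[, 2:4]), n, 3))
    if (anyNA(xyz)) stop("malformed XYZ coordinates in frame ", f)
    f <- f + 1
    frames[[f]] <- xyz
    if (is.null(bx)) {
      if (is.null(box)) stop("frame ", f - 1, " carries no box and none was supplied")
      bx <- as.numeric(simulation_box(box))
    }
    boxes <- rbind(boxes, bx)
    i <- i + 2 + n
  }
  if (f == 0) stop("no frames in ", path)
  system_from_frames(structure, frames, boxes)
}

#' Write a trajectory as binary DCD
#'
#' Minimal CHARMM-style DCD (native endianness, no unit cell block):
#' standard header records, then per frame one float record per coordinate
#' axis. Readable by [bio3d::read.dcd()] and the usual MD tooling. Since
#' the format carries no box here, readers take the box from the structure
#' or an explicit argument.
#'
#' @param system a [solvation_system()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_dcd <- function(system, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_atoms <- system_total_atoms(system)
  nf <- system$n_frames
  rec <- function(writer) {
    # Fortran-style record: byte length, payload, byte length
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    payload <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(as.integer(length(payload)), con, size = 4)
    writeBin(payload, con)
    writeBin(as.integer(length(payload)), con, size = 4)
  }
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- as.integer(nf)   # frames
    icntrl[2] <- 1L               # first step
    icntrl[3] <- 1L               # save interval
    icntrl[4] <- as.integer(nf)   # total steps
    icntrl[20] <- 24L             # CHARMM version marker
    writeBin(icntrl[1:9], c2, size = 4)
    writeBin(1, c2, size = 4)     # delta as float32
    writeBin(icntrl[11:20], c2, size = 4)
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4)
    writeChar(formatC("written by solvkb", width = -80), c2, nchars = 80,
              eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(n_atoms), c2, size = 4))
  for (f in seq_len(nf)) {
    xyz <- frame_all_coords(system, f)
    for (k in 1:3) rec(function(c2) writeBin(xyz[, k], c2, size = 4))
  }
  invisible(path)
}

#' Read a trajectory into a solvation system
#'
#' Reads a multi-frame coordinate file and splits each frame into solute
#' and solvent blocks according to a structure template (a
#' [solvation_system()] whose atom counts and species layout describe the
#' file's atom ordering: solute first, then each species molecule-major).
#' XYZ files may carry the box on their comment line; DCD files written
#' without a unit cell take the box from `box` or the template. XTC is not
#' supported: no installed reader exists for it here, so convert to DCD or
#' XYZ first.
#'
#' @param path trajectory file
#' @param structure template [solvation_system()] (its own frames are
#'   ignored)
#' @param format `"xyz"` or `"dcd"`; inferred from the extension when
#'   missing
#' @param box optional [simulation_box()] (or per-frame matrix) overriding
#'   the template's box for formats that carry none
#' @return a [solvation_system()] with the file's frames, in file order
#' @export
read_trajectory <- function(path, structure, format = NULL, box = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (format == "xtc")
    stop("XTC is not supported (no installed reader); convert to DCD or XYZ")
  format <- match.arg(format, c("xyz", "dcd"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "xyz") return(read_trajectory_xyz(path, structure, box))
  n_expect <- system_total_atoms(structure)
  m <- bio3d::read.dcd(path, verbose = FALSE)
  if (ncol(m) != 3 * n_expect)
    stop("atom-count mismatch at frame 0: file has ", ncol(m) / 3,
         " atoms, structure expects ", n_expect)
  frames <- lapply(seq_len(nrow(m)), function(f)
    matrix(m[f, ], ncol = 3, byrow = TRUE))
  boxes <- if (!is.null(box)) {
    if (inherits(box, "simulation_box"))
      matrix(as.numeric(box), length(frames), 3, byrow = TRUE) else rbind(box)
  } else NULL
  system_from_frames(structure, frames, boxes)
}

#' Write a synthetic fixture directory
#'
#' Writes a system as `structure.pdb` (solute only), `trajectory.xyz`
#' (solute + solvent, box on the comment lines) and `manifest.yaml`
#' (species layout and box), so a fixture can be regenerated, shipped and
#' read back without any binary file.
#'
#' @param system a [solvation_system()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(system$solute_atoms, frame_solute(system, 1),
                  file.path(dir, "structure.pdb"), "pdb")
  write_trajectory_xyz(system, file.path(dir, "trajectory.xyz"))
  manifest <- list(
    box = as.numeric(system$box[1, ]),
    n_frames = system$n_frames,
    solute_atoms = nrow(system$solute_atoms),
    species = lapply(system$species, function(sp) list(
      name = sp$name, n_molecules = sp$n_molecules,
      atoms_per_molecule = sp$atoms_per_molecule,
      atom_names = sp$atom_records$atom_name,
      residue_name = sp$atom_records$residue_name[1]))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a fixture directory back into a solvation system
#'
#' @param dir directory written by [write_fixture()]
#' @return a [solvation_system()]
#' @export
read_fixture <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  st <- read_structure(file.path(dir, "structure.pdb"), "pdb")
  species <- lapply(manifest$species, function(m) {
    solvent_species(m$name,
                    atom_table(unlist(m$atom_names),
                               rep(1L, m$atoms_per_molecule),
                               rep(m$residue_name, m$atoms_per_molecule),
                               solvent = TRUE),
                    m$n_molecules)
  })
  names(species) <- vapply(species, function(s) s$name, "")
  box <- simulation_box(unlist(manifest$box))
  template <- solvation_system(
    st$atoms, st$xyz, species,
    lapply(species, function(sp)
      matrix(0, sp$n_molecules * sp$atoms_per_molecule, 3)),
    box)
  read_trajectory(file.path(dir, "trajectory.xyz"), template, "xyz", box)
}
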