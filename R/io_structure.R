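# PDB ATOM/HETATM line pre-validation: bio3d tolerates malformed records
# silently, so coordinate fields are checked up front and reported with
# their line number.
validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": truncated coordinate field")
    for (field in list(c(31, 38), c(39, 46), c(47, 54))) {
      txt <- substr(ln, field[1], field[2])
      if (is.na(suppressWarnings(as.numeric(txt))))
        stop("malformed PDB record at line ", i, ": bad coordinate '", txt, "'")
    }
  }
  invisible(TRUE)
}

#' Read a solute structure (PDB or GRO)
#'
#' Reads atoms and first-frame coordinates from a PDB file (parsed with
#' bio3d, after a validation pass that reports malformed ATOM records by
#' line number) or a GROMACS GRO file (fixed-width; coordinates are
#' converted from nm to Angstrom). Atom roles and polarity classes are
#' assigned from the residue/atom-name tables; 1-based residue numbering
#' in the file is preserved, so author numbering such as 120-152 survives.
#' Unknown residues are kept with polarity class `"n/a"` and a warning.
#'
#' @param path file path
#' @param format `"pdb"` or `"gro"`; inferred from the extension when
#'   missing
#' @param polarity_table override for [polarity_table()]
#' @return list with `atoms` (atom table), `xyz` (matrix, Angstrom) and
#'   `box` (a [simulation_box()] when the file carries one, else `NULL`)
#' @export
read_structure <- function(path, format = NULL,
                           polarity_table = solvkb::polarity_table()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("pdb", "gro"))
  if (format == "pdb") {
    validate_pdb_lines(readLines(path, warn = FALSE))
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    atoms <- atom_table(at$elety, at$resno, at$resid,
                        element = if (all(is.na(at$elesy)) || all(at$elesy == ""))
                          NULL else at$elesy,
                        polarity_table = polarity_table)
    xyz <- cbind(at$x, at$y, at$z)
    list(atoms = atoms, xyz = xyz, box = NULL)
  } else {
    read_gro(path, polarity_table)
  }
}

# GRO fixed format: title, atom count, then per atom
# resno(5) resname(5) atomname(5) atomno(5) x,y,z (%8.3f, nm); last line box (nm)
read_gro <- function(path, polarity_table = solvkb::polarity_table()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || length(lines) < n + 3)
    stop("malformed GRO file: bad atom count at line 2")
  al <- lines[3:(n + 2)]
  num <- function(s, a, b, what, off) {
    v <- suppressWarnings(as.numeric(substr(s, a, b)))
    if (anyNA(v))
      stop("malformed GRO record at line ", which(is.na(v))[1] + off,
           ": bad ", what)
    v
  }
  resno <- as.integer(num(al, 1, 5, "residue number", 2))
  resname <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  xyz <- 10 * cbind(num(al, 21, 28, "x coordinate", 2),
                    num(al, 29, 36, "y coordinate", 2),
                    num(al, 37, 44, "z coordinate", 2))
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  box <- if (length(boxv) >= 3 && !anyNA(boxv[1:3]) && all(boxv[1:3] > 0))
    simulation_box(10 * boxv[1:3]) else NULL
  atoms <- atom_table(aname, resno, resname, polarity_table = polarity_table)
  list(atoms = atoms, xyz = xyz, box = box)
}

#' Write a structure to PDB or GRO
#'
#' PDB output goes through [bio3d::write.pdb()]; GRO is written in the
#' fixed GROMACS format (Angstrom converted to nm, 3 decimals). Note the
#' formats' native precisions: 0.001 A for PDB, 0.001 nm = 0.01 A for GRO.
#'
#' @param atoms atom table (see [atom_table()])
#' @param xyz coordinates, `n x 3`, Angstrom
#' @param path output file
#' @param format `"pdb"` or `"gro"`; inferred from the extension when missing
#' @param box a [simulation_box()] (required for GRO; ignored for PDB)
#' @return `path`, invisibly
#' @export
write_structure <- function(atoms, xyz, path, format = NULL, box = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("pdb", "gro"))
  xyz <- rbind(xyz)
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     resno = atoms$residue_index, resid = atoms$residue_name,
                     elety = atoms$atom_name, eleno = seq_len(nrow(atoms)),
                     chain = "A")
  } else {
    if (is.null(box)) stop("GRO output requires a box")
    lines <- c("written by solvkb", sprintf("%5d", nrow(atoms)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$residue_index %% 100000L,
                       substr(atoms$residue_name, 1, 5),
                       substr(atoms$atom_name, 1, 5),
                       seq_len(nrow(atoms)) %% 100000L,
                       xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10),
               sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10))
    writeLines(lines, path)
  }
  invisible(path)
}
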