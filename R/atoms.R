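#' Default residue polarity classification table
#'
#' Maps three-letter residue codes to a polarity class used by selections
#' and MDDF decompositions. Charged: Asp, Glu, Lys, Arg and protonated His
#' (HIP/HSP); polar uncharged: Ser, Thr, Asn, Gln, Tyr, Cys and neutral His
#' (including HID/HIE/HSD/HSE tautomer names); nonpolar: the remaining
#' standard amino acids. The table is a plain named character vector and can
#' be amended or replaced wherever a `polarity_table` argument is accepted
#' (e.g. to treat His as charged).
#'
#' @return named character vector: residue code -> one of
#'   `"polar_charged"`, `"polar_uncharged"`, `"nonpolar"`
#' @export
polarity_table <- function() {
  c(
    ASP = "polar_charged", GLU = "polar_charged", LYS = "polar_charged",
    ARG = "polar_charged", HIP = "polar_charged", HSP = "polar_charged",
    SER = "polar_uncharged", THR = "polar_uncharged", ASN = "polar_uncharged",
    GLN = "polar_uncharged", TYR = "polar_uncharged", CYS = "polar_uncharged",
    HIS = "polar_uncharged", HID = "polar_uncharged", HIE = "polar_uncharged",
    HSD = "polar_uncharged", HSE = "polar_uncharged",
    ALA = "nonpolar", VAL = "nonpolar", LEU = "nonpolar", ILE = "nonpolar",
    PRO = "nonpolar", PHE = "nonpolar", MET = "nonpolar", TRP = "nonpolar",
    GLY = "nonpolar"
  )
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HN", "H1", "H2", "H3",
                     "HA", "HA2", "HA3")

#' Build an atom table
#'
#' Creates the per-atom attribute table used throughout the package:
#' one row per atom with its name, element, 1-based residue index, residue
#' name, structural role and polarity class. Role is `"solvent"` exactly for
#' atoms that belong to a solvent molecule; solute atoms are `"backbone"`
#' or `"sidechain"` by atom name. Polarity follows [polarity_table()];
#' residues absent from the table get class `"n/a"` with a warning.
#'
#' @param atom_name character vector of atom names
#' @param residue_index integer vector, 1-based residue numbers
#' @param residue_name character vector of residue codes
#' @param element character vector; derived from the first letter of
#'   `atom_name` when missing
#' @param solvent logical scalar or vector: do atoms belong to solvent?
#' @param polarity_table named vector overriding [polarity_table()]
#' @return data.frame with columns `atom_name`, `element`, `residue_index`,
#'   `residue_name`, `role`, `polarity_class`
#' @export
atom_table <- function(atom_name, residue_index, residue_name,
                       element = NULL, solvent = FALSE,
                       polarity_table = solvkb::polarity_table()) {
  n <- length(atom_name)
  if (is.null(element))
    element <- substr(gsub("[0-9]", "", atom_name), 1, 1)
  solvent <- rep_len(solvent, n)
  role <- ifelse(solvent, "solvent",
                 ifelse(atom_name %in% .BACKBONE_NAMES, "backbone", "sidechain"))
  pol <- unname(polarity_table[residue_name])
  unknown <- !solvent & is.na(pol)
  if (any(unknown)) {
    warning("unknown residue(s) ", paste(unique(residue_name[unknown]), collapse = ", "),
            ": polarity_class set to 'n/a'")
  }
  pol[is.na(pol)] <- "n/a"
  pol[solvent] <- "n/a"
  data.frame(
    atom_name = as.character(atom_name),
    element = as.character(element),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    role = role,
    polarity_class = pol,
    stringsAsFactors = FALSE
  )
}

#' Select atoms by attribute expression
#'
#' Evaluates a logical expression over the columns of an atom table
#' (`atom_name`, `element`, `residue_index`, `residue_name`, `role`,
#' `polarity_class`) and returns the sorted indices of matching atoms.
#' The expression may use any base-R logical syntax (`==`, `%in%`, `&`,
#' `|`, `!`), so complementary selections partition the atom set and
#' selections distribute over union/intersection by construction.
#'
#' @param atoms an atom table (see [atom_table()]) or a `solvation_system`
#'   (in which case its solute atoms are used)
#' @param expr selection expression, evaluated with the table's columns in
#'   scope, e.g. `role == "backbone"` or
#'   `residue_index %in% 120:130 & polarity_class != "nonpolar"`
#' @return sorted integer vector of atom indices
#' @examples
#' at <- atom_table(c("N","CA","C","O","CB"), rep(1L,5), rep("ALA",5))
#' select_group(at, role == "sidechain")
#' @export
select_group <- function(atoms, expr) {
  if (inherits(atoms, "solvation_system")) atoms <- atoms$solute_atoms
  e <- substitute(expr)
  vars <- all.vars(e)
  known <- names(atoms)
  bad <- setdiff(vars, known)
  if (length(bad))
    stop("selection references unknown field(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  keep <- eval(e, envir = atoms, enclos = parent.frame())
  if (!is.logical(keep) || length(keep) != nrow(atoms))
    stop("selection expression must evaluate to one logical per atom")
  sort(which(keep))
}

# non-NSE variant used internally when the expression is already quoted
select_group_ <- function(atoms, expr_quoted, env = parent.frame()) {
  if (inherits(atoms, "solvation_system")) atoms <- atoms$solute_atoms
  keep <- eval(expr_quoted, envir = atoms, enclos = env)
  sort(which(keep))
}
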