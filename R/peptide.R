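# Internal-coordinate chain building (natural extension reference frame):
# place atom D given three prior atoms A-B-C, the bond length |CD|, the
# angle B-C-D (degrees) and the dihedral A-B-C-D (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m2 + d2[3] * n
}

# Ideal backbone geometry (Engh-Huber-like averages), Angstrom / degrees
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_n_h = 1.01,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5
)

#' Build an ideal polyalanine backbone
#'
#' Constructs an N/H/CA/C/O backbone (alanine residues; no side chains
#' beyond CB-free glycine-like geometry) at ideal bond lengths and angles,
#' with dihedrals set either to the canonical alpha-helix
#' (phi = -57, psi = -47 degrees) or to a fully extended chain
#' (phi = psi = 180). The amide hydrogen of residue 1 is omitted (it has no
#' preceding carbonyl to orient it); hydrogens of residues 2..n are placed
#' 1.01 A from N along the in-plane direction opposite the bisector of the
#' C(i-1)-N-CA angle. Used as the fixture for helix-assignment tests: the
#' helical form has O(i)...H(i+4) contacts near 2 A, the extended form none.
#'
#' @param n_residues chain length; at least 5 (shorter chains cannot form
#'   an i -> i+4 hydrogen bond)
#' @param conformation `"alpha_helix"` or `"extended"`
#' @return list with `atoms` (atom table) and `xyz` (matrix, Angstrom)
#' @export
gen_toy_peptide <- function(n_residues,
                            conformation = c("alpha_helix", "extended")) {
  conformation <- match.arg(conformation)
  n_residues <- as.integer(n_residues)
  if (n_residues < 5)
    stop("n_residues must be >= 5: shorter chains admit no i->i+4 hydrogen bond")
  if (conformation == "alpha_helix") { phi <- -57; psi <- -47 } else { phi <- 180; psi <- 180 }
  g <- .BB
  # seed residue 1: N at origin, CA on x, C in the xy-plane
  N <- matrix(0, n_residues, 3); CA <- N; C <- N; O <- N
  H <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_residues)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, 180)     # omega trans
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi)
      H[i, ] <- amide_h_position(C[i - 1, ], N[i, ], CA[i, ])
    }
    # carbonyl O anti to the next amide N across the C(i) sp2 center
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi + 180)
  }
  names <- character(0); res <- integer(0); xyz <- NULL
  for (i in seq_len(n_residues)) {
    block_names <- c("N", if (i > 1) "H", "CA", "C", "O")
    block <- rbind(N[i, ], if (i > 1) H[i, ], CA[i, ], C[i, ], O[i, ])
    names <- c(names, block_names)
    res <- c(res, rep(i, length(block_names)))
    xyz <- rbind(xyz, block)
  }
  atoms <- atom_table(names, res, rep("ALA", length(names)))
  rownames(xyz) <- NULL
  list(atoms = atoms, xyz = xyz)
}

# Amide hydrogen from local geometry: 1.01 A from N, in the C(prev)-N-CA
# plane, along the direction opposite the bisector of that angle.
amide_h_position <- function(c_prev, n, ca) {
  u <- c_prev - n; u <- u / sqrt(sum(u^2))
  v <- ca - n; v <- v / sqrt(sum(v^2))
  d <- -(u + v)
  d <- d / sqrt(sum(d^2))
  n + .BB$b_n_h * d
}
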