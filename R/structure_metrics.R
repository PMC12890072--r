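# Backbone atom lookup per residue for one frame: returns a list of
# matrices (rows = residues) for N, H, CA, C, O; NA rows where missing.
backbone_coords <- function(atoms, xyz) {
  res_levels <- sort(unique(atoms$residue_index))
  pick <- function(name) {
    m <- matrix(NA_real_, length(res_levels), 3)
    sel <- atoms$atom_name == name
    ri <- match(atoms$residue_index[sel], res_levels)
    m[ri, ] <- xyz[sel, , drop = FALSE]
    m
  }
  H <- pick("H")
  hn <- pick("HN")
  H[is.na(H[, 1]), ] <- hn[is.na(H[, 1]), ]
  list(res = res_levels, N = pick("N"), H = H, CA = pick("CA"),
       C = pick("C"), O = pick("O"))
}

# Kabsch-Sander electrostatic H-bond energy (kcal/mol) between the CO of
# residue i (acceptor) and the NH of residue j (donor):
# E = q1 q2 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * f with q1 q2 f = 27.888.
ks_energy <- function(C_i, O_i, N_j, H_j) {
  r <- function(a, b) sqrt(sum((a - b)^2))
  27.888 * (1 / r(O_i, N_j) + 1 / r(C_i, H_j) - 1 / r(O_i, H_j) - 1 / r(C_i, N_j))
}

#' Alpha-helix assignment for one frame
#'
#' Reimplements the alpha-helix class of the DSSP hierarchy: a backbone
#' hydrogen bond CO(i)...HN(i+4) exists when the Kabsch-Sander
#' electrostatic energy is below -0.5 kcal/mol; such a bond defines a
#' 4-turn at i; and a residue is assigned alpha-helical when it is the
#' pivot of two consecutive turns, i.e. residue j is helical iff turns at
#' j-1 and j are both bonded. This strict "minimal H" rule marks the
#' helical core (residues 2..n-4 of an ideal helix) and leaves single-turn
#' tails unassigned; 3-10/pi helices and strands are reported as not alpha.
#' Missing amide hydrogens are reconstructed from local geometry
#' (see [gen_toy_peptide()]); residues missing other backbone atoms are
#' returned as `NA` (unassignable).
#'
#' @param atoms solute atom table (see [atom_table()])
#' @param xyz solute coordinates for one frame, matrix `n x 3` (Angstrom)
#' @return logical vector over residues (sorted residue index order):
#'   `TRUE` alpha-helical, `FALSE` not, `NA` unassignable
#' @export
assign_helix <- function(atoms, xyz) {
  bb <- backbone_coords(atoms, xyz)
  n <- length(bb$res)
  # reconstruct missing amide H where the previous C is available
  if (n >= 2) for (j in 2:n) {
    if (is.na(bb$H[j, 1]) && !anyNA(bb$C[j - 1, ]) &&
        !anyNA(bb$N[j, ]) && !anyNA(bb$CA[j, ]))
      bb$H[j, ] <- amide_h_position(bb$C[j - 1, ], bb$N[j, ], bb$CA[j, ])
  }
  assignable <- !is.na(bb$N[, 1]) & !is.na(bb$CA[, 1]) &
    !is.na(bb$C[, 1]) & !is.na(bb$O[, 1])
  turn <- rep(FALSE, n)   # turn[i]: CO(i)...HN(i+4) bonded
  if (n >= 5) {
    for (i in seq_len(n - 4)) {
      j <- i + 4
      if (assignable[i] && !anyNA(bb$N[j, ]) && !anyNA(bb$H[j, ]))
        turn[i] <- ks_energy(bb$C[i, ], bb$O[i, ], bb$N[j, ], bb$H[j, ]) < -0.5
    }
  }
  helix <- rep(FALSE, n)
  if (n >= 2) for (j in 2:n) if (turn[j - 1] && turn[j]) helix[j] <- TRUE
  helix[!assignable] <- NA
  helix
}

#' Helix content of an ensemble
#'
#' Applies [assign_helix()] to every frame of a system's solute and
#' aggregates: the frames x residues boolean assignment matrix, the
#' per-residue helix fraction across frames, and the per-frame helix
#' fraction across assignable residues. The mean per-frame fraction equals
#' the mean per-residue fraction (both average the same matrix) whenever
#' all residues are assignable.
#'
#' @param system a [solvation_system()] (only the solute is used)
#' @return object of class `helix_profile`: list with `assignment`
#'   (frames x residues), `per_residue_fraction`, `per_frame_fraction`,
#'   `residues`, `n_frames`
#' @export
helix_content <- function(system) {
  nf <- system$n_frames
  res <- sort(unique(system$solute_atoms$residue_index))
  A <- matrix(NA, nf, length(res), dimnames = list(NULL, res))
  for (f in seq_len(nf))
    A[f, ] <- assign_helix(system$solute_atoms, frame_solute(system, f))
  structure(list(
    assignment = A,
    per_residue_fraction = colMeans(A, na.rm = TRUE),
    per_frame_fraction = rowMeans(A, na.rm = TRUE),
    residues = res, n_frames = nf
  ), class = "helix_profile")
}

#' @export
print.helix_profile <- function(x, ...) {
  cat(sprintf("Helix profile: %d frames x %d residues\n", x$n_frames,
              length(x$residues)))
  cat(sprintf("  mean helix fraction: %.3f (per-frame SD %.3f)\n",
              mean(x$per_frame_fraction), stats::sd(x$per_frame_fraction)))
  hel <- x$residues[x$per_residue_fraction > 0.5 & !is.na(x$per_residue_fraction)]
  if (length(hel))
    cat("  mostly-helical residues:", paste(hel, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.helix_profile <- function(x, ...) {
  graphics::plot(x$residues, x$per_residue_fraction, type = "h", lwd = 3,
                 ylim = c(0, 1), xlab = "residue", ylab = "helix fraction", ...)
  invisible(x)
}

#' Geometric hydrogen-bond criterion
#'
#' @param max_da donor-acceptor maximum distance, Angstrom (default 3.5)
#' @param min_angle minimum donor-hydrogen-acceptor angle, degrees
#'   (default 150; 180 is linear)
#' @return object of class `hbond_criterion`
#' @export
hbond_criterion <- function(max_da = 3.5, min_angle = 150) {
  if (max_da <= 0) stop("max_da must be > 0")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_da = max_da, min_angle = min_angle),
            class = "hbond_criterion")
}

#' Count geometric hydrogen bonds per frame
#'
#' Applies a distance/angle criterion with minimum-image distances: a bond
#' is counted when the donor-acceptor distance is at most `max_da` and the
#' donor-hydrogen...acceptor angle is at least `min_angle` degrees. Donors
#' are given as (donor heavy atom, attached hydrogen) index pairs into the
#' solute; acceptors as solute atom indices. Returns the integer per-frame
#' time series with mean and block-averaged standard error.
#'
#' @param system a [solvation_system()]
#' @param donors two-column matrix (or data.frame) of solute atom indices:
#'   column 1 the donor heavy atom, column 2 its hydrogen
#' @param acceptors integer vector of solute acceptor atom indices
#' @param criterion an [hbond_criterion()]
#' @return object of class `hbond_series`: list with `counts` (per frame),
#'   `mean`, `se` (block-averaged when the series is long enough, else
#'   naive), `criterion`
#' @export
count_hbonds <- function(system, donors, acceptors,
                         criterion = hbond_criterion()) {
  donors <- rbind(as.matrix(donors))
  if (ncol(donors) != 2) stop("donors must be (heavy atom, hydrogen) index pairs")
  if (length(acceptors) < 1) stop("no acceptors selected")
  h_names <- system$solute_atoms$atom_name[donors[, 2]]
  if (any(!grepl("^H", h_names)))
    warning("some donor hydrogens do not look like hydrogens: ",
            paste(unique(h_names[!grepl("^H", h_names)]), collapse = ", "))
  cosmin <- cos(criterion$min_angle * pi / 180)
  nf <- system$n_frames
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_solute(system, f)
    box <- frame_box(system, f)
    Dda <- min_image_dist(xyz[donors[, 1], , drop = FALSE],
                          xyz[acceptors, , drop = FALSE], box)
    cnt <- 0L
    for (di in seq_len(nrow(donors))) {
      cand <- which(Dda[di, ] <= criterion$max_da)
      cand <- cand[acceptors[cand] != donors[di, 1] & acceptors[cand] != donors[di, 2]]
      if (!length(cand)) next
      d_at <- xyz[donors[di, 1], ]; h_at <- xyz[donors[di, 2], ]
      for (ai in cand) {
        a_at <- xyz[acceptors[ai], ]
        v1 <- mi_vec(d_at - h_at, box)
        v2 <- mi_vec(a_at - h_at, box)
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        # angle >= min_angle <=> cos(angle) <= cos(min_angle)
        if (cosang <= cosmin) cnt <- cnt + 1L
      }
    }
    counts[f] <- cnt
  }
  se <- if (nf >= 16) block_average(counts)$plateau_se
        else stats::sd(counts) / sqrt(nf)
  structure(list(counts = counts, mean = mean(counts), se = se,
                 criterion = criterion), class = "hbond_series")
}

# minimum-image reduction of a single displacement vector
mi_vec <- function(v, box) {
  box <- as.numeric(box)
  v - round(v / box) * box
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("Hydrogen bonds: mean %.3f +/- %.3f per frame (%d frames; D-A <= %.2f A, angle >= %g deg)\n",
              x$mean, x$se, length(x$counts), x$criterion$max_da,
              x$criterion$min_angle))
  invisible(x)
}
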