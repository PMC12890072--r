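# Per-frame minimum-distance engine. For one frame, returns for every
# solvent molecule of the species its minimum-image minimum distance to the
# solute selection together with the realizing (solute atom, solvent atom)
# pair. Ties are broken lexicographically: lowest solute atom index first,
# then lowest solvent atom index (scan order of the flattened matrix).
min_dist_frame <- function(solute_xyz, solvent_xyz, m, box) {
  D <- min_image_dist(solute_xyz, solvent_xyz, box)   # S x (n*m)
  s <- nrow(D)
  n <- ncol(D) / m
  # reshape to (m*s) x n with solute index varying slowest within a column:
  # column entries ordered (solute 1: atoms 1..m)? -> want (solute, atom) lexicographic
  dim(D) <- c(s, m, n)
  D <- aperm(D, c(2, 1, 3))        # m x s x n: atom fastest, solute slower
  dim(D) <- c(m * s, n)
  k <- max.col(-t(D), ties.method = "first")   # first minimum per molecule
  dmin <- D[cbind(k, seq_len(n))]
  solute_atom <- (k - 1L) %/% m + 1L
  solvent_atom <- (k - 1L) %% m + 1L
  list(dmin = dmin, solute_atom = solute_atom, solvent_atom = solvent_atom)
}

#' Per-molecule minimum distances in one frame
#'
#' For each molecule of a solvent species, the minimum over all pairs of
#' (selected solute atom, solvent atom) of the minimum-image distance, with
#' the realizing atom pair recorded (used downstream for decompositions).
#' Ties are broken deterministically by lowest solute atom index, then
#' lowest solvent atom index.
#'
#' @param system a [solvation_system()]
#' @param species species name or index
#' @param frame frame index (default 1)
#' @param solute_selection integer indices of solute atoms to consider
#'   (default: all); see [select_group()]
#' @return data.frame with one row per molecule: `molecule`, `dmin`,
#'   `solute_atom` (index into the full solute atom table) and
#'   `solvent_atom` (index within the molecule)
#' @export
min_distances <- function(system, species = 1, frame = 1,
                          solute_selection = NULL) {
  nm <- resolve_species(system, species)
  sp <- system$species[[nm]]
  if (sp$n_molecules < 1) stop("species '", nm, "' has no molecules")
  if (is.null(solute_selection))
    solute_selection <- seq_len(nrow(system$solute_atoms))
  if (length(solute_selection) == 0) stop("empty solute selection")
  su <- rbind(frame_solute(system, frame))[solute_selection, , drop = FALSE]
  sv <- frame_solvent(system, nm, frame)
  r <- min_dist_frame(su, sv, sp$atoms_per_molecule, frame_box(system, frame))
  data.frame(molecule = seq_len(sp$n_molecules),
             dmin = r$dmin,
             solute_atom = solute_selection[r$solute_atom],
             solvent_atom = r$solvent_atom)
}

# histogram of distances into bins [0, r_max) of width bw; values >= r_max drop
bin_counts <- function(d, bw, r_max) {
  n_bins <- as.integer(round(r_max / bw))
  idx <- floor(d / bw) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  tabulate(idx, nbins = n_bins)
}

#' Ideal-gas reference counts for one frame
#'
#' Re-inserts `nu * n_molecules` rigid copies of the species at uniform
#' random positions and orientations in the frame's box (internal geometries
#' resampled from the molecules observed in the frame), computes their
#' minimum distances to the solute selection, and returns per-bin counts
#' scaled by `1/nu`. This realizes the ideal-gas distribution: the same
#' molecules, but with solute-solvent interactions switched off.
#'
#' @inheritParams min_distances
#' @param config an [analysis_config()]
#' @param seed seed for the insertions (default derived from `config$seed`
#'   and the frame index)
#' @return numeric vector of per-bin reference counts (already divided by
#'   `nu`), bins `[0, r_max)` of width `config$bin_width`
#' @export
reference_counts <- function(system, species = 1, frame = 1, config = analysis_config(),
                             solute_selection = NULL, seed = NULL) {
  nm <- resolve_species(system, species)
  sp <- system$species[[nm]]
  if (is.null(solute_selection))
    solute_selection <- seq_len(nrow(system$solute_atoms))
  su <- rbind(frame_solute(system, frame))[solute_selection, , drop = FALSE]
  box <- frame_box(system, frame)
  if (is.null(seed)) seed <- (config$seed * 1009L + frame) %% 2147483647L
  d <- reference_distances(su, frame_solvent(system, nm, frame),
                           sp$atoms_per_molecule, sp$n_molecules,
                           box, config$nu, seed)
  bin_counts(d, config$bin_width, config$r_max) / config$nu
}

# raw reference minimum distances (nu * n_mol values)
reference_distances <- function(solute_xyz, solvent_xyz, m, n_mol, box, nu, seed) {
  with_seed(seed, {
    n_ins <- nu * n_mol
    if (m == 1) {
      cand <- place_rigid(matrix(0, 1, 3), n_ins, box)
    } else {
      # resample observed internal geometries (centered) with replacement
      pick <- sample.int(n_mol, n_ins, replace = TRUE)
      centers <- cbind(stats::runif(n_ins, 0, box[1]),
                       stats::runif(n_ins, 0, box[2]),
                       stats::runif(n_ins, 0, box[3]))
      R <- random_rotations(n_ins)
      cand <- matrix(0, n_ins * m, 3)
      for (i in seq_len(n_ins)) {
        rows <- ((pick[i] - 1) * m + 1):(pick[i] * m)
        tpl <- solvent_xyz[rows, , drop = FALSE]
        tpl <- tpl - matrix(colMeans(tpl), m, 3, byrow = TRUE)
        dst <- ((i - 1) * m + 1):(i * m)
        cand[dst, ] <- tpl %*% t(R[, , i]) + matrix(centers[i, ], m, 3, byrow = TRUE)
      }
    }
    mol_min_dist(cand, m, solute_xyz, box)
  })
}

#' Minimum-distance distribution function
#'
#' Accumulates observed and ideal-gas reference minimum-distance histograms
#' over all frames and forms their ratio g(r) = n(r) / n*(r) per bin. Bins
#' where the reference count is zero are flagged undefined (`NA`), not
#' reported as 0. The per-molecule minimum-distance events (with realizing
#' atom pairs) are retained in the result for decomposition, residue maps
#' and Kirkwood-Buff integration.
#'
#' @param system a [solvation_system()]
#' @param species species name or index
#' @param config an [analysis_config()]
#' @param solute_selection solute atom indices (default all)
#' @return object of class `mddf`: list with `r` (bin centers), `bin_edges`,
#'   `n_obs`/`n_ref` (mean counts per frame per bin), `g`, `undefined`
#'   (logical), per-frame count matrices `obs_mat`/`ref_mat`
#'   (bins x frames), the event table `events`, `n_frames`, `species`,
#'   and the `config` used
#' @export
compute_mddf <- function(system, species = 1, config = analysis_config(),
                         solute_selection = NULL) {
  nm <- resolve_species(system, species)
  sp <- system$species[[nm]]
  if (sp$n_molecules < 1) stop("species '", nm, "' has no molecules")
  if (is.null(solute_selection))
    solute_selection <- seq_len(nrow(system$solute_atoms))
  if (length(solute_selection) == 0) stop("empty solute selection")
  bw <- config$bin_width
  n_bins <- as.integer(round(config$r_max / bw))
  nf <- system$n_frames
  obs_mat <- matrix(0, n_bins, nf)
  ref_mat <- matrix(0, n_bins, nf)
  ev <- vector("list", nf)
  for (f in seq_len(nf)) {
    md <- min_distances(system, nm, f, solute_selection)
    obs_mat[, f] <- bin_counts(md$dmin, bw, config$r_max)
    ref_mat[, f] <- reference_counts(system, nm, f, config, solute_selection)
    keep <- md$dmin < config$r_max
    ev[[f]] <- cbind(frame = f, molecule = md$molecule[keep],
                     dmin = md$dmin[keep], solute_atom = md$solute_atom[keep],
                     solvent_atom = md$solvent_atom[keep])
  }
  events <- as.data.frame(do.call(rbind, ev))
  n_obs <- rowMeans(obs_mat)
  n_ref <- rowMeans(ref_mat)
  undefined <- n_ref == 0
  g <- ifelse(undefined, NA_real_, n_obs / n_ref)
  structure(list(
    r = (seq_len(n_bins) - 0.5) * bw,
    bin_edges = seq(0, by = bw, length.out = n_bins + 1),
    n_obs = n_obs, n_ref = n_ref, g = g, undefined = undefined,
    obs_mat = obs_mat, ref_mat = ref_mat, events = events,
    n_frames = nf, species = nm, solute_selection = solute_selection,
    config = config
  ), class = "mddf")
}

#' @export
print.mddf <- function(x, ...) {
  cat(sprintf("MDDF: species '%s', %d frames, %d bins of %.3g A (r_max %.3g A)\n",
              x$species, x$n_frames, length(x$r), x$config$bin_width, x$config$r_max))
  def <- !x$undefined & x$n_obs > 0
  if (any(def)) {
    pk <- which.max(ifelse(def, x$g, -Inf))
    cat(sprintf("  peak g = %.3f at r = %.2f A; mean count/frame within r_max: %.2f\n",
                x$g[pk], x$r[pk], sum(x$n_obs)))
  }
  invisible(x)
}

#' @export
plot.mddf <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "minimum distance r (A)",
                 ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.mddf <- function(x, ...) {
  data.frame(r_center = x$r, n_obs = x$n_obs, n_ref = x$n_ref, g = x$g,
             flag = ifelse(x$undefined, "undefined", "ok"))
}
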