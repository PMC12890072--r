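#' Orthorhombic simulation box
#'
#' Constructs a periodic orthorhombic box from its edge lengths. All
#' distance computations in the package use the minimum-image convention
#' inside such a box; triclinic cells are not supported.
#'
#' @param lengths numeric vector of 3 positive edge lengths, Angstrom. A
#'   single value is recycled to a cubic box.
#' @return an object of class `simulation_box` (numeric length-3 vector)
#' @examples
#' simulation_box(84)          # cubic, 84 A
#' simulation_box(c(40, 50, 60))
#' @export
simulation_box <- function(lengths) {
  if (length(lengths) == 1) lengths <- rep(lengths, 3)
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3 || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("box lengths must be 3 finite positive numbers (Angstrom)")
  structure(lengths, class = "simulation_box")
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("Orthorhombic box: %.3f x %.3f x %.3f A (V = %.1f A^3)\n",
              x[1], x[2], x[3], prod(x)))
  invisible(x)
}

box_volume <- function(box) prod(as.numeric(box))

# Wrap coordinates into [0, L) per dimension. `xyz` is an n x 3 matrix.
wrap_coords <- function(xyz, box) {
  box <- as.numeric(box)
  for (k in 1:3) xyz[, k] <- xyz[, k] - floor(xyz[, k] / box[k]) * box[k]
  xyz
}

# Minimum-image distance matrix between two coordinate sets in an
# orthorhombic box: a (n x 3), b (m x 3) -> n x m matrix of distances.
# The per-component reduction min(|dx|, L - |dx|) equals the true minimum
# over all periodic images because the box is orthorhombic (separable).
min_image_dist <- function(a, b, box) {
  a <- wrap_coords(rbind(a), box)
  b <- wrap_coords(rbind(b), box)
  box <- as.numeric(box)
  d2 <- 0
  for (k in 1:3) {
    dk <- abs(outer(a[, k], b[, k], "-"))
    dk <- pmin(dk, box[k] - dk)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Minimum-image displacement-aware distance between paired rows of a and b
# (vectors of the same length n) -> length-n vector.
min_image_dist_pairs <- function(a, b, box) {
  box <- as.numeric(box)
  d <- abs(wrap_coords(rbind(a), box) - wrap_coords(rbind(b), box))
  for (k in 1:3) d[, k] <- pmin(d[, k], box[k] - d[, k])
  sqrt(rowSums(d * d))
}
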