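#' REST2 replica scaling ladder
#'
#' Builds the ladder of scaling factors lambda_m = beta_m / beta_0 used by
#' replica exchange with solute tempering: lambda_0 = 1 (the physical,
#' unscaled replica) down to `lambda_min` for the most softened replica.
#' All replicas run at the same physical temperature; lambda only rescales
#' the solute-related energy terms. Geometric spacing (constant ratio) is
#' the default, the standard choice for near-uniform exchange acceptance;
#' linear spacing is available for comparison. Endpoints are exact.
#'
#' @param M number of replicas, at least 2
#' @param lambda_min final scaling factor, in (0, 1)
#' @param spacing `"geometric"` or `"linear"`
#' @param T0 base (physical) temperature, K
#' @return object of class `replica_ladder`: list with `lambda` (length M,
#'   descending from 1), `M`, `T0`, `spacing`
#' @examples
#' build_ladder(10, 0.71)   # 10 replicas, lambda from 1 to 0.71
#' @export
build_ladder <- function(M, lambda_min, spacing = c("geometric", "linear"),
                         T0 = 300) {
  spacing <- match.arg(spacing)
  M <- as.integer(M)
  if (M < 2) stop("need at least 2 replicas")
  if (!(lambda_min > 0 && lambda_min < 1))
    stop("lambda_min must lie strictly between 0 and 1")
  lambda <- switch(spacing,
    geometric = lambda_min^(seq(0, M - 1) / (M - 1)),
    linear = seq(1, lambda_min, length.out = M)
  )
  lambda[1] <- 1; lambda[M] <- lambda_min   # exact endpoints
  structure(list(lambda = lambda, M = M, T0 = T0, spacing = spacing),
            class = "replica_ladder")
}

#' @export
print.replica_ladder <- function(x, ...) {
  cat(sprintf("REST2 ladder: %d replicas at T0 = %g K, %s spacing\n",
              x$M, x$T0, x$spacing))
  cat("  lambda:", paste(sprintf("%.5f", x$lambda), collapse = " "), "\n")
  invisible(x)
}

#' Energy components of a configuration
#'
#' @param E_pp intra-solute energy, kJ/mol
#' @param E_ps solute-solvent energy, kJ/mol
#' @param E_ss solvent-solvent energy, kJ/mol (never rescaled)
#' @return object of class `energy_components`
#' @export
energy_components <- function(E_pp, E_ps, E_ss) {
  v <- c(E_pp = E_pp, E_ps = E_ps, E_ss = E_ss)
  if (any(!is.finite(v))) stop("energy components must be finite")
  structure(as.list(v), class = "energy_components")
}

#' REST2-scaled potential energy
#'
#' E(lambda) = lambda * E_pp + sqrt(lambda) * E_ps + E_ss: the intra-solute
#' term is scaled by lambda = beta_m/beta_0 and the solute-solvent term by
#' sqrt(lambda), while the solvent-solvent term is untouched. (A common
#' compact way of printing the REST2 Hamiltonian shows both solute terms
#' with the same factor; the sqrt on the cross term is the defining choice
#' of REST2 and is what this function implements.)
#'
#' @param components an [energy_components()] (or list with `E_pp`, `E_ps`,
#'   `E_ss`, kJ/mol)
#' @param lambda scaling factor in (0, 1]
#' @return scaled energy, kJ/mol
#' @examples
#' scaled_energy(energy_components(100, 50, 200), 0.49)  # 284
#' @export
scaled_energy <- function(components, lambda) {
  if (!(lambda > 0 && lambda <= 1)) stop("lambda must lie in (0, 1]")
  lambda * components$E_pp + sqrt(lambda) * components$E_ps + components$E_ss
}

#' Metropolis swap-acceptance probability between two replicas
#'
#' For configurations i and j currently at scaling factors lambda_i and
#' lambda_j, the exchange is accepted with probability min(1, exp(-Delta))
#' where Delta = beta_0 [E_i(lambda_j) + E_j(lambda_i) - E_i(lambda_i) -
#' E_j(lambda_j)] and beta_0 = 1/(kB T0). Delta is antisymmetric under
#' swapping the replica labels, so the probability is symmetric.
#'
#' @param components_i,components_j [energy_components()] of the two
#'   configurations, kJ/mol
#' @param lambda_i,lambda_j their current scaling factors, in (0, 1]
#' @param T0 base temperature, K (> 0)
#' @return acceptance probability in `[0, 1]`
#' @export
swap_acceptance <- function(components_i, components_j, lambda_i, lambda_j,
                            T0 = 300) {
  if (T0 <= 0) stop("T0 must be > 0")
  beta0 <- 1 / (.KB_KJ * T0)
  delta <- beta0 * (scaled_energy(components_i, lambda_j) +
                    scaled_energy(components_j, lambda_i) -
                    scaled_energy(components_i, lambda_i) -
                    scaled_energy(components_j, lambda_j))
  min(1, exp(-delta))
}
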