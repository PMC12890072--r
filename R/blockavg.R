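#' Block-averaging error analysis for a correlated series
#'
#' Estimates the standard error of the mean of a (possibly autocorrelated)
#' time series by averaging over progressively larger non-overlapping
#' blocks: for each dyadic block size b, the series is cut into
#' floor(n/b) blocks and the SE of the block means is computed. For
#' correlated data the SE estimate grows with b until blocks are longer
#' than the correlation time, then plateaus at the true SE of the mean.
#' The plateau is detected as the smallest block size from which all
#' larger-block estimates stay within 10% (relative), and the reported
#' plateau SE averages the estimates from there up (which damps the noise
#' of the few-block estimates). Block sizes leaving fewer than 16 blocks
#' are not used. The statistical inefficiency (plateau SE / naive SE)^2,
#' i.e. the effective number of correlated samples per independent one,
#' doubles as an integrated-autocorrelation estimate: tau_int = (g - 1)/2.
#'
#' @param series numeric vector, length at least 16
#' @return object of class `block_average`: list with `block_sizes`, `se`
#'   (per block size), `plateau_block`, `plateau_se`, `naive_se`
#'   (= sd/sqrt(n)), `stat_ineff`, `tau_int`, `mean`, `n`
#' @examples
#' x <- stats::rnorm(4096)
#' block_average(x)$plateau_se   # ~ 1/sqrt(4096)
#' @export
block_average <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 16) stop("series must have at least 16 points")
  bmax <- 2^floor(log2(n / 16))
  sizes <- 2^(0:log2(bmax))
  se <- vapply(sizes, function(b) {
    nb <- floor(n / b)
    bm <- colMeans(matrix(series[seq_len(nb * b)], b, nb))
    stats::sd(bm) / sqrt(nb)
  }, 0)
  naive <- stats::sd(series) / sqrt(n)
  if (naive == 0) {
    plateau_block <- 1
    plateau_se <- 0
  } else {
    k <- length(sizes)
    plateau_idx <- k
    for (i in seq_len(k)) {
      if (all(abs(se[i:k] - se[i]) <= 0.10 * se[i])) { plateau_idx <- i; break }
    }
    plateau_block <- sizes[plateau_idx]
    plateau_se <- mean(se[plateau_idx:length(se)])
  }
  g <- if (naive > 0) (plateau_se / naive)^2 else 1
  structure(list(block_sizes = sizes, se = se, plateau_block = plateau_block,
                 plateau_se = plateau_se, naive_se = naive,
                 stat_ineff = g, tau_int = max((g - 1) / 2, 0),
                 mean = mean(series), n = n),
            class = "block_average")
}

#' @export
print.block_average <- function(x, ...) {
  cat(sprintf("Block averaging: n = %d, mean = %.5g\n", x$n, x$mean))
  cat(sprintf("  naive SE   : %.4g\n", x$naive_se))
  cat(sprintf("  plateau SE : %.4g (from block size %d)\n", x$plateau_se,
              x$plateau_block))
  cat(sprintf("  statistical inefficiency %.2f (tau_int ~ %.2f steps)\n",
              x$stat_ineff, x$tau_int))
  invisible(x)
}

#' @export
plot.block_average <- function(x, ...) {
  graphics::plot(x$block_sizes, x$se, log = "x", type = "b",
                 xlab = "block size", ylab = "SE estimate", ...)
  graphics::abline(h = x$plateau_se, lty = 3)
  invisible(x)
}

#' Normalized autocorrelation function
#'
#' Biased (divide-by-n) estimator of the normalized autocorrelation of a
#' series, as used to judge sampling correlation of helix-content series;
#' ACF(0) = 1 by construction. Thin wrapper over [stats::acf()].
#'
#' @param series numeric vector
#' @param max_lag largest lag; must be below `length(series)/2`
#' @return numeric vector of length `max_lag + 1` (lags 0..max_lag)
#' @export
autocorrelation <- function(series, max_lag) {
  n <- length(series)
  if (max_lag >= n / 2) stop("max_lag must be < length(series)/2")
  as.numeric(stats::acf(series, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
}
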