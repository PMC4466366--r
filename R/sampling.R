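## Turning differential cross-sections into energy-loss samplers, free
## paths and channel choices for the transport loop.  All randomness goes
## through R's RNG so that a set.seed() call (or a per-history seed from
## history_seed()) makes every draw reproducible.

#' Build an inverse-CDF energy-loss sampler from a differential cross-section
#'
#' Tabulates the DCS on a log-spaced grid over the secondary-energy support,
#' accumulates the trapezoid CDF and stores the normalised inverse for
#' linear-interpolation sampling.  A channel whose total cross-section is
#' zero yields a flagged empty sampler; drawing from it is an error.
#'
#' @param dcs Vectorised function of `W` (eV) returning m\eqn{^2}/eV,
#'   non-negative.
#' @param support Length-2 numeric, the W interval (eV).
#' @param grid_points Number of grid points (default 512).
#' @param T_eV Primary energy the sampler belongs to (metadata).
#' @param channel Channel identifier (metadata).
#' @return An object of class `energy_loss_sampler` with fields `W`, `cdf`,
#'   `sigma_tot` (m\eqn{^2}), `empty`.
#' @export
build_sampler <- function(dcs, support, grid_points = 512L, T_eV = NA_real_,
                          channel = NA_character_) {
  lo <- support[1L]
  hi <- support[2L]
  if (!is.finite(hi) || hi <= lo) {
    return(structure(list(W = numeric(), cdf = numeric(), sigma_tot = 0,
                          T_eV = T_eV, channel = channel, empty = TRUE),
                     class = "energy_loss_sampler"))
  }
  lo_eff <- if (lo <= 0) hi * 1e-9 else lo
  W <- exp(seq(log(lo_eff), log(hi), length.out = grid_points))
  # pin the endpoints: exp(log(x)) can overshoot x by an ulp, which would
  # push boundary evaluations outside a hard-edged support
  W[1L] <- lo_eff
  W[grid_points] <- hi
  f <- dcs(W)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("dcs must be finite and non-negative on its support",
         call. = FALSE)
  }
  dw <- diff(W)
  incr <- dw * (f[-1L] + f[-length(f)]) / 2
  cdf <- c(0, cumsum(incr))
  sigma <- cdf[length(cdf)]
  if (!is.finite(sigma) || sigma <= 0) {
    return(structure(list(W = W, cdf = cdf, sigma_tot = 0, T_eV = T_eV,
                          channel = channel, empty = TRUE),
                     class = "energy_loss_sampler"))
  }
  structure(list(W = W, cdf = cdf / sigma, sigma_tot = sigma, T_eV = T_eV,
                 channel = channel, empty = FALSE),
            class = "energy_loss_sampler")
}

## Strictly increasing subset of the CDF for interpolation.
sampler_nodes <- function(sampler) {
  keep <- c(TRUE, diff(sampler$cdf) > 0)
  list(cdf = sampler$cdf[keep], W = sampler$W[keep])
}

#' Quantile function of an energy-loss sampler
#'
#' @param sampler An `energy_loss_sampler`.
#' @param u Probabilities in \eqn{[0, 1]}.
#' @return Energy losses W (eV).
#' @export
sampler_quantile <- function(sampler, u) {
  if (sampler$empty) {
    stop("cannot sample from an empty (zero cross-section) sampler",
         call. = FALSE)
  }
  nd <- sampler_nodes(sampler)
  stats::approx(nd$cdf, nd$W, xout = u, rule = 2, ties = "ordered")$y
}

#' Cumulative distribution of an energy-loss sampler
#'
#' @param sampler An `energy_loss_sampler`.
#' @param W Energies (eV).
#' @return CDF values in \eqn{[0, 1]}.
#' @export
sampler_cdf <- function(sampler, W) {
  stats::approx(sampler$W, sampler$cdf, xout = W, rule = 2,
                ties = "ordered")$y
}

#' Draw secondary energies from an energy-loss sampler
#'
#' @param sampler An `energy_loss_sampler`.
#' @param n Number of draws.
#' @return `n` energy losses (eV), drawn through R's RNG.
#' @export
sample_energy_loss <- function(sampler, n) {
  sampler_quantile(sampler, stats::runif(n))
}

#' @export
print.energy_loss_sampler <- function(x, ...) {
  if (x$empty) {
    cat("Empty energy-loss sampler (zero total cross-section)\n")
  } else {
    cat(sprintf(
      "Energy-loss sampler: %d grid points on [%.3g, %.3g] eV, sigma = %.4g m^2\n",
      length(x$W), min(x$W), max(x$W), x$sigma_tot))
  }
  invisible(x)
}

#' Sample exponential free-flight distances
#'
#' Distances between interactions are exponential with mean
#' \eqn{\lambda = 1/(N \sigma_{tot})}; a vanishing cross-section gives an
#' infinite path (the particle exits without interacting).
#'
#' @param n Number of draws.
#' @param sigma_tot Total cross-section per molecule (m\eqn{^2}).
#' @param number_density Molecular number density (m\eqn{^{-3}}).
#' @return Free-path lengths (m).
#' @export
sample_free_path <- function(n, sigma_tot, number_density) {
  if (sigma_tot < 0) stop("sigma_tot must be >= 0", call. = FALSE)
  if (number_density <= 0) {
    stop("number_density must be > 0", call. = FALSE)
  }
  if (sigma_tot == 0) return(rep(Inf, n))
  stats::rexp(n, rate = number_density * sigma_tot)
}

#' Select interaction channels in proportion to their cross-sections
#'
#' @param sigma Numeric vector of per-channel cross-sections (m\eqn{^2}),
#'   all \eqn{\ge 0} with a positive sum.
#' @param n Number of draws.
#' @return Integer channel indices of length `n`.
#' @export
select_channel <- function(sigma, n = 1L) {
  if (any(sigma < 0)) stop("channel cross-sections must be >= 0",
                           call. = FALSE)
  tot <- sum(sigma)
  if (tot <= 0) stop("all channel cross-sections are zero", call. = FALSE)
  p <- cumsum(sigma) / tot
  findInterval(stats::runif(n), p) + 1L
}

#' Per-history seed derived from a master seed
#'
#' Histories draw from independent, order-independent streams: history `i`
#' re-seeds from a deterministic mix of the master seed and the history
#' index, kept below \eqn{2^{31}}.
#'
#' @param master_seed Integer master seed.
#' @param index History index (0-based or 1-based; any non-negative integer).
#' @return A single integer seed.
#' @export
history_seed <- function(master_seed, index) {
  (as.numeric(master_seed) * 1664525 + as.numeric(index) * 1013904223 +
     12345) %% 2147483647
}
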