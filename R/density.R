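# Analytic densities of the diffusion elements in the natural (Z) and
# logarithmic (eta) domains, and the exact second derivative used for
# inflection-point analysis.

#' Log-domain probability density H(eta)
#'
#' Closed-form density of \eqn{\eta = \log_{10}(S)} for an N-mode Brownian
#' mixture in `n_d` dimensions. Each mode contributes
#' \deqn{\alpha_k \frac{\ln 10}{\Gamma(n_d/2)}
#'       x_k^{n_d/2} e^{-x_k}, \quad x_k = n_d \Delta t\, 10^\eta / \sigma_k^2,}
#' the chi-square (n_d degrees of freedom) law of the summed squared
#' displacement components after the logarithmic change of variables. For
#' `n_d = 2` the per-mode form reduces to
#' \eqn{\lambda_k 10^\eta \exp(-2\Delta t 10^\eta/\sigma_k^2)} with
#' \eqn{\lambda_k = 2\ln(10)\Delta t/\sigma_k^2}; for `n_d = 1` (rotational)
#' to \eqn{\lambda_\theta 10^{\eta/2} \exp(-\Delta t 10^\eta/\sigma^2)} with
#' \eqn{\lambda_\theta = \ln(10)\sqrt{\Delta t/(\pi\sigma^2)}}. The density
#' of a monomodal mode peaks exactly at \eqn{\eta_p = \log_{10}(D)},
#' independent of dimensionality.
#'
#' @param eta numeric vector of eta values (non-finite values get density 0).
#' @param model a [modal_model()].
#' @return density values, one per `eta`.
#' @export
density_eta <- function(eta, model) {
  stopifnot(inherits(model, "modal_model"))
  out <- numeric(length(eta))
  ok <- is.finite(eta)
  if (any(ok)) {
    u <- 10^eta[ok]
    half <- model$n_d / 2
    acc <- 0
    for (k in seq_len(model$n_modes)) {
      x <- model$n_d * model$dt * u / model$sigma2[k]
      acc <- acc + model$alpha[k] * log(10) / gamma(half) * x^half * exp(-x)
    }
    out[ok] <- acc
  }
  out
}

#' Natural-domain probability density F(Z)
#'
#' Density of the summed squared displacement \eqn{Z = \sum_i dx_i^2}
#' (or \eqn{\Theta = d\theta^2} for rotational data). Per mode,
#' \eqn{Z \sim \sigma_k^2 \chi^2_{n_d}}, i.e. a Gamma law with shape
#' `n_d/2` and scale \eqn{2\sigma_k^2}. For `n_d = 2` this is the
#' exponential \eqn{\exp(-Z/2\sigma^2)/(2\sigma^2)}; for `n_d = 1` it
#' diverges as \eqn{\Theta^{-1/2}} at the origin yet integrates to 1.
#'
#' @param z non-negative values of Z (um^2, or rad^2 for rotational).
#' @param model a [modal_model()].
#' @return density values, one per `z`.
#' @export
density_Z <- function(z, model) {
  stopifnot(inherits(model, "modal_model"))
  if (any(z < 0)) stop("Z must be non-negative")
  acc <- 0
  for (k in seq_len(model$n_modes)) {
    acc <- acc + model$alpha[k] *
      stats::dgamma(z, shape = model$n_d / 2, scale = 2 * model$sigma2[k])
  }
  acc
}

#' Exact second derivative of the bimodal 2D log-domain density
#'
#' Evaluates \eqn{d^2 H/d\eta^2} in closed form for a two-mode (or
#' degenerate one-mode) model in two dimensions. With
#' \eqn{u = 10^\eta}, \eqn{a_k = 2\Delta t/\sigma_k^2} and
#' \eqn{\lambda_k = a_k \ln 10}, each mode contributes
#' \deqn{\alpha_k \lambda_k \ln^2(10)\, u\,(1 - 3 a_k u + a_k^2 u^2)
#'       e^{-a_k u}.}
#' Sign changes of this expression count the inflection points of
#' \eqn{H(\eta)}; the appearance of an extra pair marks the onset of a
#' resolvable second spectral mode.
#'
#' @param eta numeric vector.
#' @param model a [modal_model()] with `n_d = 2` and at most 2 modes.
#' @return second-derivative values, one per `eta`.
#' @export
d2H_bimodal <- function(eta, model) {
  stopifnot(inherits(model, "modal_model"))
  if (model$n_d != 2L) stop("closed form requires n_d = 2")
  if (model$n_modes > 2L) stop("closed form covers at most 2 modes")
  u <- 10^eta
  l10 <- log(10)
  acc <- 0
  for (k in seq_len(model$n_modes)) {
    a <- 2 * model$dt / model$sigma2[k]
    acc <- acc + model$alpha[k] * (a * l10) * l10^2 * u *
      (1 - 3 * a * u + (a * u)^2) * exp(-a * u)
  }
  acc
}

#' Convert a spectral peak location to a diffusion coefficient
#'
#' The peak of a mode in the log-domain density sits at
#' \eqn{\eta_p = \log_{10}(D)}, so \eqn{D = 10^{\eta_p}}.
#'
#' @param eta_p peak location(s) on the eta axis.
#' @return diffusion coefficient(s) in the units of S.
#' @export
peak_diffusion <- function(eta_p) {
  if (any(!is.finite(eta_p))) stop("peak location must be finite")
  10^eta_p
}

#' Locate spectral peaks
#'
#' For an analytic [modal_model()], local maxima of the density are found
#' on a fine grid and refined by golden-section optimization. For a
#' [log_spectrum()], local maxima of the (optionally smoothed) histogram
#' density are reported.
#'
#' @param x a `"modal_model"` or `"log_spectrum"`.
#' @param smooth odd integer width of a moving-average smoothing window for
#'   spectra (1 = no smoothing).
#' @param ... unused.
#' @return numeric vector of peak eta locations, increasing.
#' @export
find_peaks <- function(x, ...) UseMethod("find_peaks")

#' @export
find_peaks.modal_model <- function(x, ...) {
  mu <- log10(x$D)
  grid <- seq(min(mu) - 2, max(mu) + 2, by = 1e-3)
  v <- density_eta(grid, x)
  n <- length(v)
  loc <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  vapply(loc, function(i) {
    stats::optimize(function(e) -density_eta(e, x),
                    c(grid[i - 1L], grid[i + 1L]), tol = 1e-10)$minimum
  }, numeric(1))
}

#' @export
find_peaks.log_spectrum <- function(x, smooth = 1L, ...) {
  dens <- x$density
  if (length(dens) == 0L || all(dens == 0)) stop("empty spectrum")
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    dens <- as.numeric(stats::filter(dens, k, sides = 2))
    dens[is.na(dens)] <- x$density[is.na(dens)]
  }
  n <- length(dens)
  if (n < 3L) return(x$mid[which.max(dens)])
  loc <- which(dens[2:(n - 1)] > dens[1:(n - 2)] &
                 dens[2:(n - 1)] >= dens[3:n] & dens[2:(n - 1)] > 0) + 1L
  if (length(loc) == 0L) loc <- which.max(dens)
  sort(x$mid[loc])
}
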