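# Information checks: KL divergence between modal densities in the natural
# and logarithmic domains.

#' Kullback-Leibler divergence between two densities
#'
#' Computes \eqn{\int p \ln(p/q)} in nats by adaptive quadrature on the
#' stated domain. Before integrating, `q` is checked to be positive
#' wherever `p` is non-negligible on a scan grid; a violation aborts with
#' the offending region named.
#'
#' @param p,q vectorized density functions on a common 1D domain.
#' @param lower,upper domain bounds (may be infinite).
#' @param rel.tol quadrature relative tolerance.
#' @param check_n size of the support-check grid (on a finite window).
#' @return the divergence in nats (non-negative up to quadrature error).
#' @export
kl_divergence <- function(p, q, lower, upper, rel.tol = 1e-10,
                          check_n = 1024L) {
  lo <- if (is.finite(lower)) lower else -50
  hi <- if (is.finite(upper)) upper else 50
  grid <- seq(lo, hi, length.out = check_n)
  pv <- p(grid); qv <- q(grid)
  bad <- pv > 1e-12 & qv <= 0
  if (any(bad)) {
    stop(sprintf("q has zero density where p > 0, e.g. near x = %.4g",
                 grid[which(bad)[1L]]))
  }
  integrand <- function(x) {
    pv <- p(x); qv <- q(x)
    out <- numeric(length(x))
    # where q underflows to exactly 0, p is itself far below the support
    # threshold (checked above); such tail slivers contribute nothing
    ok <- pv > 0 & qv > 0
    out[ok] <- pv[ok] * log(pv[ok] / qv[ok])
    out
  }
  stats::integrate(integrand, lower, upper, rel.tol = rel.tol,
                   subdivisions = 500L)$value
}

#' Moment-matched monomodal surrogate of a mixture
#'
#' The single-mode model whose per-axis displacement variance equals the
#' mixture's second moment, \eqn{\sigma_m^2 = \sum_k \alpha_k \sigma_k^2}
#' --- the SD one would measure from the pooled displacement data of the
#' mixture.
#'
#' @param model a [modal_model()].
#' @return a single-mode [modal_model()] with the same `n_d` and `dt`.
#' @export
monomodal_surrogate <- function(model) {
  stopifnot(inherits(model, "modal_model"))
  modal_model(sigma2 = sum(model$alpha * model$sigma2), alpha = 1,
              n_d = model$n_d, dt = model$dt)
}

#' KL penalty of under-representing modality, in both domains
#'
#' For a bimodal model, computes the KL divergence of the bimodal density
#' from its moment-matched monomodal surrogate, once on the natural
#' displacement domain (mixture of zero-mean Gaussians) and once on the
#' logarithmic domain ([density_eta()]). The transformation chain from
#' displacements to eta is measurable and applied identically to both
#' densities (squaring loses only the sign, to which the symmetric
#' densities are blind), so the two divergences agree: no information
#' relevant to modality is lost on the logarithmic domain.
#'
#' @param model a bimodal [modal_model()] with `n_d = 1` (displacement
#'   domain densities are the 1D Gaussian mixtures).
#' @param rel.tol quadrature tolerance.
#' @return a list with `kl_natural`, `kl_log` (nats) and the surrogate
#'   model.
#' @export
kl_domain_comparison <- function(model, rel.tol = 1e-10) {
  stopifnot(inherits(model, "modal_model"), model$n_d == 1L)
  mono <- monomodal_surrogate(model)
  dmix <- function(x, m) {
    acc <- 0
    for (k in seq_len(m$n_modes)) {
      acc <- acc + m$alpha[k] * stats::dnorm(x, 0, sqrt(m$sigma2[k]))
    }
    acc
  }
  kl_nat <- kl_divergence(function(x) dmix(x, model),
                          function(x) dmix(x, mono),
                          -Inf, Inf, rel.tol = rel.tol)
  # the 1D log-domain density decays only as 10^(eta/2) on the left, so
  # the lower truncation must sit far out for sub-1e-8 tail error
  mu <- log10(model$D)
  lo <- min(mu) - 16; hi <- max(mu) + 6
  kl_log <- kl_divergence(function(e) density_eta(e, model),
                          function(e) density_eta(e, mono),
                          lo, hi, rel.tol = rel.tol)
  list(kl_natural = kl_nat, kl_log = kl_log, surrogate = mono)
}

#' Convert a divergence between logarithm bases
#'
#' @param x divergence value(s).
#' @param from,to logarithm bases (e.g. `exp(1)` for nats, 2 for bits).
#' @return converted value(s).
#' @export
convert_log_base <- function(x, from = exp(1), to = 2) x * log(from) / log(to)
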