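# Inflection-point analysis of the bimodal log-domain density: when does a
# second spectral feature become resolvable?

# count sign changes of the exact second derivative on a fine eta grid,
# ignoring exact zeros from exponential underflow far in the tails
count_inflections <- function(model, grid = NULL, step = 1e-3) {
  if (is.null(grid)) {
    mu <- log10(max(model$D))
    grid <- seq(mu - 6, mu + 3, by = step)
  }
  s <- sign(d2H_bimodal(grid, model))
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# eta locations where the second derivative changes sign
inflection_roots <- function(model, grid = NULL, step = 1e-3) {
  if (is.null(grid)) {
    mu <- log10(max(model$D))
    grid <- seq(mu - 6, mu + 3, by = step)
  }
  v <- d2H_bimodal(grid, model)
  keep <- v != 0
  v <- v[keep]; g <- grid[keep]
  idx <- which(diff(sign(v)) != 0)
  vapply(idx, function(i) {
    stats::uniroot(function(e) d2H_bimodal(e, model), c(g[i], g[i + 1L]),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Critical mode separation of the bimodal log-domain density
#'
#' For a fixed fast-mode variance `sigma1` and mixing fraction `alpha`,
#' finds the slow-mode standard deviation `sigma2` at which an additional
#' pair of inflection points first appears in the two-mode density --- the
#' onset of a resolvable second spectral feature. Detection is by counting
#' sign changes of the exact second derivative ([d2H_bimodal()]) on a dense
#' eta grid, with bisection on `sigma2`.
#'
#' @param sigma1 fast-mode per-axis displacement SD, um.
#' @param alpha fast-mode mixing fraction, in (0, 1).
#' @param dt sampling interval, s.
#' @param tol bisection tolerance on sigma2, um.
#' @param step eta grid step for sign-change counting.
#' @return a list with `sigma2_crit` (um), `eta_crit` (location where the
#'   new inflection pair emerges, taken as the midpoint of the just-born
#'   root pair), and `D2_crit = sigma2_crit^2/(2 dt)`.
#' @export
critical_separation <- function(sigma1, alpha = 0.5, dt, tol = 1e-4,
                                step = 1e-3) {
  stopifnot(alpha > 0, alpha < 1, sigma1 > 0, dt > 0)
  nfl <- function(s2) {
    count_inflections(modal_model(sigma2 = c(sigma1^2, s2^2),
                                  alpha = c(alpha, 1 - alpha),
                                  n_d = 2L, dt = dt), step = step)
  }
  base <- nfl(sigma1 * 0.999)           # effectively monomodal
  lo <- sigma1 * 1e-3; hi <- sigma1 * 0.999
  if (nfl(lo) <= base) stop("no inflection transition found in (0, sigma1)")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nfl(mid) > base) lo <- mid else hi <- mid
  }
  s2c <- (lo + hi) / 2
  # just below critical the new pair of roots is the closest adjacent pair
  m_sub <- modal_model(sigma2 = c(sigma1^2, lo^2),
                       alpha = c(alpha, 1 - alpha), n_d = 2L, dt = dt)
  r <- inflection_roots(m_sub, step = step)
  eta_crit <- if (length(r) >= 4L) {
    gaps <- diff(r)
    i <- which.min(gaps)
    mean(r[c(i, i + 1L)])
  } else NA_real_
  list(sigma2_crit = s2c, eta_crit = eta_crit, D2_crit = s2c^2 / (2 * dt))
}

#' Critical mixing fraction for slow-mode visibility
#'
#' For fixed fast and slow modes, finds the fast-mode fraction `alpha`
#' above which the inflection-point pair associated with the slow spectral
#' peak vanishes (the slow population becomes undetectable by peak
#' counting). Bisection on alpha with sign-change counting of the exact
#' second derivative.
#'
#' @param sigma1,sigma2 fast and slow per-axis displacement SDs, um
#'   (`sigma1 > sigma2 > 0`).
#' @param dt sampling interval, s.
#' @param tol bisection tolerance on alpha.
#' @param step eta grid step.
#' @return the critical fraction `alpha_crit`.
#' @export
critical_alpha <- function(sigma1, sigma2, dt, tol = 1e-4, step = 1e-3) {
  stopifnot(sigma1 > sigma2, sigma2 > 0, dt > 0)
  nfl <- function(a) {
    count_inflections(modal_model(sigma2 = c(sigma1^2, sigma2^2),
                                  alpha = c(a, 1 - a), n_d = 2L, dt = dt),
                      step = step)
  }
  # slow-mode inflection pair present (>= 4 sign changes) at moderate alpha,
  # lost as alpha -> 1; locate the largest alpha still showing the pair
  coarse <- seq(0.05, 0.995, by = 0.05)
  vis <- vapply(coarse, function(a) nfl(a) >= 4L, logical(1))
  if (!any(vis)) stop("no inflection transition found in (0, 1): modes never resolvable")
  lo <- max(coarse[vis])
  hi <- if (any(coarse > lo & !vis)) min(coarse[coarse > lo & !vis]) else 1 - 1e-6
  if (nfl(hi) >= 4L) stop("no inflection transition found in (0, 1): pair persists as alpha -> 1")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nfl(mid) >= 4L) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
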