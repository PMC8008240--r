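# Fitting the modal model: least squares on the log-domain spectrum, and
# maximum likelihood on the natural-domain samples.

# parameter encoding: th = c(log(sigma2_1..N), w_2..N); alpha = softmax(0, w)
decode_par <- function(th, n_modes, n_d, dt) {
  sigma2 <- exp(th[seq_len(n_modes)])
  if (n_modes > 1L) {
    w <- c(0, th[n_modes + seq_len(n_modes - 1L)])
    w <- w - max(w)
    alpha <- exp(w) / sum(exp(w))
  } else {
    alpha <- 1
  }
  modal_model(sigma2 = sigma2, alpha = alpha, n_d = n_d, dt = dt)
}

encode_par <- function(model) {
  th <- log(model$sigma2)
  if (model$n_modes > 1L) {
    th <- c(th, log(model$alpha[-1L] / model$alpha[1L]))
  }
  th
}

# multi-start seeds: spectrum peaks, eta quantiles, collapsed start, init
fit_starts <- function(spectrum, n_modes, n_d, dt, init, n_starts) {
  eta_rep <- rep(spectrum$mid, times = pmax(
    round(spectrum$density * spectrum$bin_width * spectrum$n_samples), 0))
  if (length(eta_rep) == 0L) eta_rep <- spectrum$mid
  starts <- list()
  pk <- tryCatch(find_peaks(spectrum, smooth = 3L), error = function(e) numeric())
  if (length(pk) >= 1L) {
    pk <- pk[order(-spectrum$density[match(round(pk, 10),
                                           round(spectrum$mid, 10))])]
    pk <- pk[!is.na(pk)]
    if (length(pk) >= n_modes) {
      starts <- c(starts, list(sort(2 * dt * 10^pk[seq_len(n_modes)],
                                    decreasing = TRUE)))
    }
  }
  qs <- stats::quantile(eta_rep, probs = seq(0.15, 0.85,
                                             length.out = n_modes),
                        names = FALSE, type = 8)
  starts <- c(starts, list(sort(2 * dt * 10^qs, decreasing = TRUE)))
  med <- stats::median(eta_rep)
  starts <- c(starts, list(rep(2 * dt * 10^med, n_modes) *
                             10^seq(0.3, -0.3, length.out = n_modes)))
  if (!is.null(init)) starts <- c(list(init$sigma2), starts)
  # jittered replicates up to n_starts (deterministic spread, no RNG)
  i <- 1L
  while (length(starts) < n_starts) {
    base <- starts[[1L + (i - 1L) %% min(3L, length(starts))]]
    starts <- c(starts, list(base * 10^(0.4 * sin(i + seq_along(base)))))
    i <- i + 1L
  }
  starts[seq_len(max(n_starts, length(starts)))]
}

#' Fit the log-domain modal density to a spectrum
#'
#' Least-squares fit of the analytic density [density_eta()] evaluated at
#' bin centers against the normalized histogram densities, restricted to
#' occupied bins. Mode variances are kept positive and weights on the
#' simplex via an unconstrained reparameterization (log variances,
#' softmax weights); the best of several starts wins (seeded from detected
#' spectrum peaks, eta quantiles and a collapsed single-mode solution, so
#' the N-mode fit can never end worse than the nested (N-1)-mode one).
#'
#' @param x a `"diffusion_elements"` object or a prebuilt
#'   [log_spectrum()].
#' @param n_modes number of diffusive modes N.
#' @param n_d,dt dimensionality and sampling interval; taken from
#'   `"diffusion_elements"` input automatically.
#' @param bin_width histogram bin width when `x` holds raw elements.
#' @param init optional [modal_model()] used as an additional start.
#' @param n_starts number of optimizer starts.
#' @param ... unused.
#' @return an object of class `"logm_fit"`: fields `model` (the fitted
#'   [modal_model()]), `residuals` (per occupied bin), `residual_norm`
#'   (RMS residual per fitting point), `n_fit`, `converged`, `collapsed`,
#'   `spectrum`, `method = "spectrum"`, `start_used`.
#' @seealso [fit_direct_F()] for the natural-domain maximum-likelihood
#'   route; [select_modality()] for choosing N.
#' @export
fit_logmeasure <- function(x, n_modes = 1L, ...) UseMethod("fit_logmeasure")

#' @rdname fit_logmeasure
#' @export
fit_logmeasure.diffusion_elements <- function(x, n_modes = 1L,
                                              bin_width = 0.1, init = NULL,
                                              n_starts = 5L, ...) {
  sp <- log_spectrum(x, bin_width = bin_width)
  fit_logmeasure(sp, n_modes = n_modes, n_d = x$n_d, dt = x$dt, init = init,
                 n_starts = n_starts)
}

#' @rdname fit_logmeasure
#' @export
fit_logmeasure.log_spectrum <- function(x, n_modes = 1L, n_d = 2L, dt,
                                        init = NULL, n_starts = 5L, ...) {
  n_modes <- as.integer(n_modes)
  occ <- x$density > 0
  n_fit <- sum(occ)
  if (n_fit < 2L * n_modes + 1L) {
    stop(sprintf("need at least %d occupied bins to fit %d mode(s), have %d",
                 2L * n_modes + 1L, n_modes, n_fit))
  }
  mids <- x$mid[occ]
  dens <- x$density[occ]

  obj <- function(th) {
    m <- try_decode(th, n_modes, n_d, dt)
    if (is.null(m)) return(1e300)
    sum((density_eta(mids, m) - dens)^2)
  }

  sig_starts <- fit_starts(x, n_modes, n_d, dt, init, n_starts)
  best <- NULL
  best_val <- Inf
  start_used <- NA_integer_
  any_conv <- FALSE
  for (si in seq_along(sig_starts)) {
    m0 <- modal_model(sigma2 = sort(sig_starts[[si]], decreasing = TRUE),
                      alpha = if (!is.null(init) && si == 1L &&
                                  init$n_modes == n_modes) init$alpha
                              else rep(1 / n_modes, n_modes),
                      n_d = n_d, dt = dt)
    th0 <- encode_par(m0)
    fit <- if (n_modes == 1L) {
      o <- stats::optimize(function(t1) obj(t1), th0 + c(-6, 6), tol = 1e-12)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      o <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
      o2 <- suppressWarnings(
        tryCatch(stats::optim(o$par, obj, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-14)),
                 error = function(e) o))
      if (o2$value <= o$value) o2 else o
    }
    if (fit$convergence == 0L) any_conv <- TRUE
    if (fit$value < best_val) {
      best_val <- fit$value
      best <- fit
      start_used <- si
    }
  }

  model <- decode_par(best$par, n_modes, n_d, dt)
  collapsed <- FALSE
  if (model$n_modes > 1L) {
    sep <- abs(diff(log10(model$D)))
    if (any(sep < 0.05)) collapsed <- TRUE
  }
  res <- density_eta(mids, model) - dens
  structure(list(model = model, residuals = res,
                 residual_norm = sqrt(mean(res^2)), n_fit = n_fit,
                 converged = any_conv, collapsed = collapsed, spectrum = x,
                 method = "spectrum", start_used = start_used,
                 objective = best_val, call = match.call()),
            class = "logm_fit")
}

try_decode <- function(th, n_modes, n_d, dt) {
  if (any(!is.finite(th)) || any(th[seq_len(n_modes)] > 700) ||
      any(th[seq_len(n_modes)] < -700)) return(NULL)
  tryCatch(decode_par(th, n_modes, n_d, dt), error = function(e) NULL)
}

#' Maximum-likelihood fit in the natural domain
#'
#' Fits the mixture density [density_Z()] directly to the raw
#' \eqn{Z = 2 n_d \Delta t\, S} samples by maximum likelihood, without
#' histogramming. For a single mode the maximizer is the closed form
#' \eqn{\hat\sigma^2 = \mathrm{mean}(Z)/n_d}.
#'
#' @param x a `"diffusion_elements"` object.
#' @param n_modes number of modes.
#' @param init optional [modal_model()] start.
#' @param n_starts optimizer starts for multimodal fits.
#' @return a `"logm_fit"` with `method = "mle_F"` and a `logLik` field.
#'   Residual fields are computed against the default-width spectrum so
#'   that fits from both routes are comparable.
#' @export
fit_direct_F <- function(x, n_modes = 1L, init = NULL, n_starts = 5L) {
  stopifnot(inherits(x, "diffusion_elements"))
  n_modes <- as.integer(n_modes)
  z <- x$S * (2 * x$n_d * x$dt)
  z <- z[z > 0]
  if (length(z) < n_modes) stop("fewer positive samples than modes")
  nll <- function(th) {
    m <- try_decode(th, n_modes, x$n_d, x$dt)
    if (is.null(m)) return(1e300)
    v <- density_Z(z, m)
    if (any(v <= 0)) return(1e300)
    -sum(log(v))
  }
  qs <- stats::quantile(z, probs = seq(0.2, 0.8, length.out = n_modes),
                        names = FALSE)
  starts <- list(sort(qs / x$n_d, decreasing = TRUE),
                 rep(mean(z) / x$n_d, n_modes) *
                   10^seq(0.3, -0.3, length.out = n_modes))
  if (!is.null(init)) starts <- c(list(init$sigma2), starts)
  i <- 1L
  while (length(starts) < n_starts) {
    starts <- c(starts, list(starts[[1L]] * 10^(0.4 * sin(i + seq_len(n_modes)))))
    i <- i + 1L
  }
  best <- NULL; best_val <- Inf; any_conv <- FALSE
  for (s in starts) {
    m0 <- modal_model(sigma2 = sort(s, decreasing = TRUE), n_d = x$n_d,
                      dt = x$dt)
    th0 <- encode_par(m0)
    fit <- if (n_modes == 1L) {
      o <- stats::optimize(function(t1) nll(t1), th0 + c(-6, 6), tol = 1e-12)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      stats::optim(th0, nll, method = "Nelder-Mead",
                   control = list(maxit = 4000, reltol = 1e-14))
    }
    if (fit$convergence == 0L) any_conv <- TRUE
    if (fit$value < best_val) { best_val <- fit$value; best <- fit }
  }
  model <- decode_par(best$par, n_modes, x$n_d, x$dt)
  sp <- log_spectrum(x)
  occ <- sp$density > 0
  res <- density_eta(sp$mid[occ], model) - sp$density[occ]
  structure(list(model = model, residuals = res,
                 residual_norm = sqrt(mean(res^2)), n_fit = sum(occ),
                 converged = any_conv, collapsed = FALSE, spectrum = sp,
                 method = "mle_F", logLik = -best_val, n_samples = length(z),
                 call = match.call()),
            class = "logm_fit")
}

#' @export
print.logm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Log-measure fit (%s), %d mode(s)\n",
              if (x$method == "spectrum") "least squares on eta histogram"
              else "maximum likelihood on Z", x$model$n_modes))
  tab <- data.frame(alpha = signif(x$model$alpha, digits),
                    D = signif(x$model$D, digits))
  print(tab, row.names = paste0("mode", seq_len(x$model$n_modes)))
  cat(sprintf("RMS residual per fitting point: %.4g over %d bins\n",
              x$residual_norm, x$n_fit))
  if (!x$converged) cat("warning: no optimizer start reported convergence\n")
  if (x$collapsed) cat("note: modes closer than 0.05 decades; not separately identifiable\n")
  invisible(x)
}

#' @export
summary.logm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.logm_fit")
}

#' @export
print.summary.logm_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("dt = %g s, n_d = %d, method = %s, converged = %s\n",
              f$model$dt, f$model$n_d, f$method, f$converged))
  cat("peak eta locations:",
      paste(signif(find_peaks(f$model), 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.logm_fit <- function(object, ...) coef(object$model)

#' @export
residuals.logm_fit <- function(object, ...) object$residuals

#' @export
fitted.logm_fit <- function(object, ...) {
  occ <- object$spectrum$density > 0
  density_eta(object$spectrum$mid[occ], object$model)
}

#' @export
predict.logm_fit <- function(object, newdata = NULL, ...) {
  eta <- if (is.null(newdata)) object$spectrum$mid
         else if (is.list(newdata)) newdata$eta else newdata
  density_eta(eta, object$model)
}

#' @export
plot.logm_fit <- function(x, n_grid = 400, ...) {
  sp <- x$spectrum
  graphics::plot(sp$mid, sp$density, xlab = expression(eta == log[10](S)),
                 ylab = expression(H(eta)), ...)
  grid <- seq(min(sp$edges), max(sp$edges), length.out = n_grid)
  graphics::lines(grid, density_eta(grid, x$model))
  invisible(x)
}

#' @export
simulate.logm_fit <- function(object, nsim = 1, seed = NULL,
                              n = object$spectrum$n_samples, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, {
    s <- sample_elements(object$model, n)
    log10(s$S)
  }, simplify = FALSE)
  if (nsim == 1L) out[[1L]] else out
}

#' @export
logLik.logm_fit <- function(object, ...) {
  if (is.null(object$logLik)) stop("log-likelihood only defined for mle_F fits")
  structure(object$logLik, df = 2 * object$model$n_modes - 1,
            nobs = object$n_samples, class = "logLik")
}
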