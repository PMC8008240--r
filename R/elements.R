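# Diffusion elements S and their log-domain histogram.

#' Diffusion elements S and their logarithm
#'
#' The diffusion element of one step is the normalized squared displacement
#' \eqn{S = |d r|^2 / (2 n_d \Delta t)} (units um^2/s; rad^2/s for angular
#' displacements with \eqn{n_d = 1}). It has units of a diffusion
#' coefficient but is a single-step random variable, not an average. The
#' log-domain variable is \eqn{\eta = \log_{10}(S)}. Exactly zero
#' displacements have no finite \eqn{\eta}; they are excluded from
#' `eta` and counted in `n_zero`.
#'
#' @param disp a `"displacement_set"` from [displacements()] or
#'   [angular_displacements()].
#' @return an object of class `"diffusion_elements"`: fields `S`, `eta`
#'   (log10 of the positive S values), `n_d`, `dt`, `n_zero`, `kind`,
#'   `particle` (ids for the positive-S entries).
#' @export
diffusion_elements <- function(disp) {
  stopifnot(inherits(disp, "displacement_set"))
  if (nrow(disp$d) == 0L) stop("empty displacement set")
  if (disp$dt <= 0) stop("dt must be positive")
  S <- rowSums(disp$d^2) / (2 * disp$n_d * disp$dt)
  pos <- S > 0
  structure(list(S = S, eta = log10(S[pos]), n_d = disp$n_d, dt = disp$dt,
                 n_zero = sum(!pos), kind = disp$kind,
                 particle = disp$particle[pos]),
            class = "diffusion_elements")
}

#' @export
print.diffusion_elements <- function(x, ...) {
  cat(sprintf("<diffusion_elements: %d values (%d zero excluded), n_d = %d, dt = %g s>\n",
              length(x$S), x$n_zero, x$n_d, x$dt))
  invisible(x)
}

#' Log-domain spectrum (normalized histogram of eta)
#'
#' Accumulates \eqn{\eta = \log_{10}(S)} into evenly spaced bins and
#' normalizes to a probability density per unit \eqn{\eta}. Bin edges are
#' aligned to multiples of the bin width; the default range spans the data
#' padded by one bin on each side.
#'
#' @param x a `"diffusion_elements"` object, or a numeric vector of eta
#'   values.
#' @param bin_width histogram bin width on the eta axis (default 0.1; a
#'   warning is issued above 0.5, where fitted coefficients become
#'   width-dependent).
#' @param range optional length-2 eta bounds.
#' @param ... unused.
#' @return an object of class `"log_spectrum"`: fields `edges`, `mid`,
#'   `density`, `bin_width`, `n_samples`.
#' @export
log_spectrum <- function(x, bin_width = 0.1, range = NULL, ...) {
  UseMethod("log_spectrum")
}

#' @export
log_spectrum.diffusion_elements <- function(x, bin_width = 0.1, range = NULL, ...) {
  if (length(x$eta) == 0L) stop("all displacements are zero; no finite eta")
  log_spectrum(x$eta, bin_width = bin_width, range = range)
}

#' @export
log_spectrum.numeric <- function(x, bin_width = 0.1, range = NULL, ...) {
  if (length(x) == 0L) stop("no eta values")
  if (bin_width <= 0) stop("bin width must be positive")
  if (bin_width > 0.5) {
    warning("bin widths above 0.5 distort fitted coefficients; ",
            "widths below 0.5 are suitable")
  }
  if (is.null(range)) {
    range <- c(floor(min(x) / bin_width) - 1, ceiling(max(x) / bin_width) + 1) *
      bin_width
  } else {
    if (min(x) < range[1] || max(x) > range[2]) {
      stop("eta values fall outside the requested range")
    }
    range <- c(floor(range[1] / bin_width), ceiling(range[2] / bin_width)) *
      bin_width
  }
  edges <- seq(range[1], range[2], by = bin_width)
  h <- graphics::hist(x, breaks = edges, plot = FALSE, right = FALSE)
  structure(list(edges = edges, mid = h$mids, density = h$density,
                 bin_width = bin_width, n_samples = length(x)),
            class = "log_spectrum")
}

#' @export
print.log_spectrum <- function(x, ...) {
  cat(sprintf("<log_spectrum: %d bins of width %g over [%g, %g], n = %d>\n",
              length(x$mid), x$bin_width, min(x$edges), max(x$edges),
              x$n_samples))
  invisible(x)
}

#' @export
plot.log_spectrum <- function(x, ...) {
  graphics::plot(x$mid, x$density, xlab = expression(eta == log[10](S)),
                 ylab = expression(H(eta)), ...)
  invisible(x)
}

#' @export
as.data.frame.log_spectrum <- function(x, ...) {
  data.frame(eta = x$mid, density = x$density)
}
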