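# N-mode diffusion model: mixture weights and per-mode displacement variances.

#' N-mode diffusion model
#'
#' Describes a population mixing `N` Brownian modes in `n_d` dimensions.
#' Each mode k has per-axis displacement variance
#' \eqn{\sigma_k^2 = 2 D_k \Delta t} over the sampling interval
#' \eqn{\Delta t}. Supply either diffusion coefficients `D` (um^2/s, or
#' rad^2/s for rotational data) or variances `sigma2`. Modes are stored
#' sorted by decreasing variance.
#'
#' @param D diffusion coefficients, one per mode.
#' @param alpha mixture weights (positive, summing to 1); default equal.
#' @param n_d spatial dimensionality (1, 2 or 3; rotational data is 1).
#' @param dt sampling interval, seconds.
#' @param sigma2 per-axis displacement variances, alternative to `D`.
#' @return an object of class `"modal_model"` with fields `alpha`, `sigma2`,
#'   `D`, `n_modes`, `n_d`, `dt`.
#' @export
modal_model <- function(D = NULL, alpha = NULL, n_d = 2L, dt, sigma2 = NULL) {
  if (is.null(sigma2)) {
    if (is.null(D)) stop("supply D or sigma2")
    sigma2 <- 2 * D * dt
  }
  n <- length(sigma2)
  if (is.null(alpha)) alpha <- rep(1 / n, n)
  if (length(alpha) != n) stop("alpha and variances disagree in length")
  if (any(alpha <= 0)) stop("mixture weights must be positive")
  if (abs(sum(alpha) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(sigma2 <= 0)) stop("mode variances must be positive")
  if (!n_d %in% 1:3) stop("n_d must be 1, 2 or 3")
  if (dt <= 0) stop("dt must be positive")
  ord <- order(sigma2, decreasing = TRUE)
  structure(list(alpha = alpha[ord] / sum(alpha), sigma2 = sigma2[ord],
                 D = sigma2[ord] / (2 * dt), n_modes = n,
                 n_d = as.integer(n_d), dt = dt),
            class = "modal_model")
}

#' @export
print.modal_model <- function(x, digits = 4, ...) {
  cat(sprintf("<modal_model: %d mode(s), n_d = %d, dt = %g s>\n",
              x$n_modes, x$n_d, x$dt))
  tab <- data.frame(alpha = signif(x$alpha, digits),
                    sigma2 = signif(x$sigma2, digits),
                    D = signif(x$D, digits))
  print(tab, row.names = paste0("mode", seq_len(x$n_modes)))
  invisible(x)
}

#' @export
coef.modal_model <- function(object, ...) {
  n <- object$n_modes
  stats::setNames(c(object$alpha, object$sigma2, object$D),
                  c(paste0("alpha", seq_len(n)), paste0("sigma2_", seq_len(n)),
                    paste0("D", seq_len(n))))
}

# draw n diffusion elements (S values) from the model; returns list(S, mode)
sample_elements <- function(model, n) {
  mode <- sample.int(model$n_modes, n, replace = TRUE, prob = model$alpha)
  z <- model$sigma2[mode] * stats::rchisq(n, df = model$n_d)
  list(S = z / (2 * model$n_d * model$dt), mode = mode)
}
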