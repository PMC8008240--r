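# Residual-ratio model selection between one- and two-mode log-domain fits,
# and the paired-trajectory detection experiment.

#' Select between one- and two-mode models by residual ratio
#'
#' Fits both the monomodal and the bimodal log-domain density to the same
#' eta histogram and compares the RMS fitting residuals R1 and R2. The
#' two-mode model is selected when \eqn{R_2/R_1 \le \epsilon}, i.e. when
#' adding the second mode improves the residual by at least the factor
#' `epsilon`. With `epsilon = 1` there is no filtering: because the
#' two-mode family nests the one-mode family (and the two-mode fit is
#' started from the one-mode optimum), \eqn{R_2 \le R_1} and two modes are
#' essentially always selected. Decreasing `epsilon` demands increasingly
#' decisive improvement, so the bimodal detection rate is non-decreasing in
#' `epsilon`.
#'
#' @param elems a `"diffusion_elements"` object.
#' @param epsilon selection threshold in (0, 1].
#' @param bin_width histogram bin width (small pooled samples warrant a
#'   coarser width; the detection experiment uses 0.2).
#' @param n_starts optimizer starts for the two-mode fit.
#' @return an object of class `"selection_outcome"`: fields `R1`, `R2`,
#'   `ratio`, `epsilon`, `chosen` (1 or 2), `fits` (both `"logm_fit"`
#'   objects), `flag` (NA, or a reason the two-mode fit was unavailable,
#'   in which case `chosen = 1`).
#' @export
select_modality <- function(elems, epsilon = 0.95, bin_width = 0.1,
                            n_starts = 3L) {
  stopifnot(inherits(elems, "diffusion_elements"))
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must be in (0, 1]")
  sp <- log_spectrum(elems, bin_width = bin_width)
  fit1 <- tryCatch(fit_logmeasure(sp, n_modes = 1L, n_d = elems$n_d,
                                  dt = elems$dt, n_starts = n_starts),
                   error = function(e) e)
  if (inherits(fit1, "error")) {
    return(structure(list(R1 = NA_real_, R2 = NA_real_, ratio = NA_real_,
                          epsilon = epsilon, chosen = 1L, fits = NULL,
                          flag = conditionMessage(fit1)),
                     class = "selection_outcome"))
  }
  # seed the nested fit from the one-mode optimum so R2 <= R1 at the optimum
  init2 <- modal_model(sigma2 = fit1$model$sigma2 * c(1, 1),
                       alpha = c(0.5, 0.5), n_d = elems$n_d, dt = elems$dt)
  fit2 <- tryCatch(fit_logmeasure(sp, n_modes = 2L, n_d = elems$n_d,
                                  dt = elems$dt, init = init2,
                                  n_starts = n_starts),
                   error = function(e) e)
  if (inherits(fit2, "error")) {
    return(structure(list(R1 = fit1$residual_norm, R2 = NA_real_,
                          ratio = NA_real_, epsilon = epsilon, chosen = 1L,
                          fits = list(fit1 = fit1, fit2 = NULL),
                          flag = conditionMessage(fit2)),
                     class = "selection_outcome"))
  }
  ratio <- fit2$residual_norm / fit1$residual_norm
  structure(list(R1 = fit1$residual_norm, R2 = fit2$residual_norm,
                 ratio = ratio, epsilon = epsilon,
                 chosen = if (ratio <= epsilon) 2L else 1L,
                 fits = list(fit1 = fit1, fit2 = fit2), flag = NA_character_),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("Residual-ratio model selection: chose %d mode(s)\n", x$chosen))
  cat(sprintf("  R1 = %.4g, R2 = %.4g, R2/R1 = %.4g, epsilon = %g\n",
              x$R1, x$R2, x$ratio, x$epsilon))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Bimodal detection experiment on paired short trajectories
#'
#' Repeats the paired-sample protocol: each repetition draws `n_pairs`
#' fast and `n_pairs` slow ideal Brownian trajectories of `n_frames`
#' frames, pools their displacements, and runs [select_modality()]. The
#' detection percentage is the fraction of repetitions selecting two
#' modes; the distribution of the fitted fast and slow coefficients over
#' the detecting repetitions is summarized alongside.
#'
#' @param D_fast,D_slow the two mode coefficients, um^2/s.
#' @param n_frames frames per trajectory (a 5-frame track contributes 4
#'   displacements).
#' @param n_pairs sample size N_s (trajectory pairs per repetition).
#' @param reps number of repetitions.
#' @param epsilon selection threshold.
#' @param dt frame interval, s.
#' @param n_d dimensionality.
#' @param bin_width histogram bin width for the small-sample fits.
#' @param seed master seed; repetitions use derived substreams.
#' @return a list with `detection_pct`, `chosen` (per-repetition), `D_fast`
#'   and `D_slow` (per-repetition fitted coefficients where two modes were
#'   selected, NA otherwise), and summary `means` and `sds`.
#' @export
detection_experiment <- function(D_fast, D_slow, n_frames = 5L, n_pairs = 1L,
                                 reps = 200L, epsilon = 1, dt = 2.5,
                                 n_d = 2L, bin_width = 0.2, seed = 1L) {
  stopifnot(n_frames >= 2L, D_fast > D_slow)
  chosen <- integer(reps)
  dfast <- dslow <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    sub <- track_seed(seed, r)
    fast <- simulate_ideal(mixture_spec(D = D_fast, alpha = 1, n_d = n_d,
                                        dt = dt, n_steps = n_frames - 1L,
                                        n_tracks = n_pairs, seed = sub))
    slow <- simulate_ideal(mixture_spec(D = D_slow, alpha = 1, n_d = n_d,
                                        dt = dt, n_steps = n_frames - 1L,
                                        n_tracks = n_pairs,
                                        seed = track_seed(sub, 7L)))
    pooled <- traj_set(c(unclass(fast), unclass(slow)))
    el <- diffusion_elements(displacements(pooled))
    out <- select_modality(el, epsilon = epsilon, bin_width = bin_width)
    chosen[r] <- out$chosen
    if (out$chosen == 2L) {
      dfast[r] <- max(out$fits$fit2$model$D)
      dslow[r] <- min(out$fits$fit2$model$D)
    }
  }
  det <- chosen == 2L
  list(detection_pct = 100 * mean(det), chosen = chosen,
       D_fast = dfast, D_slow = dslow,
       means = c(D_fast = mean(dfast[det]), D_slow = mean(dslow[det])),
       sds = c(D_fast = stats::sd(dfast[det]), D_slow = stats::sd(dslow[det])),
       epsilon = epsilon, n_pairs = n_pairs, n_frames = n_frames,
       reps = reps, seed = seed)
}
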