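test_that("noiseless self-consistency: fitting the analytic density recovers it", {
  m <- modal_model(D = 2.4e-3, n_d = 2, dt = 2.5)
  mid <- seq(-5, -1, by = 0.1) + 0.05
  sp <- structure(list(edges = seq(-5, -0.9, by = 0.1), mid = mid,
                       density = density_eta(mid, m), bin_width = 0.1,
                       n_samples = 10000L), class = "log_spectrum")
  fit <- fit_logmeasure(sp, n_modes = 1, n_d = 2, dt = 2.5)
  expect_equal(fit$model$sigma2, m$sigma2, tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)

  m2 <- modal_model(D = c(1.8e-3, 6.5e-5), alpha = c(0.6, 0.4), n_d = 2,
                    dt = 2.5)
  sp2 <- structure(list(edges = seq(-6.5, -0.9, by = 0.1),
                        mid = seq(-6.5, -1, by = 0.1) + 0.05,
                        density = density_eta(seq(-6.5, -1, by = 0.1) + 0.05, m2),
                        bin_width = 0.1, n_samples = 10000L),
                   class = "log_spectrum")
  fit2 <- fit_logmeasure(sp2, n_modes = 2, n_d = 2, dt = 2.5)
  expect_equal(fit2$model$D, m2$D, tolerance = 1e-4)
  expect_equal(fit2$model$alpha, m2$alpha, tolerance = 1e-4)
})

test_that("bimodal parameter recovery from synthetic displacements", {
  spec <- mixture_spec(D = c(1.8e-3, 6.5e-5), alpha = c(0.5, 0.5), n_d = 2,
                       dt = 2.5, n_steps = 25, n_tracks = 800, seed = 21)
  el <- diffusion_elements(displacements(simulate_ideal(spec)))
  fit <- fit_logmeasure(el, n_modes = 2)
  expect_equal(fit$model$D[1], 1.8e-3, tolerance = 0.10)
  expect_equal(fit$model$D[2], 6.5e-5, tolerance = 0.10)
  expect_equal(fit$model$alpha[1], 0.5, tolerance = 0.12)
  expect_true(fit$converged)

  # residual identity: residual_norm = sqrt(mean(residuals^2)); n_fit = bins used
  expect_equal(fit$residual_norm, sqrt(mean(fit$residuals^2)))
  expect_identical(fit$n_fit, sum(fit$spectrum$density > 0))
})

test_that("insufficient occupied bins is a hard precondition", {
  sp <- log_spectrum(c(-3.01, -2.52), bin_width = 0.1)
  expect_error(fit_logmeasure(sp, n_modes = 2, n_d = 2, dt = 2.5),
               "occupied bins")
})

test_that("direct-F maximum likelihood matches the closed form", {
  set.seed(9)
  for (n_d in c(1L, 2L)) {
    m <- modal_model(D = 5e-4, n_d = n_d, dt = 2.5)
    s <- logdiffuse:::sample_elements(m, 400)
    # components chosen so |d|^2 / (2 n_d dt) reproduces the drawn S exactly
    d <- structure(list(d = matrix(sqrt(2 * 2.5 * s$S), 400, n_d),
                        n_d = n_d, dt = 2.5,
                        particle = rep("p", 400), step = 1:400,
                        kind = "translational"),
                   class = "displacement_set")
    el <- diffusion_elements(d)
    fit <- fit_direct_F(el, n_modes = 1)
    z <- el$S * 2 * n_d * el$dt
    expect_equal(fit$model$sigma2, mean(z) / n_d, tolerance = 1e-6)
  }
  # single-sample edge case: sigma2_hat = Z / n_d
  d1 <- structure(list(d = matrix(c(0.3, 0.4), 1, 2), n_d = 2L, dt = 2.5,
                       particle = "p", step = 1L, kind = "translational"),
                  class = "displacement_set")
  el1 <- diffusion_elements(d1)
  fit1 <- fit_direct_F(el1, n_modes = 1)
  expect_equal(fit1$model$sigma2, 0.25 / 2, tolerance = 1e-6)
})

test_that("logm_fit methods are coherent", {
  spec <- mixture_spec(D = 1.8e-3, alpha = 1, n_d = 2, dt = 2.5,
                       n_steps = 40, n_tracks = 150, seed = 33)
  el <- diffusion_elements(displacements(simulate_ideal(spec)))
  fit <- fit_logmeasure(el, n_modes = 1)
  co <- coef(fit)
  expect_named(co, c("alpha1", "sigma2_1", "D1"))
  expect_equal(unname(co["D1"]), unname(co["sigma2_1"]) / (2 * 2.5))
  expect_length(residuals(fit), fit$n_fit)
  expect_equal(fitted(fit) - residuals(fit),
               fit$spectrum$density[fit$spectrum$density > 0])
  grid <- seq(-5, -1, by = 0.5)
  expect_equal(predict(fit, grid), density_eta(grid, fit$model))
  sim <- simulate(fit, seed = 1, n = 500)
  expect_length(sim, 500L)
  expect_output(print(summary(fit)), "peak eta")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("robustness curve has its minimum at the fit and is locally quadratic", {
  # population of short tracks: the regime where the L2 curve is smooth
  # and locally quadratic around the optimum
  spec <- mixture_spec(D = 1.8e-3, alpha = 1, n_d = 2, dt = 2.5,
                       n_steps = 20, n_tracks = 150, seed = 14)
  el <- diffusion_elements(displacements(simulate_ideal(spec)))
  fit <- fit_logmeasure(el, n_modes = 1)
  rs <- robustness_and_sensitivity(fit)
  at0 <- rs$curve$l2[rs$curve$delta == 0]
  expect_equal(at0, fit$residual_norm, tolerance = 1e-10)
  expect_true(all(rs$curve$l2 >= at0 - 1e-12))
  expect_gt(rs$curvature, 0)
  expect_gt(rs$r_squared, 0.99)
  expect_error(robustness_and_sensitivity(fit, delta = c(-1.5, 0)), "-1")
})

test_that("fitted D is stable across histogram bin widths below 0.5", {
  spec <- mixture_spec(D = 1.8e-3, alpha = 1, n_d = 2, dt = 2.5,
                       n_steps = 50, n_tracks = 800, seed = 8)
  el <- diffusion_elements(displacements(simulate_ideal(spec)))
  sweep <- bin_width_sweep(el, widths = c(0.05, 0.1, 0.2, 0.5), n_modes = 1)
  expect_true(all(!sweep$flagged[sweep$bin_width <= 0.5]))
  d05 <- sweep$D[sweep$bin_width == 0.05]
  d10 <- sweep$D[sweep$bin_width == 0.1]
  expect_equal(d05, d10, tolerance = 0.02)
})
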