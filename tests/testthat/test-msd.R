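test_that("MSD closed forms: ballistic and stationary motion", {
  tr <- ballistic_traj(v = 0.3, n = 21, dt = 0.5)
  cv <- msd_curve(tr, max_lag = 10)
  expect_equal(cv$msd, 0.3^2 * cv$lag^2, tolerance = 1e-12)
  expect_true(all(diff(cv$lag) > 0))
  expect_equal(cv$n_pairs, 21 - (1:10))   # internal averaging pair counts

  still <- trajectory("s", 0:10, matrix(1.5, 11, 2))
  expect_true(all(msd_curve(still)$msd == 0))
  expect_error(msd_curve(still, max_lag = 11), "max_lag")
})

test_that("internal averaging at lag 1 equals the mean squared step", {
  set.seed(6)
  tr <- trajectory("p", 0:30, apply(matrix(rnorm(62, 0, 0.2), 31, 2), 2, cumsum))
  cv <- msd_curve(tr, max_lag = 5)
  steps <- diff(tr$pos[, 1])^2 + diff(tr$pos[, 2])^2
  expect_equal(cv$msd[1], mean(steps), tolerance = 1e-12)
  # direct enumeration oracle at lag 3
  lag3 <- rowSums((tr$pos[4:31, ] - tr$pos[1:28, ])^2)
  expect_equal(cv$msd[3], mean(lag3), tolerance = 1e-12)
})

test_that("regression on an exact line returns slope/(2 n_d) with free intercept", {
  lag <- (1:20) * 2.5
  cv <- structure(data.frame(lag = lag, msd = 4 * 1.8e-3 * lag + 0.01,
                             n_pairs = 40L),
                  dt = 2.5, n_d = 2L, internal = TRUE,
                  class = c("msd_curve", "data.frame"))
  fit <- d_from_msd(cv, filter = "full")
  expect_equal(fit$D, 1.8e-3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-9)
  # degenerate decreasing curve: negative D flagged, no exception
  cv$msd <- rev(cv$msd)
  neg <- d_from_msd(cv, filter = "fifth")
  expect_true(neg$flagged_negative)
  expect_lt(neg$D, 0)
  expect_error(d_from_msd(cv[1, , drop = FALSE], n_max = 1), "2 lags")
})

test_that("frame-based and individual-based averages weight steps differently", {
  # particle A: 10 steps with mean S 2; particle B: 2 steps with mean S 4
  mk <- function(id, svals, dt = 1) {
    comp <- sqrt(svals * 2 * 2 * dt / 2)   # 2D equal components
    pos <- apply(rbind(0, cbind(comp, comp)), 2, cumsum)
    trajectory(id, (0:length(svals)) * dt, pos)
  }
  trajs <- traj_set(list(mk("A", rep(2, 10)), mk("B", rep(4, 2))))
  expect_equal(d_individual_based(trajs), 3, tolerance = 1e-12)
  expect_equal(d_frame_based(trajs), (10 * 2 + 2 * 4) / 12, tolerance = 1e-12)

  # identity: D_FB equals the pooled mean of the diffusion elements
  set.seed(44)
  rnd <- traj_set(lapply(1:5, function(i) {
    trajectory(paste0("r", i), 0:(5 + i),
               apply(matrix(rnorm((6 + i) * 2, 0, 0.3), 6 + i, 2), 2, cumsum))
  }))
  el <- diffusion_elements(displacements(rnd))
  expect_equal(d_frame_based(rnd), mean(el$S), tolerance = 1e-12)
  # equal track lengths make the two averages coincide exactly
  eq <- traj_set(lapply(1:4, function(i) {
    trajectory(paste0("e", i), 0:6,
               apply(matrix(rnorm(14, 0, 0.3), 7, 2), 2, cumsum))
  }))
  expect_equal(d_frame_based(eq), d_individual_based(eq), tolerance = 1e-12)
})

test_that("mode-correlated track lengths split D_IB from D_FB", {
  set.seed(15)
  slow <- simulate_ideal(mixture_spec(D = 6.5e-5, alpha = 1, n_d = 2,
                                      dt = 2.5, n_steps = 60, n_tracks = 40,
                                      seed = 1))
  fast <- simulate_ideal(mixture_spec(D = 1.8e-3, alpha = 1, n_d = 2,
                                      dt = 2.5, n_steps = 6, n_tracks = 40,
                                      seed = 2))
  fast <- traj_set(lapply(fast, function(tr) {
    tr$particle_id <- paste0("fast_", tr$particle_id)
    tr
  }))
  mixed <- traj_set(c(unclass(slow), unclass(fast)))
  # step-weighting pulls the frame-based average towards the long-lived
  # slow population, so it falls below the per-particle average
  expect_lt(d_frame_based(mixed), d_individual_based(mixed))
  # expectation oracle: D_FB ~ steps-weighted mode mean, D_IB ~ unweighted
  w_fb <- (40 * 60 * 6.5e-5 + 40 * 6 * 1.8e-3) / (40 * 60 + 40 * 6)
  w_ib <- (6.5e-5 + 1.8e-3) / 2
  expect_equal(d_frame_based(mixed), w_fb, tolerance = 0.15)
  expect_equal(d_individual_based(mixed), w_ib, tolerance = 0.15)
})

test_that("population error statistics: estimators are unbiased, MSD error flat", {
  pe_msd <- population_error(1.8e-3, dt = 2.5, track_lengths = c(5, 20, 100),
                             n_tracks = 400, estimator = "msd_full", seed = 2)
  # unbiased within 3 standard errors at every length
  expect_true(all(abs(pe_msd$mean - 1.8e-3) <
                    3 * pe_msd$sd / sqrt(pe_msd$n)))
  # full-MSD error roughly constant in track length (well off the -1/2 law)
  slope_msd <- unname(coef(lm(log(sd) ~ log(N_T), pe_msd))[2])
  expect_gt(slope_msd, -0.25)

  pe_f <- population_error(1.8e-3, dt = 2.5, track_lengths = c(5, 20, 100),
                           n_tracks = 400, estimator = "direct_F", seed = 3)
  expect_true(all(abs(pe_f$mean - 1.8e-3) < 3 * pe_f$sd / sqrt(pe_f$n)))
  slope_f <- unname(coef(lm(log(sd) ~ log(N_T), pe_f))[2])
  expect_lt(abs(slope_f + 0.5), 0.12)
})
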