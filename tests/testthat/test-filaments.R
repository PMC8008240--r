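test_that("rod drag formulas and derived diffusion coefficients", {
  dc <- drag_coefficients(L = 1, d = 0.025, zeta = 1, temperature = 300)
  lg <- log(40)
  expect_equal(dc$gamma_par, 2 * pi / lg, tolerance = 1e-12)
  expect_equal(dc$gamma_perp / dc$gamma_par, 2)     # universal ratio
  expect_equal(dc$gamma_rot, pi / (3 * lg), tolerance = 1e-12)
  expect_equal(signif(dc$D_com, 2), 1.8e-3)
  expect_equal(dc$D_rot, 1.459e-2, tolerance = 1e-3)
  # ratio holds for arbitrary geometry
  dc2 <- drag_coefficients(L = 4, d = 0.1, zeta = 3, temperature = 290)
  expect_equal(dc2$gamma_perp / dc2$gamma_par, 2)
  expect_error(drag_coefficients(L = 0.01, d = 0.025), "exceed")
})

test_that("segment minimum distance: symmetric and crossing cases", {
  # parallel horizontal segments offset in y
  g <- segment_min_distance(c(0, 0), 0, 1, c(0, 0.1), 0, 1)
  expect_equal(g$dist, 0.1, tolerance = 1e-12)
  expect_equal(g$lambda1, 0, tolerance = 1e-9)
  expect_equal(g$lambda2, 0, tolerance = 1e-9)
  # perpendicular crossing segments touch
  gx <- segment_min_distance(c(0, 0), 0, 1, c(0, 0), pi / 2, 1)
  expect_equal(gx$dist, 0, tolerance = 1e-12)
  # minimum image: neighbors across the periodic boundary
  gp <- segment_min_distance(c(0.2, 5), pi / 2, 1, c(29.9, 5), pi / 2, 1,
                             box = c(30, 30))
  expect_equal(gp$dist, 0.3, tolerance = 1e-12)
})

test_that("segment minimum distance agrees with brute-force discretization", {
  set.seed(23)
  n_grid <- 201L
  s_par <- seq(-0.5, 0.5, length.out = n_grid)
  worst <- 0
  for (k in 1:200) {
    r2 <- runif(2, -1.2, 1.2)
    th <- runif(2, -pi, pi)
    g <- segment_min_distance(c(0, 0), th[1], 1, r2, th[2], 1)
    p1 <- cbind(s_par * cos(th[1]), s_par * sin(th[1]))
    p2 <- cbind(r2[1] + s_par * cos(th[2]), r2[2] + s_par * sin(th[2]))
    dd <- sqrt(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2)
    worst <- max(worst, abs(g$dist - min(dd)))
    expect_lte(g$dist, min(dd) + 1e-9)   # never above the discretized min
  }
  expect_lt(worst, 2e-2)                 # within the grid resolution
})

test_that("WCA and tether forces match their potentials", {
  d <- 0.025
  eps <- kBT(300)
  expect_equal(wca_force(2^(1 / 6) * d, d, eps), 0, tolerance = 1e-9)
  expect_equal(wca_force(0.05, d, eps), 0)               # beyond cutoff
  expect_equal(wca_force(d, d, eps), 24 * eps / d, tolerance = 1e-9)
  # force = -dU/ds by central differences inside the cutoff
  U <- function(s) 4 * eps * ((d / s)^12 - (d / s)^6) + eps
  for (s in c(0.024, 0.026, 0.0278)) {
    expect_equal(wca_force(s, d, eps), -(U(s + 1e-9) - U(s - 1e-9)) / 2e-9,
                 tolerance = 1e-4)
  }
  # Hooke arithmetic: 10 nm extension at 0.3 pN/nm is 3 pN
  cfg <- filament_config(bundles = c("2" = 1), seed = 1)
  expect_equal(cfg$kappa * (0.09 - cfg$d0), 3, tolerance = 1e-9)
})

test_that("pair interactions are momentum free and torque free", {
  set.seed(31)
  cfg <- filament_config(bundles = c("2" = 2), box = c(6, 6), seed = 31)
  for (k in 1:20) {
    n <- 4L
    state <- list(r = cbind(runif(n, 2, 4), runif(n, 2, 4)),
                  theta = runif(n, -pi, pi))
    topo <- data.frame(i = c(1L, 3L), j = c(2L, 4L),
                       eps_i = runif(2, -0.45, 0.45),
                       eps_j = runif(2, -0.45, 0.45))
    inter <- logdiffuse:::pair_interactions(state, topo, cfg)
    if (!nrow(inter)) next
    for (b in seq_len(nrow(inter))) {
      f <- c(inter$fx[b], inter$fy[b])
      # equal and opposite forces by construction; torque about the contact
      # line vanishes because the force acts along the separation of the
      # application points
      i <- inter$i[b]; j <- inter$j[b]
      pi_ <- state$r[i, ] + inter$lam_i[b] *
        c(cos(state$theta[i]), sin(state$theta[i]))
      pj_ <- state$r[j, ] + inter$lam_j[b] *
        c(cos(state$theta[j]), sin(state$theta[j]))
      lever <- pi_ - pj_
      tq_pair <- lever[1] * f[2] - lever[2] * f[1]
      expect_equal(tq_pair, 0, tolerance = 1e-9 * (1 + sqrt(sum(f^2))))
    }
    fr <- logdiffuse:::filament_forces(state, topo, cfg)
    expect_equal(colSums(fr$F), c(0, 0), tolerance = 1e-9)
  }
})

test_that("a stretched bonded dimer relaxes monotonically to the rest length", {
  cfg <- filament_config(bundles = c("2" = 1), dt_s = 1e-5, seed = 3)
  sys <- build_filament_system(cfg)
  st <- sys$state
  st$r[2, ] <- st$r[2, ] + 0.05
  drag <- drag_coefficients(cfg$L, cfg$d, cfg$zeta, cfg$temperature)
  bond_len <- function(st) {
    pi_ <- st$r[1, ] + sys$topology$eps_i[1] *
      c(cos(st$theta[1]), sin(st$theta[1]))
    pj_ <- st$r[2, ] + sys$topology$eps_j[1] *
      c(cos(st$theta[2]), sin(st$theta[2]))
    sqrt(sum((pj_ - pi_)^2))
  }
  lens <- numeric(500)
  for (k in 1:500) {
    st <- logdiffuse:::bd_step(st, sys$topology, cfg, drag, noise = FALSE)
    lens[k] <- bond_len(st)
  }
  expect_true(all(diff(lens) <= 1e-9))
  expect_equal(lens[500], cfg$d0, tolerance = 0.05)

  # sign check: a single stretched bond along x pulls the filaments together
  st2 <- list(r = rbind(c(3, 3), c(3.5, 3)), theta = c(pi / 2, pi / 2))
  topo2 <- data.frame(i = 1L, j = 2L, eps_i = 0, eps_j = 0)
  st3 <- logdiffuse:::bd_step(st2, topo2, cfg, drag, noise = FALSE)
  expect_gt(st3$r[1, 1], st2$r[1, 1])
  expect_lt(st3$r[2, 1], st2$r[2, 1])
})

test_that("free filament obeys fluctuation-dissipation in the body frame", {
  cfg <- filament_config(bundles = c("1" = 1), dt_s = 1e-4, n_steps = 4e4,
                         output_stride = 1, seed = 6)
  tr <- simulate_free_filament(cfg)
  dc <- drag_coefficients(cfg$L, cfg$d, cfg$zeta, cfg$temperature)
  # angular increments: variance 2 D_r dt within 3 SE
  dth <- angular_displacements(tr, mode = "full")$d[, 1]
  v <- var(dth)
  target <- 2 * dc$D_rot * cfg$dt
  expect_lt(abs(v - target), 3 * target * sqrt(2 / length(dth)))
  # body-frame translational increments: diag(2 D_axis dt, 2 D_trans dt);
  # under the printed friction convention the axis carries D_perp
  d <- diff(tr$pos)
  u <- cbind(cos(tr$angle), sin(tr$angle))[-length(tr$angle), ]
  da <- rowSums(d * u)
  dtr <- -d[, 1] * u[, 2] + d[, 2] * u[, 1]
  t_axis <- 2 * dc$D_perp * cfg$dt
  t_trans <- 2 * dc$D_par * cfg$dt
  nn <- length(da)
  expect_lt(abs(var(da) - t_axis), 3 * t_axis * sqrt(2 / nn))
  expect_lt(abs(var(dtr) - t_trans), 3 * t_trans * sqrt(2 / nn))
  expect_lt(abs(mean(da * dtr)), 3 * sqrt(t_axis * t_trans) / sqrt(nn))
  # long-run center-of-mass diffusion matches (D_par + D_perp)/2
  el <- diffusion_elements(displacements(tr, stride = 2000))
  se <- dc$D_com / sqrt(length(el$S))
  expect_lt(abs(mean(el$S) - dc$D_com), 3.5 * se)
})

test_that("stepping is seed-reproducible and translation invariant", {
  cfg <- filament_config(bundles = c("2" = 1, "1" = 2), box = c(8, 8),
                         dt_s = 1e-4, n_steps = 50, output_stride = 10,
                         seed = 11)
  a <- run_filament_sim(cfg)
  b <- run_filament_sim(cfg)
  expect_identical(lapply(a, `[[`, "pos"), lapply(b, `[[`, "pos"))

  # rigid translation by one box length leaves forces unchanged
  sys <- build_filament_system(cfg)
  fr1 <- logdiffuse:::filament_forces(sys$state, sys$topology, cfg)
  shifted <- sys$state
  shifted$r <- shifted$r + cfg$box[1]
  fr2 <- logdiffuse:::filament_forces(shifted, sys$topology, cfg)
  expect_equal(fr1$F, fr2$F, tolerance = 1e-9)
  expect_equal(fr1$Tq, fr2$Tq, tolerance = 1e-9)
})

test_that("system building honors composition, bonds and rest lengths", {
  cfg <- filament_config(bundles = c("1" = 6), box = c(10, 10), seed = 2)
  sys <- build_filament_system(cfg)
  expect_identical(nrow(sys$state$r), 6L)
  expect_identical(nrow(sys$topology), 0L)

  cfg2 <- filament_config(bundles = c("3" = 2, "1" = 4), box = c(12, 12),
                          seed = 5, n_cross = 2L)
  sys2 <- build_filament_system(cfg2)
  expect_identical(nrow(sys2$state$r), 10L)
  # adjacent pairs within each 3-bundle, n_cross bonds each
  expect_identical(nrow(sys2$topology), 2L * 2L * 2L)
  # connected components of the bond graph: 2 bundles + 4 singles
  edges <- unique(sys2$topology[, c("i", "j")])
  comp <- seq_len(10L)
  for (b in seq_len(nrow(edges))) {
    ci <- comp[edges$i[b]]; cj <- comp[edges$j[b]]
    comp[comp == cj] <- ci
  }
  expect_identical(length(unique(comp)), 6L)
  # initial bond lengths start unstressed over many seeds
  for (s in 1:25) {
    cfg3 <- filament_config(bundles = c("4" = 1), box = c(8, 8), seed = s)
    sys3 <- build_filament_system(cfg3)
    inter <- logdiffuse:::pair_interactions(sys3$state, sys3$topology, cfg3)
    bonds <- inter[seq(nrow(inter) - nrow(sys3$topology) + 1, nrow(inter)), ]
    # bond force magnitudes correspond to lengths within [0, 2 d0]
    fmax <- cfg3$kappa * cfg3$d0
    expect_true(all(sqrt(bonds$fx^2 + bonds$fy^2) <= fmax + 1e-9))
  }
  expect_error(
    build_filament_system(filament_config(bundles = c("30" = 40),
                                          box = c(7, 7), seed = 1)),
    "larger box")
})
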