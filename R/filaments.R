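# Brownian dynamics of permanently cross-linked rigid filaments in a 2D
# periodic box: anisotropic drag, WCA sterics along the line of closest
# approach, harmonic tethers at fixed arc-length sites, forward Euler.
# Units: pN, um, s; 1 Pa s = 1 pN s/um^2.

#' Anisotropic drag and diffusion coefficients of a rigid rod
#'
#' Slender-body drag of a rod of length `L` and diameter `d` in a solvent
#' of viscosity `zeta`:
#' \deqn{\gamma_\parallel = \frac{2\pi\zeta L}{\ln(L/d)},\quad
#'       \gamma_\perp = \frac{4\pi\zeta L}{\ln(L/d)},\quad
#'       \gamma_r = \frac{\pi\zeta L^3}{3\ln(L/d)},}
#' with diffusion coefficients \eqn{D_x = k_B T / \gamma_x} and the 2D
#' center-of-mass coefficient \eqn{D = (D_\parallel + D_\perp)/2}. For
#' L = 1 um, d = 25 nm, zeta = 1 Pa s, T = 300 K this gives
#' D = 1.8e-3 um^2/s; direct evaluation of the rotational coefficient
#' gives D_r = 1.46e-2 rad^2/s (a slightly smaller value, 0.0135, is
#' sometimes quoted for the same parameters; the discrepancy is documented
#' rather than resolved here).
#'
#' @param L filament length, um.
#' @param d filament diameter, um (must be below `L`).
#' @param zeta solvent viscosity, Pa s (numerically equal to pN s/um^2).
#' @param temperature absolute temperature, K.
#' @return a list with `gamma_par`, `gamma_perp`, `gamma_rot` (pN s/um,
#'   pN s um for rotation), `D_par`, `D_perp`, `D_rot`, `D_com`.
#' @export
drag_coefficients <- function(L = 1, d = 0.025, zeta = 1, temperature = 300) {
  if (L <= d) stop("length must exceed diameter")
  if (d <= 0) stop("diameter must be positive")
  lg <- log(L / d)
  g_par <- 2 * pi * zeta * L / lg
  g_perp <- 4 * pi * zeta * L / lg
  g_rot <- pi * zeta * L^3 / (3 * lg)
  kt <- kBT(temperature)
  list(gamma_par = g_par, gamma_perp = g_perp, gamma_rot = g_rot,
       D_par = kt / g_par, D_perp = kt / g_perp, D_rot = kt / g_rot,
       D_com = (kt / g_par + kt / g_perp) / 2)
}

#' Minimum distance between two filament segments
#'
#' Closest approach between segments defined by center, orientation angle
#' and length, with the minimum-image convention applied to the center
#' separation when a periodic `box` is given. Line parameters are clamped
#' to the physical segments.
#'
#' @param r1,r2 segment centers (length-2 vectors, um).
#' @param th1,th2 orientation angles, radians.
#' @param L1,L2 segment lengths, um.
#' @param box optional periodic box lengths, um.
#' @return a list with `dist` (um), `lambda1`, `lambda2` (arc-length
#'   parameters of the closest points, in `[-L/2, L/2]`), `dir` (unit
#'   vector from the point on segment 2 towards the point on segment 1;
#'   zero when `dist` is 0), and `p1`, `p2` (closest points, with `p2`
#'   expressed in the minimum image relative to `r1`).
#' @export
segment_min_distance <- function(r1, th1, L1, r2, th2, L2, box = NULL) {
  u1 <- c(cos(th1), sin(th1))
  u2 <- c(cos(th2), sin(th2))
  d12 <- r2 - r1
  if (!is.null(box)) d12 <- d12 - box * floor(d12 / box + 0.5)
  # closest points between P(s) = r1 + s u1 and Q(t) = r1 + d12 + t u2
  b <- sum(u1 * u2)
  dd <- -sum(u1 * d12)
  e <- -sum(u2 * d12)
  den <- 1 - b^2
  h1 <- L1 / 2; h2 <- L2 / 2
  if (den > 1e-12) {
    s <- (b * e - dd) / den
  } else {
    s <- 0
  }
  s <- min(max(s, -h1), h1)
  t <- e + b * s
  t <- min(max(t, -h2), h2)
  s <- b * t - dd
  s <- min(max(s, -h1), h1)
  t2 <- e + b * s
  t2 <- min(max(t2, -h2), h2)
  p1 <- s * u1
  p2 <- d12 + t2 * u2
  sep <- p1 - p2
  dist <- sqrt(sum(sep^2))
  dir <- if (dist > 0) sep / dist else c(0, 0)
  list(dist = dist, lambda1 = s, lambda2 = t2, dir = dir,
       p1 = r1 + p1, p2 = r1 + p2)
}

#' Weeks-Chandler-Andersen repulsive force magnitude
#'
#' Force from the truncated-shifted Lennard-Jones potential
#' \eqn{U(s) = 4\epsilon[(d/s)^{12} - (d/s)^6] + \epsilon} for
#' \eqn{s < 2^{1/6} d}, zero beyond the cutoff. Separations below
#' `0.5 d` are evaluated at that floor (capped force, ~6.5e4 pN for the
#' default filament): deep transient overlaps then produce a strong finite
#' repulsion instead of forces so large that they swamp double-precision
#' force accumulation for every other interaction.
#'
#' @param s separation(s), um.
#' @param d Lennard-Jones distance (filament diameter), um.
#' @param eps energy scale, pN um (1 kBT in the filament model).
#' @return force magnitude(s), pN (positive = repulsive).
#' @export
wca_force <- function(s, d, eps = kBT(300)) {
  s <- pmax(s, 0.5 * d)
  cutoff <- 2^(1 / 6) * d
  r6 <- (d / s)^6
  ifelse(s < cutoff, 24 * eps / s * (2 * r6^2 - r6), 0)
}

#' Configuration for a filament-bundle simulation
#'
#' Physical parameters follow the reference system: L = 1 um rods of
#' diameter 25 nm in a 1 Pa s solvent at 300 K, cross-linked by springs of
#' stiffness 0.3 pN/nm and rest length 80 nm (values representative of a
#' kinesin-5 tether). The friction tensor assignment is switchable: the
#' `"printed"` convention pairs the perpendicular coefficient with the
#' filament axis (a transposed variant seen in print), `"conventional"`
#' pairs the parallel coefficient with the axis; the free center-of-mass
#' coefficient (D_par + D_perp)/2 is identical under both.
#'
#' @param box periodic box lengths, um (length 1 or 2).
#' @param bundles named integer vector: names are bundle sizes, values are
#'   bundle counts, e.g. `c("1" = 60, "30" = 2)`.
#' @param L,d filament length and diameter, um.
#' @param zeta viscosity, Pa s.
#' @param temperature kelvin.
#' @param kappa_pN_per_nm cross-link stiffness, pN/nm.
#' @param d0_nm cross-link rest length, nm.
#' @param dt_s integration time step, s.
#' @param n_steps number of integration steps.
#' @param output_stride record every this many steps.
#' @param seed RNG seed.
#' @param n_cross cross-link bonds per linked filament pair.
#' @param friction `"printed"` or `"conventional"`.
#' @return an object of class `"filament_config"`.
#' @export
filament_config <- function(box = c(30, 30), bundles = c("1" = 20), L = 1,
                            d = 0.025, zeta = 1, temperature = 300,
                            kappa_pN_per_nm = 0.3, d0_nm = 80, dt_s = 1e-4,
                            n_steps = 1000L, output_stride = 10L, seed = 1L,
                            n_cross = 2L,
                            friction = c("printed", "conventional")) {
  friction <- match.arg(friction)
  if (length(box) == 1L) box <- rep(box, 2L)
  if (dt_s <= 0) stop("time step must be positive")
  if (any(box <= 2 * L)) stop("box must exceed twice the filament length")
  sizes <- as.integer(names(bundles))
  if (any(is.na(sizes)) || any(sizes < 1L)) {
    stop("bundle sizes (names of `bundles`) must be positive integers")
  }
  structure(list(box = box, bundles = bundles, L = L, d = d, zeta = zeta,
                 temperature = temperature,
                 kappa = kappa_pN_per_nm * 1000,   # pN/um
                 d0 = d0_nm / 1000,                # um
                 dt = dt_s, n_steps = as.integer(n_steps),
                 output_stride = as.integer(output_stride),
                 seed = as.integer(seed), n_cross = as.integer(n_cross),
                 friction = friction),
            class = "filament_config")
}

#' Build the initial filament system
#'
#' Places each bundle as a stack of near-parallel filaments laterally
#' spaced by the cross-link rest length, at non-overlapping random
#' locations in the box; all cross-link bonds are formed as an initial
#' condition between adjacent filaments in a bundle, at random arc-length
#' sites (the same site parameter on both partners, so initial bond
#' lengths start at the rest length), and are never created or destroyed
#' afterwards.
#'
#' @param config a [filament_config()].
#' @return a list with `state` (list of `r`, an N x 2 matrix of centers,
#'   and `theta`), `topology` (data.frame of bonds: `i`, `j`, `eps_i`,
#'   `eps_j`), and `bundle_id` per filament.
#' @export
build_filament_system <- function(config) {
  set.seed(config$seed)
  sizes <- rep(as.integer(names(config$bundles)), config$bundles)
  n_fil <- sum(sizes)
  r <- matrix(NA_real_, n_fil, 2L)
  theta <- numeric(n_fil)
  bundle_id <- integer(n_fil)
  placed_c <- matrix(numeric(0), 0L, 2L)
  placed_rad <- numeric(0)
  bonds <- list()
  idx <- 0L
  for (bi in seq_along(sizes)) {
    m <- sizes[bi]
    rad <- sqrt((config$L / 2)^2 + (m * config$d0 / 2)^2) + config$d
    ok <- FALSE
    for (try in seq_len(500L)) {
      cen <- stats::runif(2L) * config$box
      if (nrow(placed_c) == 0L) { ok <- TRUE; break }
      dd <- sweep(placed_c, 2L, cen)
      dd <- dd - sweep(floor(sweep(dd, 2L, config$box, "/") + 0.5), 2L,
                       config$box, "*")
      if (all(sqrt(rowSums(dd^2)) > placed_rad + rad)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place bundles without overlap; use a larger box")
    placed_c <- rbind(placed_c, cen)
    placed_rad <- c(placed_rad, rad)
    th0 <- stats::runif(1L, -pi, pi)
    perp <- c(-sin(th0), cos(th0))
    members <- idx + seq_len(m)
    for (k in seq_len(m)) {
      off <- (k - (m + 1) / 2) * config$d0
      r[members[k], ] <- cen + off * perp
      theta[members[k]] <- wrap_angle(th0 + stats::rnorm(1L, 0, 0.01))
      bundle_id[members[k]] <- bi
    }
    if (m > 1L) {
      for (k in seq_len(m - 1L)) {
        eps <- stats::runif(config$n_cross, -0.9, 0.9) * config$L / 2
        bonds[[length(bonds) + 1L]] <-
          data.frame(i = members[k], j = members[k + 1L],
                     eps_i = eps, eps_j = eps)
      }
    }
    idx <- idx + m
  }
  r <- r %% matrix(config$box, n_fil, 2L, byrow = TRUE)
  topology <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(), j = integer(), eps_i = numeric(),
               eps_j = numeric())
  list(state = list(r = r, theta = theta), topology = topology,
       bundle_id = bundle_id)
}

# all pairwise interactions (steric + bond) as a table of equal-and-opposite
# forces with their application points; exact O(N^2) candidate pruning by
# minimum-image center distance. Matrix columns: i, j, fx, fy, lam_i,
# lam_j, capped.
pair_interactions_mat <- function(state, topology, config) {
  n <- nrow(state$r)
  eps_en <- kBT(config$temperature)
  cutoff <- 2^(1 / 6) * config$d
  out <- list()
  if (n > 1L) {
    cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dx <- state$r[cand[, 2L], 1L] - state$r[cand[, 1L], 1L]
    dy <- state$r[cand[, 2L], 2L] - state$r[cand[, 1L], 2L]
    dx <- dx - config$box[1L] * floor(dx / config$box[1L] + 0.5)
    dy <- dy - config$box[2L] * floor(dy / config$box[2L] + 0.5)
    near <- which(dx^2 + dy^2 < (config$L + cutoff)^2)
    for (p in near) {
      i <- cand[p, 1L]; j <- cand[p, 2L]
      g <- segment_min_distance(state$r[i, ], state$theta[i], config$L,
                                state$r[j, ], state$theta[j], config$L,
                                box = config$box)
      if (g$dist >= cutoff) next
      dir <- g$dir
      if (all(dir == 0)) {
        # zero-distance crossing: push perpendicular to filament i
        dir <- c(-sin(state$theta[i]), cos(state$theta[i]))
      }
      fmag <- wca_force(g$dist, config$d, eps_en)
      out[[length(out) + 1L]] <- c(i, j, fmag * dir, g$lambda1, g$lambda2,
                                   capped = g$dist < 0.5 * config$d)
    }
  }
  if (nrow(topology)) {
    ui <- cbind(cos(state$theta[topology$i]), sin(state$theta[topology$i]))
    uj <- cbind(cos(state$theta[topology$j]), sin(state$theta[topology$j]))
    pi_ <- state$r[topology$i, , drop = FALSE] + topology$eps_i * ui
    pj_ <- state$r[topology$j, , drop = FALSE] + topology$eps_j * uj
    sep <- pj_ - pi_
    sep <- sep - sweep(floor(sweep(sep, 2L, config$box, "/") + 0.5), 2L,
                       config$box, "*")
    dij <- sqrt(rowSums(sep^2))
    for (b in seq_len(nrow(topology))) {
      if (dij[b] == 0) next  # undefined direction: zero force, logged
      fmag <- config$kappa * (dij[b] - config$d0)
      # force on i pulls towards j when stretched
      out[[length(out) + 1L]] <- c(topology$i[b], topology$j[b],
                                   fmag * sep[b, ] / dij[b],
                                   topology$eps_i[b], topology$eps_j[b],
                                   capped = FALSE)
    }
  }
  if (!length(out)) return(matrix(numeric(0), 0L, 7L))
  do.call(rbind, out)
}

# readable view of the interaction table
pair_interactions <- function(state, topology, config) {
  m <- pair_interactions_mat(state, topology, config)
  data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]),
             fx = m[, 3L], fy = m[, 4L], lam_i = m[, 5L], lam_j = m[, 6L],
             capped = as.logical(m[, 7L]))
}

# net force (N x 2) and torque (N) from the interaction table
filament_forces <- function(state, topology, config) {
  n <- nrow(state$r)
  m <- pair_interactions_mat(state, topology, config)
  F <- matrix(0, n, 2L)
  Tq <- numeric(n)
  for (b in seq_len(nrow(m))) {
    i <- m[b, 1L]; j <- m[b, 2L]
    fx <- m[b, 3L]; fy <- m[b, 4L]
    F[i, 1L] <- F[i, 1L] + fx; F[i, 2L] <- F[i, 2L] + fy
    F[j, 1L] <- F[j, 1L] - fx; F[j, 2L] <- F[j, 2L] - fy
    # torque = lever (lambda u) x force, 2D scalar cross product
    Tq[i] <- Tq[i] + m[b, 5L] * (cos(state$theta[i]) * fy -
                                   sin(state$theta[i]) * fx)
    Tq[j] <- Tq[j] - m[b, 6L] * (cos(state$theta[j]) * fy -
                                   sin(state$theta[j]) * fx)
  }
  list(F = F, Tq = Tq, n_capped = sum(m[, 7L]))
}

# one forward-Euler step; noise optional (fluctuation-dissipation with the
# selected friction convention)
bd_step <- function(state, topology, config, drag, noise = TRUE) {
  fr <- filament_forces(state, topology, config)
  kt <- kBT(config$temperature)
  if (config$friction == "printed") {
    g_axis <- drag$gamma_perp; g_trans <- drag$gamma_par
  } else {
    g_axis <- drag$gamma_par; g_trans <- drag$gamma_perp
  }
  n <- nrow(state$r)
  ux <- cos(state$theta); uy <- sin(state$theta)
  f_axis <- fr$F[, 1L] * ux + fr$F[, 2L] * uy
  f_trans <- -fr$F[, 1L] * uy + fr$F[, 2L] * ux
  da <- f_axis / g_axis * config$dt
  dtr <- f_trans / g_trans * config$dt
  dth <- fr$Tq / drag$gamma_rot * config$dt
  if (noise) {
    da <- da + sqrt(2 * kt / g_axis * config$dt) * stats::rnorm(n)
    dtr <- dtr + sqrt(2 * kt / g_trans * config$dt) * stats::rnorm(n)
    dth <- dth + sqrt(2 * kt / drag$gamma_rot * config$dt) * stats::rnorm(n)
  }
  dr <- cbind(da * ux - dtr * uy, da * uy + dtr * ux)
  if (any(!is.finite(dr)) || any(!is.finite(dth))) {
    stop("non-finite state update; system diverged (inspect forces/overlaps)")
  }
  state$r <- (state$r + dr) %% matrix(config$box, n, 2L, byrow = TRUE)
  state$theta <- wrap_angle(state$theta + dth)
  state$dr <- dr
  state$dtheta <- dth
  state
}

#' Run a filament-bundle Brownian-dynamics simulation
#'
#' Integrates the over-damped equations of motion (anisotropic drag, WCA
#' sterics, harmonic cross-links, forward Euler) and records
#' center-of-mass positions and orientation angles at the output stride.
#' Recorded positions are unwrapped (cumulative displacements), so MSDs
#' and displacement statistics can be computed without box artifacts.
#'
#' @param config a [filament_config()].
#' @return a [traj_set()] (one oriented trajectory per filament) with
#'   attributes `bundle_id`, `provenance` (config, seed, package version)
#'   and `n_capped` (count of capped steric overlaps).
#' @export
run_filament_sim <- function(config) {
  stopifnot(inherits(config, "filament_config"))
  sys <- build_filament_system(config)
  state <- sys$state
  drag <- drag_coefficients(config$L, config$d, config$zeta,
                            config$temperature)
  n <- nrow(state$r)
  n_rec <- config$n_steps %/% config$output_stride + 1L
  pos <- array(NA_real_, c(n_rec, n, 2L))
  ang <- matrix(NA_real_, n_rec, n)
  unwrapped <- state$r
  pos[1L, , ] <- unwrapped
  ang[1L, ] <- state$theta
  n_capped <- 0L
  rec <- 1L
  for (s in seq_len(config$n_steps)) {
    state <- bd_step(state, sys$topology, config, drag)
    unwrapped <- unwrapped + state$dr
    if (s %% config$output_stride == 0L) {
      rec <- rec + 1L
      pos[rec, , ] <- unwrapped
      ang[rec, ] <- state$theta
    }
  }
  times <- (seq_len(n_rec) - 1L) * config$dt * config$output_stride
  trajs <- lapply(seq_len(n), function(i) {
    trajectory(sprintf("fil%03d", i), times, pos[, i, ], angle = ang[, i])
  })
  out <- traj_set(trajs)
  attr(out, "bundle_id") <- sys$bundle_id
  attr(out, "provenance") <- list(
    config = unclass(config), seed = config$seed,
    version = as.character(utils::packageVersion("logdiffuse")))
  out
}

#' Fast exact sampler for a single free filament
#'
#' A filament with no interactions has exactly Gaussian body-frame
#' increments, so its trajectory can be sampled directly without the force
#' loop: the orientation performs free rotational diffusion and each
#' translational step has variance \eqn{2 D_a dt} along the instantaneous
#' axis and \eqn{2 D_t dt} transverse to it.
#'
#' @param config a [filament_config()]; only the physical parameters,
#'   `dt_s`, `n_steps`, `output_stride`, `friction` and `seed` are used.
#' @return a [trajectory()] with orientation angle.
#' @export
simulate_free_filament <- function(config) {
  stopifnot(inherits(config, "filament_config"))
  set.seed(config$seed)
  drag <- drag_coefficients(config$L, config$d, config$zeta,
                            config$temperature)
  kt <- kBT(config$temperature)
  if (config$friction == "printed") {
    D_axis <- kt / drag$gamma_perp; D_trans <- kt / drag$gamma_par
  } else {
    D_axis <- kt / drag$gamma_par; D_trans <- kt / drag$gamma_perp
  }
  ns <- config$n_steps
  th <- cumsum(c(stats::runif(1L, -pi, pi),
                 stats::rnorm(ns, 0, sqrt(2 * drag$D_rot * config$dt))))
  ux <- cos(th[-(ns + 1L)]); uy <- sin(th[-(ns + 1L)])
  da <- stats::rnorm(ns, 0, sqrt(2 * D_axis * config$dt))
  dtr <- stats::rnorm(ns, 0, sqrt(2 * D_trans * config$dt))
  x <- cumsum(c(0, da * ux - dtr * uy))
  y <- cumsum(c(0, da * uy + dtr * ux))
  keep <- seq(1L, ns + 1L, by = config$output_stride)
  trajectory("fil001", (keep - 1L) * config$dt, cbind(x[keep], y[keep]),
             angle = wrap_angle(th[keep]))
}
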