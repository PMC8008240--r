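# Ideal multimodal Brownian trajectory generator: the reference engine for
# all statistical validation.

#' Specification of an ideal Brownian mixture
#'
#' Describes a population of ideal Brownian walkers mixing several
#' diffusive modes. Each track is assigned one mode for its whole lifetime
#' (population mixture, no state switching); steps are IID zero-mean
#' Gaussian per axis with variance \eqn{2 D_k \Delta t}. Rotational tracks
#' accumulate a 1D angle wrapped into (-pi, pi].
#'
#' @param D mode diffusion coefficients (um^2/s, or rad^2/s for
#'   rotational).
#' @param alpha mode weights (sum to 1); default equal.
#' @param n_d spatial dimensionality of translational tracks.
#' @param dt frame interval, s.
#' @param n_steps steps per track (frames = n_steps + 1).
#' @param n_tracks number of tracks.
#' @param kind `"translational"` or `"rotational"`.
#' @param box optional periodic box lengths; positions are wrapped into
#'   `[0, box)` (displacement extraction then needs the same `box`).
#' @param seed master seed; per-track streams are derived from it so that
#'   changing the track count does not reshuffle earlier tracks.
#' @return an object of class `"mixture_spec"`.
#' @export
mixture_spec <- function(D, alpha = NULL, n_d = 2L, dt, n_steps, n_tracks,
                         kind = c("translational", "rotational"),
                         box = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(alpha)) alpha <- rep(1 / length(D), length(D))
  stopifnot(length(D) == length(alpha), all(D > 0), all(alpha > 0),
            abs(sum(alpha) - 1) < 1e-8, n_steps >= 1L, n_tracks >= 1L,
            dt > 0)
  if (kind == "rotational") {
    n_d <- 1L
    if (any(sqrt(2 * D * dt) > pi / 6)) {
      warning("per-step angular SD exceeds pi/6; wrapping will bias ",
              "angular displacements - reduce dt")
    }
  }
  structure(list(D = D, alpha = alpha, n_d = as.integer(n_d), dt = dt,
                 n_steps = as.integer(n_steps),
                 n_tracks = as.integer(n_tracks), kind = kind, box = box,
                 seed = seed),
            class = "mixture_spec")
}

# deterministic per-track substream seed below 2^31: two rounds of a
# Lehmer generator (a = 48271, m = 2^31 - 1; products stay exact in
# doubles) so that derived streams do not collide under index shifts
track_seed <- function(master, i) {
  m <- 2147483647
  x <- (as.numeric(master) %% (m - 1)) + 1
  x <- (48271 * x) %% m
  x <- (x + as.numeric(i)) %% m
  x <- (48271 * x) %% m
  if (x == 0) 1 else x
}

#' Generate ideal multimodal Brownian trajectories
#'
#' @param spec a [mixture_spec()].
#' @return a [traj_set()]; the ground-truth mode index of each track is
#'   attached as `attr(, "modes")` (metadata alongside, never inside, the
#'   trajectory data).
#' @export
simulate_ideal <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  seed <- if (is.null(spec$seed)) sample.int(2^31 - 1L, 1L) else spec$seed
  nfr <- spec$n_steps + 1L
  times <- (seq_len(nfr) - 1L) * spec$dt
  cum <- cumsum(spec$alpha)
  modes <- integer(spec$n_tracks)
  trajs <- vector("list", spec$n_tracks)
  for (i in seq_len(spec$n_tracks)) {
    set.seed(track_seed(seed, i))
    mode <- findInterval(stats::runif(1), cum) + 1L
    modes[i] <- mode
    sdk <- sqrt(2 * spec$D[mode] * spec$dt)
    if (spec$kind == "rotational") {
      ang <- wrap_angle(cumsum(c(stats::runif(1, -pi, pi),
                                 stats::rnorm(spec$n_steps, 0, sdk))))
      trajs[[i]] <- trajectory(sprintf("track%04d", i), times,
                               matrix(0, nfr, 1L), angle = ang)
    } else {
      steps <- matrix(stats::rnorm(spec$n_steps * spec$n_d, 0, sdk),
                      spec$n_steps, spec$n_d)
      pos <- apply(rbind(0, steps), 2L, cumsum)
      if (!is.null(spec$box)) {
        box <- if (length(spec$box) == 1L) rep(spec$box, spec$n_d) else spec$box
        pos <- pos %% matrix(box, nfr, spec$n_d, byrow = TRUE)
      }
      trajs[[i]] <- trajectory(sprintf("track%04d", i), times, pos)
    }
  }
  out <- traj_set(trajs)
  attr(out, "modes") <- modes
  attr(out, "seed") <- seed
  out
}
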