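# Trajectory container, canonical CSV I/O, and displacement extraction.

#' Single-particle trajectory
#'
#' A time-ordered series of positions (and optionally an orientation angle)
#' for one tracked particle, sampled at a uniform frame interval.
#'
#' @param particle_id identifier for the particle.
#' @param times frame times in seconds; must be strictly increasing with
#'   constant spacing (1e-9 relative tolerance).
#' @param pos numeric matrix of positions, one row per frame, 1-3 columns
#'   (um). A vector is taken as a single spatial component.
#' @param angle optional orientation angle per frame, radians; wrapped into
#'   (-pi, pi].
#' @return an object of class `"trajectory"` with fields `particle_id`,
#'   `times`, `pos`, `angle`, `dt` (frame interval, s) and `n_d`.
#' @export
trajectory <- function(particle_id, times, pos, angle = NULL) {
  if (is.vector(pos)) pos <- matrix(pos, ncol = 1L)
  pos <- as.matrix(pos)
  n <- length(times)
  if (n < 2L) stop("a trajectory needs at least 2 frames")
  if (nrow(pos) != n) stop("times and positions disagree in length")
  dts <- diff(times)
  if (any(dts <= 0)) {
    stop(sprintf("times of particle '%s' are not strictly increasing",
                 particle_id))
  }
  dt <- dts[1L]
  if (any(abs(dts - dt) > 1e-9 * dt)) {
    stop(sprintf("non-uniform spacing: particle '%s' has unequal frame intervals",
                 particle_id))
  }
  if (!is.null(angle)) {
    if (length(angle) != n) stop("angle and times disagree in length")
    angle <- wrap_angle(angle)
  }
  structure(list(particle_id = particle_id, times = as.numeric(times),
                 pos = pos, angle = angle, dt = dt, n_d = ncol(pos)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames, dt = %g s, %dD%s>\n",
              x$particle_id, length(x$times), x$dt, x$n_d,
              if (is.null(x$angle)) "" else ", with angle"))
  invisible(x)
}

#' Collection of trajectories
#'
#' @param x a list of [trajectory()] objects.
#' @return an object of class `"traj_set"`.
#' @export
traj_set <- function(x) {
  if (inherits(x, "trajectory")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "trajectory")))
  structure(x, class = "traj_set")
}

#' @export
print.traj_set <- function(x, ...) {
  nf <- vapply(x, function(tr) length(tr$times), integer(1))
  cat(sprintf("<traj_set: %d trajectories, %d frames total>\n",
              length(x), sum(nf)))
  invisible(x)
}

#' @export
`[.traj_set` <- function(x, i) traj_set(unclass(x)[i])

# wrap into (-pi, pi]; `period = pi` gives the nematic map into (-pi/2, pi/2]
wrap_angle <- function(a, period = 2 * pi) {
  h <- period / 2
  w <- (a + h) %% period - h
  w[w == -h] <- h
  w
}

#' Read trajectories from delimited text
#'
#' Reads a particle-tracking table (canonical dialect: comma-separated with
#' header `particle,frame,t,x,y[,theta]`; coordinates in um, time in s,
#' theta in radians). Third-party exports can be ingested by supplying a
#' column mapping.
#'
#' @param path file path.
#' @param mapping named character vector mapping canonical roles
#'   (`particle`, `frame`, `t`, `x`, `y`, `z`, `theta`) to column names in
#'   the file. Only roles present in the file need be mapped; at minimum an
#'   id, a time (or frame) and one coordinate must resolve.
#' @param sep field separator.
#' @return a [traj_set()], grouped by particle id and sorted by time. Frames
#'   with missing coordinates are dropped per particle with a message.
#' @export
read_trajectories <- function(path, mapping = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c(particle = "particle", frame = "frame", t = "t",
             x = "x", y = "y", z = "z", theta = "theta")
  if (!is.null(mapping)) canon[names(mapping)] <- mapping
  have <- canon[canon %in% names(df)]
  if (!"particle" %in% names(have)) stop("no particle id column mappable")
  coords <- intersect(c("x", "y", "z"), names(have))
  if (length(coords) == 0L) stop("no coordinate column mappable")
  if (!any(c("t", "frame") %in% names(have))) {
    stop("no time or frame column mappable")
  }

  num_cols <- setdiff(names(have), "particle")
  for (role in num_cols) {
    v <- df[[have[[role]]]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad)) {
      stop(sprintf("unparseable values in column '%s' at line(s) %s",
                   have[[role]], paste(bad + 1L, collapse = ", ")))
    }
    df[[have[[role]]]] <- vn
  }

  tcol <- if ("t" %in% names(have)) df[[have[["t"]]]] else df[[have[["frame"]]]]
  ids <- df[[have[["particle"]]]]
  out <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    sub <- df[idx, , drop = FALSE]
    tt <- tcol[idx]
    ord <- order(tt)
    sub <- sub[ord, , drop = FALSE]; tt <- tt[ord]
    pm <- sapply(coords, function(cc) sub[[have[[cc]]]])
    pm <- matrix(pm, ncol = length(coords))
    keep <- stats::complete.cases(pm) & !is.na(tt)
    if (!all(keep)) {
      message(sprintf("particle '%s': dropped %d frame(s) with missing coordinates",
                      ids[idx][1L], sum(!keep)))
    }
    ang <- if ("theta" %in% names(have)) sub[[have[["theta"]]]][keep] else NULL
    trajectory(ids[idx][1L], tt[keep], pm[keep, , drop = FALSE], ang)
  })
  traj_set(unname(out))
}

#' Write trajectories in the canonical CSV dialect
#'
#' @param trajs a [traj_set()] or single [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- traj_set(list(trajs))
  rows <- lapply(trajs, function(tr) {
    d <- data.frame(particle = tr$particle_id,
                    frame = seq_along(tr$times) - 1L,
                    t = tr$times)
    cn <- c("x", "y", "z")[seq_len(tr$n_d)]
    for (k in seq_len(tr$n_d)) d[[cn[k]]] <- tr$pos[, k]
    if (!is.null(tr$angle)) d$theta <- tr$angle
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-step displacements of a trajectory
#'
#' Extracts displacement vectors between frames separated by `stride`
#' frames. By default displacements are non-overlapping (independent
#' increments, matching the IID assumption behind the analytic log-domain
#' densities); set `overlapping = TRUE` for the sliding-window variant.
#'
#' @param x a [trajectory()] or [traj_set()].
#' @param stride positive integer; the effective sampling interval is
#'   `stride * dt`.
#' @param box optional periodic box lengths (um) per coordinate; each
#'   displacement component is minimum-image reduced into
#'   `[-L_box/2, L_box/2)`.
#' @param overlapping logical; use all start frames instead of
#'   non-overlapping blocks.
#' @param ... unused.
#' @return an object of class `"displacement_set"`: fields `d` (matrix, one
#'   displacement per row, um), `n_d`, `dt` (effective interval, s),
#'   `particle`, `step`, `kind = "translational"`.
#' @export
displacements <- function(x, stride = 1L, box = NULL, overlapping = FALSE, ...) {
  UseMethod("displacements")
}

#' @export
displacements.trajectory <- function(x, stride = 1L, box = NULL,
                                     overlapping = FALSE, ...) {
  stride <- as.integer(stride)
  nf <- length(x$times)
  if (stride < 1L) stop("stride must be >= 1")
  if (stride >= nf) stop("stride must be smaller than the number of frames")
  if (!is.null(box) && any(box <= 0)) stop("box lengths must be positive")
  starts <- if (overlapping) seq_len(nf - stride) else
    seq.int(1L, by = stride, length.out = (nf - 1L) %/% stride)
  d <- x$pos[starts + stride, , drop = FALSE] - x$pos[starts, , drop = FALSE]
  if (!is.null(box)) {
    if (length(box) == 1L) box <- rep(box, x$n_d)
    for (k in seq_len(x$n_d)) {
      d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
    }
  }
  structure(list(d = d, n_d = x$n_d, dt = stride * x$dt,
                 particle = rep(x$particle_id, length(starts)),
                 step = starts, kind = "translational"),
            class = "displacement_set")
}

#' @export
displacements.traj_set <- function(x, stride = 1L, box = NULL,
                                   overlapping = FALSE, ...) {
  parts <- lapply(x, displacements, stride = stride, box = box,
                  overlapping = overlapping)
  bind_displacement_sets(parts)
}

bind_displacement_sets <- function(parts) {
  dts <- vapply(parts, `[[`, numeric(1), "dt")
  if (max(dts) - min(dts) > 1e-9 * dts[1L]) {
    stop("trajectories have inconsistent frame intervals")
  }
  structure(list(d = do.call(rbind, lapply(parts, `[[`, "d")),
                 n_d = parts[[1L]]$n_d, dt = dts[1L],
                 particle = unlist(lapply(parts, `[[`, "particle")),
                 step = unlist(lapply(parts, `[[`, "step")),
                 kind = parts[[1L]]$kind,
                 n_flagged = sum(vapply(parts, function(p)
                   if (is.null(p$n_flagged)) 0L else p$n_flagged, integer(1)))),
            class = "displacement_set")
}

#' @export
print.displacement_set <- function(x, ...) {
  cat(sprintf("<displacement_set: %d %s displacements, n_d = %d, dt = %g s>\n",
              nrow(x$d), x$kind, x$n_d, x$dt))
  invisible(x)
}

#' Angular displacements of an oriented trajectory
#'
#' Wrapped frame-to-frame differences of the orientation angle. The default
#' `"nematic"` mode treats the particle as head-tail symmetric (apolar rod):
#' differences are mapped into `(-pi/2, pi/2]` (period pi). `"full"` mode
#' maps into `(-pi, pi]`. Entries with `|dtheta| > pi/2` are flagged; a
#' flagged fraction above `flag_threshold` aborts with advice to use a
#' smaller effective time interval, since wrapping then biases the
#' displacement statistics.
#'
#' @inheritParams displacements
#' @param mode `"nematic"` (period pi) or `"full"` (period 2 pi).
#' @param flag_threshold maximum tolerated fraction of flagged entries.
#' @return a `"displacement_set"` with `kind = "rotational"` and `n_d = 1`.
#' @export
angular_displacements <- function(x, stride = 1L, mode = c("nematic", "full"),
                                  overlapping = FALSE, flag_threshold = 0.01) {
  mode <- match.arg(mode)
  if (inherits(x, "traj_set")) {
    parts <- lapply(x, angular_displacements_one, stride = stride, mode = mode,
                    overlapping = overlapping)
    out <- bind_displacement_sets(parts)
  } else {
    out <- angular_displacements_one(x, stride, mode, overlapping)
  }
  frac <- out$n_flagged / nrow(out$d)
  if (frac > flag_threshold) {
    stop(sprintf(paste0("%.1f%% of angular displacements exceed pi/2; ",
                        "wrapping biases the statistics - use a smaller ",
                        "effective time interval (stride * dt)"), 100 * frac))
  }
  out
}

angular_displacements_one <- function(x, stride, mode, overlapping) {
  if (is.null(x$angle)) {
    stop(sprintf("particle '%s' has no orientation angle", x$particle_id))
  }
  stride <- as.integer(stride)
  nf <- length(x$times)
  if (stride < 1L) stop("stride must be >= 1")
  if (stride >= nf) stop("stride must be smaller than the number of frames")
  starts <- if (overlapping) seq_len(nf - stride) else
    seq.int(1L, by = stride, length.out = (nf - 1L) %/% stride)
  dth <- x$angle[starts + stride] - x$angle[starts]
  dth <- if (mode == "nematic") wrap_angle(dth, pi) else wrap_angle(dth)
  structure(list(d = matrix(dth, ncol = 1L), n_d = 1L, dt = stride * x$dt,
                 particle = rep(x$particle_id, length(starts)),
                 step = starts, kind = "rotational",
                 n_flagged = sum(abs(dth) > pi / 2)),
            class = "displacement_set")
}
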