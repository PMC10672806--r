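# isotropic unit vectors on the sphere
runit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# One draw from the von Mises-Fisher distribution on S^2 with mean direction
# mu and concentration kappa (exact inverse-CDF for the cosine in 3D).
rvmf1 <- function(mu, kappa) {
  if (kappa < 1e-8) return(drop(runit(1)))
  u <- stats::runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  # orthonormal basis completing mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  w * mu + s * (cos(phi) * e1 + sin(phi) * e2)
}

WALKER_MODELS <- c("ballistic", "brownian", "persistent", "confined",
                   "back_and_forth")

#' Specification of a synthetic 3D walker
#'
#' Defines one motility phenotype for the track generator. Step lengths are
#' speed times time step; per-step speeds are drawn from a normal
#' distribution truncated at zero (left-clipped), optionally around a
#' per-cell mean drawn from a population distribution (`cell_speed_sd`).
#' Direction models:
#' \describe{
#'   \item{ballistic}{a single fixed random direction and constant per-cell
#'     speed — straight tracks (meandering ratio 1, MSD slope 2).}
#'   \item{brownian}{i.i.d. isotropic directions each step — memoryless,
#'     turning-angle density proportional to sin(theta).}
#'   \item{persistent}{each heading is a von Mises-Fisher perturbation of
#'     the previous one with concentration `persistence` — superdiffusive,
#'     low turning angles.}
#'   \item{back_and_forth}{with probability `reversal_prob` the heading
#'     reverses (von Mises-Fisher about the negated previous heading,
#'     angular jitter `reversal_jitter_deg`), otherwise it persists with the
#'     same jitter — produces a turning-angle mode near 180 degrees.}
#'   \item{confined}{isotropic proposals rejected when they would take the
#'     cell beyond `tether_radius` of its starting point (the cell stays put
#'     after 100 failed proposals) — subdiffusive at matched duration.}
#' }
#' Observation times are `0, dt, 2*dt, ...` with optional Gaussian jitter of
#' sd `time_jitter_sd` seconds (kept strictly increasing).
#'
#' @param model one of `"ballistic"`, `"brownian"`, `"persistent"`,
#'   `"confined"`, `"back_and_forth"`.
#' @param speed_mean,speed_sd per-step speed distribution, um/min.
#' @param cell_speed_sd sd of the per-cell mean speed around `speed_mean`,
#'   um/min (0 = all cells share the mean).
#' @param persistence von Mises-Fisher concentration of the heading about
#'   the previous heading (persistent model).
#' @param reversal_prob probability of reversing at each step
#'   (back_and_forth model).
#' @param reversal_jitter_deg angular jitter around the (possibly reversed)
#'   heading, degrees (back_and_forth model).
#' @param tether_radius confinement radius, um (confined model).
#' @param dt sampling interval, seconds.
#' @param n_steps number of steps (track has `n_steps + 1` points).
#' @param time_jitter_sd sd of observation-time jitter, seconds.
#' @param seed optional integer; when set, [generate_track()] seeds the RNG
#'   itself so the track is reproducible in isolation.
#' @return object of class `walker_spec`.
#' @export
walker_spec <- function(model = "brownian", speed_mean = 6, speed_sd = 2,
                        cell_speed_sd = 0, persistence = 2,
                        reversal_prob = 0.8, reversal_jitter_deg = 20,
                        tether_radius = 10, dt = 90, n_steps = 15,
                        time_jitter_sd = 0, seed = NULL) {
  model <- match.arg(model, WALKER_MODELS)
  stopifnot(speed_mean > 0, speed_sd >= 0, cell_speed_sd >= 0,
            persistence >= 0, reversal_prob >= 0, reversal_prob <= 1,
            reversal_jitter_deg > 0, tether_radius > 0, dt > 0,
            n_steps >= 1, time_jitter_sd >= 0)
  structure(as.list(environment()), class = "walker_spec")
}

#' Generate one synthetic track
#'
#' Draws a single 3D walker trajectory under a [walker_spec()]. Uses the
#' current RNG stream unless the spec carries a `seed`. The walk starts at a
#' uniform random position in the central 200-um cube of the frame so tracks
#' look like absolute imaging coordinates.
#'
#' @param spec a `walker_spec`.
#' @param cell_id,frame_id,tissue identity strings for the output rows.
#' @return a single track in [tracks_split()] form (list with `cell_id`,
#'   `frame_id`, `tissue`, `t`, `pos`).
#' @export
generate_track <- function(spec, cell_id = "c1", frame_id = "f1",
                           tissue = "synthetic") {
  stopifnot(inherits(spec, "walker_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ns <- spec$n_steps
  mu_c <- max(stats::rnorm(1, spec$speed_mean, spec$cell_speed_sd), 0.1)
  speeds <- if (spec$model == "ballistic") {
    rep(mu_c, ns)
  } else {
    pmax(stats::rnorm(ns, mu_c, spec$speed_sd), 0)
  }

  t <- (0:ns) * spec$dt
  if (spec$time_jitter_sd > 0) {
    t[-1] <- t[-1] + stats::rnorm(ns, 0, spec$time_jitter_sd)
    t <- sort(t)
    # enforce strict increase on (vanishingly rare) collisions
    for (i in seq_len(ns)) {
      if (t[i + 1] <= t[i]) t[i + 1] <- t[i] + 1e-3
    }
  }
  steplen <- speeds * diff(t) / 60

  pos <- matrix(0, ns + 1, 3)
  pos[1, ] <- stats::runif(3, 100, 300)
  origin <- pos[1, ]
  jit_kappa <- 1 / (spec$reversal_jitter_deg * pi / 180)^2
  dir <- drop(runit(1))
  for (i in seq_len(ns)) {
    if (i > 1) {
      dir <- switch(spec$model,
        ballistic = dir,
        brownian = drop(runit(1)),
        persistent = rvmf1(dir, spec$persistence),
        back_and_forth = {
          mu <- if (stats::runif(1) < spec$reversal_prob) -dir else dir
          rvmf1(mu, jit_kappa)
        },
        confined = drop(runit(1)))
    }
    if (spec$model == "confined") {
      placed <- FALSE
      for (try in 1:100) {
        cand <- pos[i, ] + steplen[i] * dir
        if (sqrt(sum((cand - origin)^2)) <= spec$tether_radius) {
          pos[i + 1, ] <- cand
          placed <- TRUE
          break
        }
        dir <- drop(runit(1))
      }
      if (!placed) pos[i + 1, ] <- pos[i, ]
    } else {
      pos[i + 1, ] <- pos[i, ] + steplen[i] * dir
    }
  }
  list(cell_id = cell_id, frame_id = frame_id, tissue = tissue,
       t = t, pos = pos)
}

#' Generate a multi-tissue synthetic cohort
#'
#' Builds a full `track_set` with the tissue -> frame -> cell hierarchy the
#' comparison layer expects. Each tissue entry is a list with fields:
#' \describe{
#'   \item{walkers}{list of components, each `list(spec = walker_spec(...),
#'     weight = ...)`; each cell draws its phenotype from these weights.}
#'   \item{n_frames, cells_per_frame}{frame structure.}
#'   \item{frame_speed_sd}{sd (um/min) of a per-frame additive offset on
#'     `speed_mean`, drawn once per frame — the frame-level heterogeneity
#'     probed by the intra-tissue ANOVA.}
#'   \item{n_steps_range}{integer range; each cell's step count is uniform
#'     on it (track lengths of real two-photon data vary).}
#' }
#' The whole cohort is reproducible: the same `tissues` spec and `seed` give
#' a bit-identical `track_set`.
#'
#' @param tissues named list of tissue entries (names become tissue labels).
#' @param seed integer RNG seed.
#' @return a `track_set`.
#' @export
generate_cohort <- function(tissues, seed = 1) {
  stopifnot(is.list(tissues), !is.null(names(tissues)))
  set.seed(seed)
  rows <- list()
  for (ti in names(tissues)) {
    cfg <- tissues[[ti]]
    stopifnot(cfg$n_frames >= 1, cfg$cells_per_frame >= 1)
    w <- vapply(cfg$walkers, function(x) x$weight, numeric(1))
    stopifnot(all(w >= 0), sum(w) > 0)
    rng <- cfg$n_steps_range %||% c(5, 30)
    for (fr in seq_len(cfg$n_frames)) {
      frame_id <- sprintf("f%02d", fr)
      offset <- stats::rnorm(1, 0, cfg$frame_speed_sd %||% 0)
      for (cl in seq_len(cfg$cells_per_frame)) {
        comp <- sample.int(length(w), 1, prob = w)
        sp <- cfg$walkers[[comp]]$spec
        sp$speed_mean <- max(sp$speed_mean + offset, 0.5)
        sp$n_steps <- if (rng[1] == rng[2]) rng[1] else
          sample(seq.int(rng[1], rng[2]), 1)
        sp$seed <- NULL
        tr <- generate_track(sp, cell_id = sprintf("c%04d", cl),
                             frame_id = frame_id, tissue = ti)
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = tr$cell_id, frame_id = tr$frame_id, tissue = tr$tissue,
          time_s = tr$t, x_um = tr$pos[, 1], y_um = tr$pos[, 2],
          z_um = tr$pos[, 3], stringsAsFactors = FALSE)
      }
    }
  }
  track_set(do.call(rbind, rows),
            source = sprintf("synthetic cohort (seed %d)", seed))
}

#' Default synthetic study cohort
#'
#' A stylized four-tissue cohort mirroring the frame structure and motility
#' phenotypes of a two-photon T cell imaging study: a lymph-node-like tissue
#' (many frames of fast persistent walkers sampled every 45 s, so the 90 s
#' normalization phase-splits them), a villi-like tissue (persistent, ~46.5 s
#' sampling), an influenza-lung-like tissue (reversing walkers with a
#' turning-angle mode near 160 degrees, 90 s sampling), and an LPS-lung-like
#' tissue (a confined/Brownian mixture, 90 s sampling). Frame counts and
#' cells per frame (40x110, 10x42, 5x71, 3x64) follow the study scale;
#' `scale` shrinks cells per frame proportionally for quick runs.
#'
#' @param scale multiplier on cells per frame (default 1; e.g. 0.1 for a
#'   fast test-sized cohort).
#' @return a `tissues` list for [generate_cohort()].
#' @export
study_cohort_spec <- function(scale = 1) {
  cells <- function(n) max(2L, as.integer(round(n * scale)))
  list(
    LN = list(
      walkers = list(list(
        spec = walker_spec("persistent", speed_mean = 6.5, speed_sd = 2,
                           cell_speed_sd = 1.5, persistence = 2.5,
                           dt = 45, time_jitter_sd = 1.5),
        weight = 1)),
      n_frames = 40, cells_per_frame = cells(110), frame_speed_sd = 1.2,
      n_steps_range = c(10, 40)),
    villi = list(
      walkers = list(list(
        spec = walker_spec("persistent", speed_mean = 7, speed_sd = 2,
                           cell_speed_sd = 1.5, persistence = 2,
                           dt = 46.5, time_jitter_sd = 4),
        weight = 1)),
      n_frames = 10, cells_per_frame = cells(42), frame_speed_sd = 1.0,
      n_steps_range = c(10, 40)),
    lung_flu = list(
      walkers = list(list(
        spec = walker_spec("back_and_forth", speed_mean = 5.5, speed_sd = 2,
                           cell_speed_sd = 3, reversal_prob = 0.6,
                           reversal_jitter_deg = 20, dt = 90,
                           time_jitter_sd = 0.12),
        weight = 1)),
      n_frames = 5, cells_per_frame = cells(71), frame_speed_sd = 0.9,
      n_steps_range = c(5, 30)),
    lung_lps = list(
      walkers = list(
        list(spec = walker_spec("confined", speed_mean = 4, speed_sd = 1.5,
                                cell_speed_sd = 1, tether_radius = 4,
                                dt = 90, time_jitter_sd = 0.10),
             weight = 0.6),
        list(spec = walker_spec("brownian", speed_mean = 5, speed_sd = 2,
                                cell_speed_sd = 1.5, dt = 90,
                                time_jitter_sd = 0.10),
             weight = 0.4)),
      n_frames = 3, cells_per_frame = cells(64), frame_speed_sd = 0.15,
      n_steps_range = c(5, 30)))
}
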