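#' Euclidean step distances of a track
#'
#' @param pos n x 3 matrix of positions (micrometres).
#' @return numeric vector of length n-1, the 3D distances between consecutive
#'   positions.
#' @export
step_distances <- function(pos) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 2) stop("track needs at least 2 points")
  d <- diff(pos)
  sqrt(rowSums(d^2))
}

#' Cell-based speed
#'
#' Total path length divided by total elapsed time: the mean speed along the
#' whole trajectory, in micrometres per minute.
#'
#' @param pos n x 3 position matrix (um).
#' @param t time vector, seconds, strictly increasing.
#' @return speed in um/min, or `NA` if the elapsed time is zero.
#' @export
cell_speed <- function(pos, t) {
  elapsed <- t[length(t)] - t[1]
  if (elapsed <= 0) return(NA_real_)
  sum(step_distances(pos)) / elapsed * 60
}

#' Displacement speed
#'
#' Straight-line distance from the first to the last observed position
#' divided by total elapsed time, in micrometres per minute. Always at most
#' the cell-based speed (triangle inequality).
#'
#' @inheritParams cell_speed
#' @return speed in um/min, or `NA` if the elapsed time is zero.
#' @export
displacement_speed <- function(pos, t) {
  elapsed <- t[length(t)] - t[1]
  if (elapsed <= 0) return(NA_real_)
  sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2)) / elapsed * 60
}

#' Meandering ratio
#'
#' Net displacement over total path length, in \[0, 1\]: 1 for a perfectly
#' straight path, near 0 for a path that returns to its origin. Satisfies
#' `meandering_ratio * cell_speed == displacement_speed` exactly.
#'
#' @inheritParams cell_speed
#' @return dimensionless ratio, or `NA` if the path length is zero.
#' @export
meandering_ratio <- function(pos, t = NULL) {
  path <- sum(step_distances(pos))
  if (path <= 0) return(NA_real_)
  sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2)) / path
}

#' Turning angles of a track
#'
#' For each interior position, the angle between the incoming displacement
#' vector v1 and the outgoing vector v2, `acos(v1.v2 / (|v1||v2|))` in
#' degrees (0 = no turn, 180 = full reversal). Each angle carries the speeds
#' of its two steps; the speed associated with an angle is their mean, and
#' angles whose associated speed falls below `min_speed` are flagged excluded
#' (near-stationary cells produce artifactual angles). Angles at zero-length
#' steps are undefined and returned as `NA` with a degenerate counter.
#'
#' @inheritParams cell_speed
#' @param min_speed exclusion threshold on the associated (mean of incoming
#'   and outgoing) step speed, um/min; default 1.
#' @return data.frame with one row per interior point: `angle_deg`,
#'   `speed_in`, `speed_out`, `step_speed` (the associated speed), and
#'   `included` (TRUE if the angle is defined and the associated speed is at
#'   least `min_speed`). Attribute `"n_degenerate"` counts undefined angles.
#' @export
turning_angles <- function(pos, t, min_speed = 1) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 3) stop("turning angles need at least 3 points")
  v <- diff(pos)
  len <- sqrt(rowSums(v^2))
  dt <- diff(t)
  sp <- len / dt * 60
  i1 <- seq_len(n - 2)
  i2 <- i1 + 1L
  denom <- len[i1] * len[i2]
  cosang <- rowSums(v[i1, , drop = FALSE] * v[i2, , drop = FALSE]) / denom
  cosang <- pmin(1, pmax(-1, cosang))
  angle <- acos(cosang) * 180 / pi
  angle[denom == 0] <- NA_real_
  assoc <- (sp[i1] + sp[i2]) / 2
  out <- data.frame(angle_deg = angle, speed_in = sp[i1], speed_out = sp[i2],
                    step_speed = assoc,
                    included = !is.na(angle) & assoc >= min_speed)
  attr(out, "n_degenerate") <- sum(is.na(angle))
  out
}

#' Pooled per-step table for a track set
#'
#' One row per turning angle (interior track point), with cell/frame/tissue
#' identity, for distributional analyses across cells.
#'
#' @param ts a `track_set` (normally already resampled).
#' @param min_speed angle exclusion threshold, um/min (see
#'   [turning_angles()]).
#' @return data.frame with columns `cell_id`, `frame_id`, `tissue`,
#'   `angle_deg`, `speed_in`, `speed_out`, `step_speed`, `included`.
#'   Attribute `"n_degenerate"` totals undefined angles across tracks.
#' @export
step_table <- function(ts, min_speed = 1) {
  trs <- tracks_split(ts)
  degen <- 0L
  rows <- lapply(trs, function(tr) {
    if (length(tr$t) < 3) return(NULL)
    a <- turning_angles(tr$pos, tr$t, min_speed = min_speed)
    degen <<- degen + attr(a, "n_degenerate")
    cbind(data.frame(cell_id = tr$cell_id, frame_id = tr$frame_id,
                     tissue = tr$tissue, stringsAsFactors = FALSE),
          a)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(cell_id = character(), frame_id = character(),
                      tissue = character(), angle_deg = numeric(),
                      speed_in = numeric(), speed_out = numeric(),
                      step_speed = numeric(), included = logical())
  }
  rownames(out) <- NULL
  attr(out, "n_degenerate") <- degen
  out
}

#' Relative-frequency histogram of turning angles
#'
#' Bins the included angles of a step table into fixed-width bins over
#' \[0, 180\] degrees (default 9 degrees, i.e. 20 bins; 180 falls in the top
#' bin) and returns relative frequencies summing to 1.
#'
#' @param steps a step table from [step_table()].
#' @param bin_width bin width in degrees.
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `count`, `freq`.
#' @export
angle_histogram <- function(steps, bin_width = 9) {
  ang <- steps$angle_deg[steps$included]
  if (length(ang) == 0) stop("no included turning angles to histogram")
  edges <- seq(0, 180, by = bin_width)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  bin <- findInterval(ang, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
             count = counts, freq = counts / sum(counts))
}

#' Per-cell proportion of turning angles below a threshold
#'
#' For each cell with at least one included angle, the fraction of its
#' included turning angles below `threshold` degrees. These per-cell
#' proportions are the unit of downstream pairwise tests on turning
#' behaviour.
#'
#' @param steps a step table from [step_table()].
#' @param threshold angle threshold in degrees (default 90).
#' @return data.frame with `cell_id`, `frame_id`, `tissue`, `n_angles`,
#'   `frac_below`. Cells with no included angles are omitted.
#' @export
fraction_below <- function(steps, threshold = 90) {
  s <- steps[steps$included, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(cell_id = character(), frame_id = character(),
                      tissue = character(), n_angles = integer(),
                      frac_below = numeric()))
  }
  key <- paste(s$tissue, s$frame_id, s$cell_id, sep = "\r")
  idx <- split(seq_len(nrow(s)), key)
  rows <- lapply(idx, function(i) {
    data.frame(cell_id = s$cell_id[i[1]], frame_id = s$frame_id[i[1]],
               tissue = s$tissue[i[1]], n_angles = length(i),
               frac_below = mean(s$angle_deg[i] < threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Speed versus turning-angle profile
#'
#' Bins included angles (default 9-degree bins) and reports, per bin, the
#' mean associated step speed, its population standard deviation, one eighth
#' of that sd (the plotted half-error-bar), and the count. Empty bins are
#' kept with count 0.
#'
#' @param steps a step table from [step_table()].
#' @param bin_width angle bin width in degrees.
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `n`, `mean_speed`,
#'   `sd_speed`, `err_speed` (= sd/8).
#' @export
speed_angle_profile <- function(steps, bin_width = 9) {
  s <- steps[steps$included, , drop = FALSE]
  if (nrow(s) == 0) stop("no included turning angles")
  edges <- seq(0, 180, by = bin_width)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  bin <- findInterval(s$angle_deg, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  mean_speed <- rep(NA_real_, nb)
  sd_speed <- rep(NA_real_, nb)
  n <- tabulate(bin, nbins = nb)
  for (b in which(n > 0)) {
    v <- s$step_speed[bin == b]
    mean_speed[b] <- mean(v)
    sd_speed[b] <- sqrt(mean((v - mean(v))^2))
  }
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
             n = n, mean_speed = mean_speed, sd_speed = sd_speed,
             err_speed = sd_speed / 8)
}

#' Speed-persistence likelihood from pooled consecutive speed pairs
#'
#' For consecutive step speeds (s_before, s_after) pooled over cells, and
#' speed bins of width `bin_width` um/min, the fold increase in the
#' probability that s_after falls in bin i given that s_before fell in bin i,
#' relative to the marginal probability:
#' ratio_i = (m * m_ab) / (m_a * m_b), where m is the total number of pairs,
#' m_b / m_a the counts of s_before / s_after in bin i, and m_ab the count of
#' pairs with both in bin i. Ratio 1 means speeds are memoryless; above 1,
#' the cell tends to persist at that speed. Bins with m_a * m_b = 0 are
#' undefined (`NA`). The top bin is open-ended at `max_bin`.
#'
#' @param s_before,s_after equal-length numeric vectors of consecutive step
#'   speeds, um/min.
#' @param bin_width speed bin width, um/min (default 1).
#' @param max_bin lower edge of the open top bin, um/min (default 12).
#' @return data.frame of class `persistence_table` with `bin_lo`, `bin_hi`
#'   (`Inf` for the top bin), `m_b`, `m_a`, `m_ab`, `ratio`; attribute
#'   `"m"` is the total pair count.
#' @export
persistence_from_speeds <- function(s_before, s_after, bin_width = 1,
                                    max_bin = 12) {
  stopifnot(length(s_before) == length(s_after))
  m <- length(s_before)
  if (m == 0) stop("no consecutive speed pairs")
  edges <- c(seq(0, max_bin, by = bin_width), Inf)
  nb <- length(edges) - 1
  bb <- findInterval(s_before, edges)
  ba <- findInterval(s_after, edges)
  m_b <- tabulate(bb, nbins = nb)
  m_a <- tabulate(ba, nbins = nb)
  m_ab <- tabulate(ifelse(bb == ba, bb, NA_integer_), nbins = nb)
  ratio <- ifelse(m_a > 0 & m_b > 0,
                  as.numeric(m) * as.numeric(m_ab) /
                    (as.numeric(m_a) * as.numeric(m_b)),
                  NA_real_)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    m_b = m_b, m_a = m_a, m_ab = m_ab, ratio = ratio)
  attr(out, "m") <- m
  class(out) <- c("persistence_table", "data.frame")
  out
}

#' Speed-persistence likelihood table for a track set
#'
#' Extracts all consecutive same-cell step-speed pairs from the set, pooled
#' across cells, and computes the persistence ratio per speed bin (see
#' [persistence_from_speeds()]). Typically called per tissue.
#'
#' @param ts a `track_set`.
#' @inheritParams persistence_from_speeds
#' @return a `persistence_table` (see [persistence_from_speeds()]).
#' @export
persistence_table <- function(ts, bin_width = 1, max_bin = 12) {
  trs <- tracks_split(ts)
  pairs <- lapply(trs, function(tr) {
    sp <- step_distances(tr$pos) / diff(tr$t) * 60
    if (length(sp) < 2) return(NULL)
    cbind(sp[-length(sp)], sp[-1])
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0) stop("no consecutive speed pairs")
  persistence_from_speeds(pairs[, 1], pairs[, 2], bin_width, max_bin)
}

#' Anomalous-diffusion exponent from MSD log-log regression
#'
#' Squared displacements from the first track position, (d_1k)^2, are
#' regressed on elapsed time t_k - t_1 on log-log axes; the least-squares
#' slope classifies the motion: about 1 is Brownian-like (diffusive),
#' between 1 and 2 superdiffusive (Levy-like, up to 2 for ballistic), below 1
#' subdiffusive. Elapsed time is capped (default 10.5 min) so long tracks do
#' not dominate the fit, and zero displacements are excluded (log undefined).
#' The slope is invariant to the logarithm base and to rigid-body motion of
#' the track.
#'
#' @inheritParams cell_speed
#' @param max_elapsed_min cap on elapsed time used in the fit, minutes.
#' @return the slope (dimensionless), or `NA` if fewer than 3 usable points
#'   remain.
#' @export
msd_slope <- function(pos, t, max_elapsed_min = 10.5) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 3) return(NA_real_)
  dt <- t[-1] - t[1]
  d2 <- rowSums((pos[-1, , drop = FALSE] -
                   matrix(pos[1, ], n - 1, 3, byrow = TRUE))^2)
  keep <- dt > 0 & dt <= max_elapsed_min * 60 & d2 > 0
  if (sum(keep) < 3) return(NA_real_)
  lx <- log(dt[keep])
  ly <- log(d2[keep])
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Confinement of a track
#'
#' Two related quantities around a 5-um ball criterion:
#'
#' \strong{Confined ratio} — an anchor scan. The anchor starts at the first
#' position; while subsequent positions stay within `radius` of the anchor
#' the cell is dwelling. When it first steps outside (at index k), the dwell
#' (time from the anchor to the last inside position) counts as confined if
#' it exceeds `min_dwell` seconds, and the scan restarts with the anchor at
#' k. A final dwell that never exits is treated the same way. The ratio is
#' total confined time over total track time.
#'
#' \strong{Confined time} — for every position taken as an anchor, the time
#' until the track first leaves the `radius`-ball around it; anchors whose
#' ball is never exited contribute the (censored) time to track end. The
#' mean over all positions, in minutes.
#'
#' @inheritParams cell_speed
#' @param radius ball radius, um (default 5).
#' @param min_dwell minimum dwell to count as confined, seconds (default
#'   150).
#' @return named numeric vector: `confined_ratio` (dimensionless, in
#'   \[0, 1\]) and `confined_time_min` (minutes).
#' @export
confinement <- function(pos, t, radius = 5, min_dwell = 150) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 2) stop("track needs at least 2 points")
  total <- t[n] - t[1]

  # confined ratio: anchor scan
  confined <- 0
  a <- 1L
  j <- 2L
  while (a < n) {
    anchor <- pos[a, ]
    exit <- NA_integer_
    for (j in seq.int(a + 1L, n)) {
      if (sqrt(sum((pos[j, ] - anchor)^2)) >= radius) {
        exit <- j
        break
      }
    }
    last_inside <- if (is.na(exit)) n else exit - 1L
    dwell <- t[last_inside] - t[a]
    if (dwell > min_dwell) confined <- confined + dwell
    if (is.na(exit)) break
    a <- exit
  }
  ratio <- if (total > 0) confined / total else NA_real_

  # confined time: mean first-exit time over all anchors (censored at end)
  exit_times <- numeric(n)
  for (i in seq_len(n)) {
    te <- t[n] - t[i]
    if (i < n) {
      for (j in seq.int(i + 1L, n)) {
        if (sqrt(sum((pos[j, ] - pos[i, ])^2)) >= radius) {
          te <- t[j] - t[i]
          break
        }
      }
    }
    exit_times[i] <- te
  }
  c(confined_ratio = ratio, confined_time_min = mean(exit_times) / 60)
}

#' Patrolled-volume rate of a track
#'
#' The track is placed (bounding box centered) in a cubic domain of side
#' `domain` um partitioned into `voxel`-um cubes. A cube is patrolled when
#' its center lies within `reach` um of any observed position or of any
#' point along the straight segments joining successive positions (segments
#' are sampled every `voxel/2` um, fine enough that no cube within reach is
#' missed). The patrolled volume is the marked-cube count times the cube
#' volume, and the rate divides by the tracked time, giving um^3/s.
#'
#' @inheritParams cell_speed
#' @param voxel cube edge, um (default 2.5).
#' @param reach patrol radius around the cell center, um (default 5).
#' @param domain cubic domain edge, um (default 400).
#' @return rate in um^3/s. Errors on zero-duration tracks or tracks whose
#'   extent exceeds the domain.
#' @export
volume_rate <- function(pos, t, voxel = 2.5, reach = 5, domain = 400) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 2) stop("track needs at least 2 points")
  elapsed <- t[n] - t[1]
  if (elapsed <= 0) stop("zero-duration track")
  ext <- apply(pos, 2, range)
  if (any(ext[2, ] - ext[1, ] > domain)) {
    stop("track extent exceeds the ", domain, " um domain")
  }
  shift <- domain / 2 - (ext[1, ] + ext[2, ]) / 2
  p <- sweep(pos, 2, shift, "+")

  # dense sample points: vertices plus points every voxel/2 along segments
  samples <- list(p)
  step <- voxel / 2
  for (i in seq_len(n - 1)) {
    seg <- p[i + 1, ] - p[i, ]
    L <- sqrt(sum(seg^2))
    if (L > step) {
      m <- ceiling(L / step)
      fr <- seq_len(m - 1) / m
      samples[[length(samples) + 1]] <-
        matrix(p[i, ], length(fr), 3, byrow = TRUE) + outer(fr, seg)
    }
  }
  S <- do.call(rbind, samples)

  nx <- round(domain / voxel)
  # voxel index window around each sample point; +/-2 cells cover reach = 2*voxel
  off <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2))
  base <- floor(S / voxel) + 1
  ns <- nrow(S)
  no <- nrow(off)
  idx <- base[rep(seq_len(ns), each = no), ] + off[rep(seq_len(no), ns), ]
  ok <- idx >= 1 & idx <= nx
  ok <- ok[, 1] & ok[, 2] & ok[, 3]
  idx <- idx[ok, , drop = FALSE]
  centers <- (idx - 0.5) * voxel
  d2 <- rowSums((centers - S[rep(seq_len(ns), each = no), ][ok, , drop = FALSE])^2)
  hit <- idx[d2 < reach^2, , drop = FALSE]
  lin <- unique(hit[, 1] + nx * (hit[, 2] - 1) + nx^2 * (hit[, 3] - 1))
  length(lin) * voxel^3 / elapsed
}

#' Compute all per-cell metrics and the pooled step table
#'
#' Runs every per-cell metric over a (normally resampled) track set: speeds,
#' meandering ratio, MSD slope, confinement, patrolled-volume rate, along
#' with track size and duration; and builds the pooled per-step table of
#' turning angles. Metrics that are undefined for a cell (too few points,
#' zero path, ...) are `NA`, never silent zeros; exclusion counts are
#' attached as the `"exclusions"` attribute.
#'
#' @param ts a `track_set`.
#' @param params list of metric parameters; recognized entries (with
#'   defaults): `min_speed` (1 um/min), `msd_cap_min` (10.5), `confine_radius`
#'   (5 um), `confine_dwell` (150 s), `voxel` (2.5 um), `reach` (5 um),
#'   `domain` (400 um).
#' @return list with `cell_metrics` (data.frame, one row per cell) and
#'   `steps` (the step table).
#' @export
compute_all <- function(ts, params = list()) {
  p <- utils::modifyList(
    list(min_speed = 1, msd_cap_min = 10.5, confine_radius = 5,
         confine_dwell = 150, voxel = 2.5, reach = 5, domain = 400),
    params)
  trs <- tracks_split(ts)
  n_msd_undefined <- 0L
  rows <- lapply(trs, function(tr) {
    n <- length(tr$t)
    cs <- cell_speed(tr$pos, tr$t)
    ds <- displacement_speed(tr$pos, tr$t)
    mr <- meandering_ratio(tr$pos)
    ms <- msd_slope(tr$pos, tr$t, p$msd_cap_min)
    if (is.na(ms)) n_msd_undefined <<- n_msd_undefined + 1L
    cf <- confinement(tr$pos, tr$t, p$confine_radius, p$confine_dwell)
    vr <- tryCatch(
      volume_rate(tr$pos, tr$t, p$voxel, p$reach, p$domain),
      error = function(e) stop("volume_rate failed for cell '", tr$cell_id,
                               "': ", conditionMessage(e)))
    data.frame(cell_id = tr$cell_id, frame_id = tr$frame_id,
               tissue = tr$tissue, n_points = n,
               duration_min = (tr$t[n] - tr$t[1]) / 60,
               cell_speed = cs, displacement_speed = ds,
               meandering_ratio = mr, msd_slope = ms,
               confined_ratio = unname(cf["confined_ratio"]),
               confined_time = unname(cf["confined_time_min"]),
               volume_rate = vr, stringsAsFactors = FALSE)
  })
  cm <- do.call(rbind, rows)
  rownames(cm) <- NULL
  steps <- step_table(ts, min_speed = p$min_speed)
  attr(cm, "exclusions") <- list(
    msd_undefined = n_msd_undefined,
    degenerate_angles = attr(steps, "n_degenerate"),
    slow_angles_excluded = sum(!steps$included))
  list(cell_metrics = cm, steps = steps)
}
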