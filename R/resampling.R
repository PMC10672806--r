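#' Resampling specification
#'
#' Different imaging sessions acquire positions at different intervals; all
#' metrics downstream assume a common nominal step. The default target is
#' 90 s. Tracks whose native step is already within `tolerance` of the target
#' are passed through unchanged; faster-sampled tracks are phase-split (see
#' [resample_track()]).
#'
#' @param target_dt target time step, seconds (> 0).
#' @param tolerance allowed deviation, seconds, when matching samples to the
#'   target grid and when deciding a track is already at the target step.
#' @return object of class `resample_spec`.
#' @export
resample_spec <- function(target_dt = 90, tolerance = 10) {
  stopifnot(is.numeric(target_dt), length(target_dt) == 1, target_dt > 0,
            is.numeric(tolerance), length(tolerance) == 1, tolerance >= 0)
  structure(list(target_dt = target_dt, tolerance = tolerance),
            class = "resample_spec")
}

# Phase-complete subsampling of a time vector: returns a list of index
# vectors, one per phase offset. For a native step d and target T with
# k = round(T/d) >= 2, emits k phases anchored at points 1..k, each greedily
# selecting the remaining sample nearest to (last selected time + T), so
# every original point is used exactly once on a regular grid (a short
# remainder may be dropped where a phase ends with < 2 points).
resample_indices <- function(t, target_dt, tolerance) {
  n <- length(t)
  native <- stats::median(diff(t))
  if (abs(native - target_dt) <= tolerance) {
    return(list(seq_len(n)))
  }
  k <- round(target_dt / native)
  if (k < 2) {
    # undersampled relative to the target; nothing to thin, no interpolation
    return(list(seq_len(n)))
  }
  phases <- vector("list", k)
  for (off in seq_len(min(k, n))) {
    sel <- off
    cur <- off
    repeat {
      if (cur + 1L > n) break
      want <- t[cur] + target_dt
      cand <- seq.int(cur + 1L, n)
      j <- cand[which.min(abs(t[cand] - want))]
      if (abs(t[j] - want) > tolerance) break
      sel <- c(sel, j)
      cur <- j
    }
    phases[[off]] <- sel
  }
  phases[!vapply(phases, is.null, logical(1))]
}

#' Resample one track to the target time step
#'
#' Implements phase-complete subsampling: a series acquired every 45 s and
#' normalized to 90 s yields two tracks, one from the even-indexed times
#' \{t0, t2, t4, ...\} and one from the odd \{t1, t3, t5, ...\}, so no
#' observation is discarded. Generally, for native step d the stride is
#' k = round(target/d) and all k phase offsets are emitted; selection within
#' a phase is greedy nearest-time, so jittered series are handled without
#' interpolation (every output point is an input point). Tracks already at
#' the target step (within tolerance) are returned unchanged.
#'
#' @param tr a single track as returned by [tracks_split()] (list with
#'   `cell_id`, `frame_id`, `tissue`, `t`, `pos`).
#' @param spec a [resample_spec()].
#' @return list of tracks in the same form. Phase-split tracks inherit the
#'   cell id with a `_p<offset>` suffix and are treated downstream as
#'   independent tracks. Phases left with fewer than 2 points are dropped;
#'   the number dropped is in attribute `"n_dropped"`.
#' @export
resample_track <- function(tr, spec = resample_spec()) {
  phases <- resample_indices(tr$t, spec$target_dt, spec$tolerance)
  keep <- phases[vapply(phases, length, integer(1)) >= 2]
  n_dropped <- length(phases) - length(keep)
  out <- lapply(seq_along(keep), function(p) {
    idx <- keep[[p]]
    id <- if (length(phases) > 1) paste0(tr$cell_id, "_p", p) else tr$cell_id
    list(cell_id = id, frame_id = tr$frame_id, tissue = tr$tissue,
         t = tr$t[idx], pos = tr$pos[idx, , drop = FALSE])
  })
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Resample every track in a set to a common time step
#'
#' @param ts a `track_set`.
#' @param spec a [resample_spec()].
#' @return a new `track_set` at the nominal step `spec$target_dt`; the log
#'   carries the count of phase tracks dropped for having < 2 points.
#' @export
resample_tracks <- function(ts, spec = resample_spec()) {
  trs <- tracks_split(ts)
  dropped <- 0L
  rows <- vector("list", length(trs))
  for (i in seq_along(trs)) {
    res <- resample_track(trs[[i]], spec)
    dropped <- dropped + attr(res, "n_dropped")
    rows[[i]] <- do.call(rbind, lapply(res, function(x) {
      data.frame(cell_id = x$cell_id, frame_id = x$frame_id,
                 tissue = x$tissue, time_s = x$t,
                 x_um = x$pos[, 1], y_um = x$pos[, 2], z_um = x$pos[, 3],
                 stringsAsFactors = FALSE)
    }))
  }
  pts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pts)) {
    pts <- empty_points()
  }
  log <- ts$log
  log$dropped_resample_phases <- dropped
  track_set(pts, source = paste0(ts$metadata$source, " [resampled]"),
            nominal_dt = spec$target_dt, log = log)
}

empty_points <- function() {
  data.frame(cell_id = character(), frame_id = character(),
             tissue = character(), time_s = numeric(), x_um = numeric(),
             y_um = numeric(), z_um = numeric(), stringsAsFactors = FALSE)
}

#' Per-tissue summary of realized time steps
#'
#' Pools all consecutive time differences within each track, per tissue, and
#' reports their mean and standard deviation in seconds. The sd is the
#' population (divide-by-n) sd over the pooled steps. Used after resampling
#' to confirm the realized step sits at the nominal target.
#'
#' @param ts a `track_set`.
#' @return data.frame with columns `tissue`, `mean_dt_s`, `sd_dt_s`,
#'   `n_steps`. Tissues contributing no steps are omitted with a warning.
#' @export
timestep_summary <- function(ts) {
  trs <- tracks_split(ts)
  tissues <- vapply(trs, `[[`, character(1), "tissue")
  steps <- lapply(trs, function(x) diff(x$t))
  by_tissue <- split(steps, tissues)
  all_tissues <- unique(ts$points$tissue)
  rows <- lapply(names(by_tissue), function(ti) {
    d <- unlist(by_tissue[[ti]], use.names = FALSE)
    if (length(d) == 0) return(NULL)
    data.frame(tissue = ti, mean_dt_s = mean(d),
               sd_dt_s = sqrt(mean((d - mean(d))^2)),
               n_steps = length(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  absent <- setdiff(all_tissues, out$tissue)
  if (length(absent) > 0) {
    warning("tissue(s) with no time steps omitted: ",
            paste(absent, collapse = ", "))
  }
  out[order(out$tissue), , drop = FALSE]
}
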