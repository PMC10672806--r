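#' @keywords internal
"_PACKAGE"

# Canonical column order for the track table.
TRACK_COLS <- c("cell_id", "frame_id", "tissue", "time_s", "x_um", "y_um", "z_um")

#' Construct a track set
#'
#' A `track_set` holds 3D cell trajectories from time-lapse imaging as a
#' single long table (one row per cell per time point) plus provenance
#' metadata and load-time bookkeeping. Positions are in micrometres, times in
#' seconds. Cells are grouped into imaging frames (fields) and frames into
#' tissues/conditions; a cell is identified by the triple
#' (tissue, frame_id, cell_id).
#'
#' Validation: times must be finite and non-negative, coordinates finite,
#' times strictly increasing within a cell (duplicate times are an error),
#' and every track must have at least 2 points — shorter tracks are dropped
#' and counted in `$log$dropped_short_tracks`.
#'
#' @param points data.frame with columns `cell_id`, `frame_id`, `tissue`
#'   (character), `time_s`, `x_um`, `y_um`, `z_um` (numeric).
#' @param source character description of provenance.
#' @param nominal_dt nominal sampling interval in seconds, or `NA` if unknown.
#' @param log list of load-time counters (rejected rows, dropped tracks).
#' @return An object of class `track_set`.
#' @export
track_set <- function(points, source = "unspecified", nominal_dt = NA_real_,
                      log = list()) {
  stopifnot(is.data.frame(points))
  missing <- setdiff(TRACK_COLS, names(points))
  if (length(missing) > 0) {
    stop("track table is missing column(s): ", paste(missing, collapse = ", "))
  }
  points <- as.data.frame(points)[TRACK_COLS]
  for (col in c("cell_id", "frame_id", "tissue")) {
    points[[col]] <- as.character(points[[col]])
  }
  for (col in c("time_s", "x_um", "y_um", "z_um")) {
    if (!is.numeric(points[[col]])) {
      stop("column '", col, "' must be numeric")
    }
  }
  num <- as.matrix(points[c("time_s", "x_um", "y_um", "z_um")])
  if (nrow(points) > 0 && !all(is.finite(num))) {
    stop("non-finite time or coordinate values in track table")
  }
  if (nrow(points) > 0 && any(points$time_s < 0)) {
    stop("negative times in track table")
  }

  key <- track_key(points)
  ord <- order(points$tissue, points$frame_id, points$cell_id, points$time_s)
  points <- points[ord, , drop = FALSE]
  key <- key[ord]
  rownames(points) <- NULL

  # duplicate (cell, t) within a track is a hard validation error
  if (anyDuplicated(paste(key, points$time_s, sep = "\r"))) {
    bad <- key[duplicated(paste(key, points$time_s, sep = "\r"))][1]
    stop("duplicate time point within track '", bad, "'")
  }

  # drop single-point tracks, keep a counter
  n_per <- table(key)
  short <- names(n_per)[n_per < 2]
  if (length(short) > 0) {
    points <- points[!(key %in% short), , drop = FALSE]
    rownames(points) <- NULL
  }
  log$dropped_short_tracks <- length(short) + (log$dropped_short_tracks %||% 0L)

  structure(
    list(points = points,
         metadata = list(source = source, nominal_dt = nominal_dt),
         log = log),
    class = "track_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

track_key <- function(points) {
  paste(points$tissue, points$frame_id, points$cell_id, sep = "\r")
}

#' @export
print.track_set <- function(x, ...) {
  n_tr <- n_tracks(x)
  cat(sprintf("<track_set> %d tracks, %d points, %d tissue(s)\n",
              n_tr, nrow(x$points), length(unique(x$points$tissue))))
  cat("  source:", x$metadata$source, "\n")
  if (!is.na(x$metadata$nominal_dt)) {
    cat("  nominal time step:", x$metadata$nominal_dt, "s\n")
  }
  invisible(x)
}

#' Number of tracks in a track set
#' @param ts a `track_set`
#' @return integer count of distinct (tissue, frame, cell) tracks
#' @export
n_tracks <- function(ts) {
  length(unique(track_key(ts$points)))
}

#' Split a track set into per-cell trajectories
#'
#' @param ts a `track_set`
#' @return a list, one element per track, each a list with `cell_id`,
#'   `frame_id`, `tissue`, `t` (seconds, strictly increasing) and `pos`
#'   (n x 3 matrix of x/y/z in micrometres).
#' @export
tracks_split <- function(ts) {
  pts <- ts$points
  key <- track_key(pts)
  idx <- split(seq_len(nrow(pts)), key)
  lapply(idx, function(i) {
    list(cell_id = pts$cell_id[i[1]],
         frame_id = pts$frame_id[i[1]],
         tissue = pts$tissue[i[1]],
         t = pts$time_s[i],
         pos = as.matrix(pts[i, c("x_um", "y_um", "z_um"), drop = FALSE]))
  })
}

#' Read cell tracks from a delimited text file
#'
#' Expects a header row and, by default, the canonical columns
#' `cell_id,frame_id,tissue,time_s,x_um,y_um,z_um`. Comma and tab separators
#' are auto-detected from the header. Exports from other trackers can be
#' adapted with `dialect`, a named character vector mapping canonical names
#' to the file's column names, e.g.
#' `c(cell_id = "TrackID", time_s = "Time", x_um = "PosX", ...)`.
#'
#' Rows with non-numeric time or coordinates raise an error naming the line;
#' tracks with fewer than 2 points are dropped with a counter in the result's
#' `$log`. Row order in the file is irrelevant: points are sorted by time
#' within each cell.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical column names to
#'   file column names; `NULL` for the canonical names.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @return a `track_set`.
#' @export
read_tracks <- function(path, dialect = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (is.null(sep)) {
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", encoding = "UTF-8",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- TRACK_COLS
  names(cols) <- TRACK_COLS
  if (!is.null(dialect)) {
    stopifnot(is.character(dialect), !is.null(names(dialect)))
    unknown <- setdiff(names(dialect), TRACK_COLS)
    if (length(unknown) > 0) {
      stop("dialect maps unknown column(s): ", paste(unknown, collapse = ", "))
    }
    cols[names(dialect)] <- dialect
  }
  missing <- cols[!(cols %in% names(raw))]
  if (length(missing) > 0) {
    stop("input is missing required column(s): ",
         paste(sprintf("%s (for %s)", missing, names(missing)), collapse = ", "))
  }
  out <- raw[unname(cols)]
  names(out) <- TRACK_COLS
  for (col in c("time_s", "x_um", "y_um", "z_um")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at line ", bad[1] + 1L,
           " of ", path)
    }
    out[[col]] <- vals
  }
  track_set(out, source = path)
}

#' Write cell tracks to CSV
#'
#' Writes the canonical track CSV (`cell_id,frame_id,tissue,time_s,x_um,y_um,
#' z_um`, UTF-8, header always present). `read_tracks()` on the written file
#' reproduces the track set.
#'
#' @param ts a `track_set`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(ts$points, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
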