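# Build a single track in tracks_split() form from coordinate vectors.
make_track <- function(x, y = rep(0, length(x)), z = rep(0, length(x)),
                       t = (seq_along(x) - 1) * 90, cell_id = "c1",
                       frame_id = "f1", tissue = "T") {
  list(cell_id = cell_id, frame_id = frame_id, tissue = tissue,
       t = t, pos = cbind(x_um = x, y_um = y, z_um = z))
}

# Wrap one or more tracks into a track_set.
make_track_set <- function(...) {
  trs <- list(...)
  pts <- do.call(rbind, lapply(trs, function(tr) {
    data.frame(cell_id = tr$cell_id, frame_id = tr$frame_id,
               tissue = tr$tissue, time_s = tr$t, x_um = tr$pos[, 1],
               y_um = tr$pos[, 2], z_um = tr$pos[, 3],
               stringsAsFactors = FALSE)
  }))
  track_set(pts, source = "test fixture")
}

# Independent brute-force oracle for the patrolled volume: same geometric
# definition (bounding-box centering, dense segment sampling every voxel/2),
# but marks voxels by exhaustively scanning EVERY cube center in the domain
# instead of windowed candidate enumeration.
bf_volume_rate <- function(pos, t, voxel = 2.5, reach = 5, domain = 50) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  elapsed <- t[n] - t[1]
  ext <- apply(pos, 2, range)
  shift <- domain / 2 - (ext[1, ] + ext[2, ]) / 2
  p <- sweep(pos, 2, shift, "+")
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
  cent <- (seq_len(nx) - 0.5) * voxel
  grid <- as.matrix(expand.grid(x = cent, y = cent, z = cent))
  hit <- rep(FALSE, nrow(grid))
  for (k in seq_len(nrow(S))) {
    d2 <- (grid[, 1] - S[k, 1])^2 + (grid[, 2] - S[k, 2])^2 +
      (grid[, 3] - S[k, 3])^2
    hit <- hit | (d2 < reach^2)
  }
  sum(hit) * voxel^3 / elapsed
}

# One-tissue per-cell metrics table with normal frame values and an optional
# shifted frame, for exercising the ANOVA / outlier-reduction layer.
make_frame_metrics <- function(n_frames = 6, cells = 12, mean = 6, sd = 1,
                               shift_frame = NULL, shift = 3, tissue = "T") {
  rows <- lapply(seq_len(n_frames), function(f) {
    mu <- mean + if (!is.null(shift_frame) && f == shift_frame) shift else 0
    data.frame(cell_id = sprintf("c%02d_%02d", f, seq_len(cells)),
               frame_id = sprintf("f%02d", f), tissue = tissue,
               cell_speed = rnorm(cells, mu, sd), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
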