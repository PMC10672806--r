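test_that("step distances match closed forms", {
  expect_equal(step_distances(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(step_distances(rbind(c(1, 1, 1), c(1, 1, 1))), 0)
  expect_equal(step_distances(rbind(c(0, 0, 0), c(1, 1, 1))), sqrt(3))
})

test_that("speeds and meandering match hand-computed tracks", {
  t <- c(0, 90, 180)
  straight <- rbind(c(0, 0, 0), c(9, 0, 0), c(18, 0, 0))
  outback <- rbind(c(0, 0, 0), c(9, 0, 0), c(0, 0, 0))
  lshape <- rbind(c(0, 0, 0), c(9, 0, 0), c(9, 9, 0))

  expect_equal(cell_speed(straight, t), 6)
  expect_equal(cell_speed(outback, t), 6)
  expect_equal(displacement_speed(straight, t), 6)
  expect_equal(displacement_speed(outback, t), 0)
  expect_equal(displacement_speed(lshape, t), 9 * sqrt(2) / 3)
  expect_equal(meandering_ratio(straight), 1)
  expect_equal(meandering_ratio(outback), 0)
  expect_equal(meandering_ratio(lshape), sqrt(2) / 2)

  stationary <- rbind(c(2, 2, 2), c(2, 2, 2))
  expect_equal(cell_speed(stationary, c(0, 90)), 0)
  expect_true(is.na(meandering_ratio(stationary)))
  expect_true(is.na(cell_speed(straight, c(0, 0, 0))))
})

test_that("turning angles match right-angle, reversal, and collinear cases", {
  t <- c(0, 90, 180)
  right <- turning_angles(rbind(c(0, 0, 0), c(9, 0, 0), c(9, 9, 0)), t)
  expect_equal(right$angle_deg, 90)
  rev <- turning_angles(rbind(c(0, 0, 0), c(9, 0, 0), c(0, 0, 0)), t)
  expect_equal(rev$angle_deg, 180)
  straight <- turning_angles(rbind(c(0, 0, 0), c(9, 0, 0), c(18, 0, 0)), t)
  expect_equal(straight$angle_deg, 0)
})

test_that("zero-length steps give undefined angles; slow angles are excluded", {
  t <- c(0, 90, 180)
  degen <- turning_angles(rbind(c(0, 0, 0), c(0, 0, 0), c(9, 0, 0)), t)
  expect_true(is.na(degen$angle_deg))
  expect_equal(attr(degen, "n_degenerate"), 1)
  # steps of 0.6 um / 90 s = 0.4 um/min: below the 1 um/min threshold
  slow <- turning_angles(rbind(c(0, 0, 0), c(0.6, 0, 0), c(0.6, 0.6, 0)), t)
  expect_false(slow$included)
  expect_true(turning_angles(rbind(c(0, 0, 0), c(0.6, 0, 0), c(0.6, 0.6, 0)),
                             t, min_speed = 0)$included)
})

test_that("angle histogram frequencies sum to one and land in the right bins", {
  steps <- data.frame(angle_deg = c(45, 45, 135, 180), included = TRUE)
  h <- angle_histogram(steps, bin_width = 9)
  expect_equal(sum(h$freq), 1)
  expect_equal(h$freq[h$bin_lo == 45], 0.5)
  expect_equal(h$freq[h$bin_lo == 171], 0.25)  # 180 closed into the top bin
  expect_error(angle_histogram(data.frame(angle_deg = 10, included = FALSE)),
               "no included")
})

test_that("per-cell fraction of low angles matches hand counts", {
  steps <- data.frame(
    cell_id = c("a", "a", "b", "c"), frame_id = "f1", tissue = "T",
    angle_deg = c(45, 135, 45, 135), included = c(TRUE, TRUE, TRUE, FALSE))
  fb <- fraction_below(steps, 90)
  expect_equal(fb$frac_below[fb$cell_id == "a"], 0.5)
  expect_equal(fb$frac_below[fb$cell_id == "b"], 1)
  expect_false("c" %in% fb$cell_id)  # no valid angles -> omitted
})

test_that("speed-angle profile reports per-bin means, sd/8 and counts", {
  steps <- data.frame(angle_deg = c(4, 5, 100), step_speed = c(6, 6, 2),
                      included = TRUE)
  prof <- speed_angle_profile(steps, 9)
  expect_equal(prof$mean_speed[1], 6)
  expect_equal(prof$sd_speed[1], 0)
  expect_equal(prof$n[1], 2)
  expect_equal(prof$err_speed[prof$bin_lo == 99], 0)  # single record: sd 0
  expect_equal(sum(prof$n), 3)
  # two-population input: fast/straight + slow/turny -> decreasing means
  set.seed(4)
  pop <- data.frame(
    angle_deg = c(runif(500, 0, 40), runif(500, 140, 180)),
    step_speed = c(rnorm(500, 10, 1), rnorm(500, 2, 0.5)),
    included = TRUE)
  p2 <- speed_angle_profile(pop, 9)
  lo <- mean(p2$mean_speed[p2$bin_lo < 40], na.rm = TRUE)
  hi <- mean(p2$mean_speed[p2$bin_lo >= 140], na.rm = TRUE)
  expect_gt(lo, hi)
})

test_that("persistence ratio matches direct counting on a hand-built case", {
  # one bin with m=4 pairs, m_b=2, m_a=2, m_ab=2 -> ratio (4*2)/(2*2) = 2
  sb <- c(0.5, 0.5, 5.5, 5.5)
  sa <- c(0.5, 0.5, 5.5, 5.5)
  pt <- persistence_from_speeds(sb, sa, bin_width = 1, max_bin = 12)
  expect_equal(attr(pt, "m"), 4)
  expect_equal(pt$ratio[pt$bin_lo == 0], 2)
  expect_equal(pt$ratio[pt$bin_lo == 5], 2)
  expect_true(is.na(pt$ratio[pt$bin_lo == 3]))  # empty bin undefined
  # constant-speed pairs: single occupied bin, ratio m*m/(m*m) = 1
  cst <- persistence_from_speeds(rep(4.2, 10), rep(4.2, 10))
  expect_equal(cst$ratio[cst$bin_lo == 4], 1)
})

test_that("persistence_table pools consecutive pairs across a track set", {
  # track with steps 3, 3, 9 um per 90 s -> speeds 2, 2, 6 -> pairs (2,2), (2,6)
  tr <- make_track(x = c(0, 3, 6, 15))
  pt <- persistence_table(make_track_set(tr), max_bin = 12)
  expect_equal(attr(pt, "m"), 2)
  expect_equal(pt$m_ab[pt$bin_lo == 2], 1)
  expect_equal(pt$m_b[pt$bin_lo == 2], 2)
  expect_equal(pt$m_a[pt$bin_lo == 6], 1)
  expect_error(persistence_table(make_track_set(make_track(x = c(0, 1)))),
               "no consecutive")
})

test_that("MSD slope is exactly 2 for constant-velocity motion", {
  t <- (0:10) * 90
  pos <- cbind(3 * (0:10), 0, 0)
  expect_equal(msd_slope(pos, t), 2, tolerance = 1e-12)
})

test_that("MSD slope respects the elapsed-time cap and domain rules", {
  t <- (0:10) * 90
  # ballistic for 7 steps then a huge jump: cap at 10.5 min ignores the jump
  pos <- cbind(c(3 * (0:7), 500, 510, 520), 0, 0)
  expect_equal(msd_slope(pos, t, max_elapsed_min = 10.5), 2, tolerance = 1e-12)
  # return to origin: that point is excluded (log 0), remaining fit works
  pos2 <- cbind(c(0, 3, 0, 6, 9), 0, 0)
  expect_false(is.na(msd_slope(pos2, (0:4) * 90)))
  # fewer than 3 usable points -> NA marker
  expect_true(is.na(msd_slope(cbind(c(0, 1, 0), 0, 0), (0:2) * 90)))
})

test_that("MSD slope is invariant to rigid-body motion and log base", {
  set.seed(8)
  tr <- generate_track(walker_spec("persistent", n_steps = 12))
  s0 <- msd_slope(tr$pos, tr$t)
  # random rotation (QR of a random matrix) + translation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  moved <- tr$pos %*% R + matrix(c(100, -50, 7), nrow(tr$pos), 3, byrow = TRUE)
  expect_equal(msd_slope(moved, tr$t), s0, tolerance = 1e-9)
})

test_that("confinement matches the anchor-scan definition", {
  # stationary for 10 steps of 90 s: one dwell of 900 s > 150 s -> ratio 1
  n <- 10
  stat <- make_track(x = rep(0, n + 1), t = (0:n) * 90)
  cf <- confinement(stat$pos, stat$t)
  expect_equal(unname(cf["confined_ratio"]), 1)
  # confined time: mean over anchors i of (T - t_i), censored at track end
  expect_equal(unname(cf["confined_time_min"]),
               mean(900 - (0:n) * 90) / 60)
  # straight mover exiting the 5-um ball every step: never confined
  fast <- make_track(x = 9 * (0:n), t = (0:n) * 90)
  cf2 <- confinement(fast$pos, fast$t)
  expect_equal(unname(cf2["confined_ratio"]), 0)
  expect_equal(unname(cf2["confined_time_min"]),
               mean(c(rep(90, n), 0)) / 60)
  # dwell shorter than 150 s does not count: 2 steps inside then exit
  mix <- make_track(x = c(0, 1, 9, 18), t = (0:3) * 60)
  expect_equal(unname(confinement(mix$pos, mix$t)["confined_ratio"]), 0)
})

test_that("patrolled volume equals the brute-force oracle", {
  # stationary cell: marked volume approximates the 5-um ball
  pos <- rbind(c(25, 25, 25), c(25, 25, 25))
  t <- c(0, 90)
  v <- volume_rate(pos, t, domain = 50)
  expect_equal(v, bf_volume_rate(pos, t, domain = 50))
  expect_equal(v * 90, 4 / 3 * pi * 5^3, tolerance = 0.1)
  # straight 90-um segment: capsule voxelization, exact match
  seg <- rbind(c(0, 0, 0), c(90, 0, 0))
  ts <- c(0, 900)
  expect_equal(volume_rate(seg, ts, domain = 120),
               bf_volume_rate(seg, ts, domain = 120))
  # doubling duration with identical geometry halves the rate
  expect_equal(volume_rate(seg, c(0, 1800), domain = 120),
               volume_rate(seg, ts, domain = 120) / 2)
  expect_error(volume_rate(pos, c(0, 0), domain = 50), "zero-duration")
  expect_error(volume_rate(rbind(c(0, 0, 0), c(60, 0, 0)), t, domain = 50),
               "exceeds")
})

test_that("all metrics are translation invariant; speeds rotation invariant", {
  set.seed(15)
  for (model in c("brownian", "persistent", "back_and_forth")) {
    tr <- generate_track(walker_spec(model, n_steps = 10))
    shift <- matrix(c(-30, 12, 44), nrow(tr$pos), 3, byrow = TRUE)
    moved <- tr$pos + shift
    expect_equal(cell_speed(moved, tr$t), cell_speed(tr$pos, tr$t))
    expect_equal(displacement_speed(moved, tr$t),
                 displacement_speed(tr$pos, tr$t))
    expect_equal(meandering_ratio(moved), meandering_ratio(tr$pos))
    expect_equal(confinement(moved, tr$t), confinement(tr$pos, tr$t))
    expect_equal(msd_slope(moved, tr$t), msd_slope(tr$pos, tr$t))
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rot <- tr$pos %*% R
    expect_equal(cell_speed(rot, tr$t), cell_speed(tr$pos, tr$t))
    expect_equal(displacement_speed(rot, tr$t),
                 displacement_speed(tr$pos, tr$t))
  }
})

test_that("compute_all composes per-cell metrics and propagates NA markers", {
  set.seed(33)
  tr1 <- generate_track(walker_spec("persistent", n_steps = 8),
                        cell_id = "long")
  tr2 <- make_track(x = c(0, 5), cell_id = "short")  # 2 points: no MSD slope
  ts <- make_track_set(tr1, tr2)
  out <- compute_all(ts)
  cm <- out$cell_metrics
  expect_equal(nrow(cm), 2)
  long <- cm[cm$cell_id == "long", ]
  expect_equal(long$cell_speed, cell_speed(tr1$pos, tr1$t))
  expect_equal(long$volume_rate, volume_rate(tr1$pos, tr1$t))
  short <- cm[cm$cell_id == "short", ]
  expect_true(is.na(short$msd_slope))
  expect_equal(short$cell_speed, 5 / 1.5)
  expect_equal(attr(cm, "exclusions")$msd_undefined, 1)
  # deterministic on fixed input
  out2 <- compute_all(ts)
  expect_identical(out$cell_metrics, out2$cell_metrics)
  expect_identical(out$steps, out2$steps)
})

test_that("displacement <= cell speed and the speed identity holds exactly", {
  set.seed(99)
  for (i in 1:25) {
    model <- sample(c("brownian", "persistent", "confined",
                      "back_and_forth"), 1)
    tr <- generate_track(walker_spec(model, n_steps = sample(3:20, 1)))
    cs <- cell_speed(tr$pos, tr$t)
    ds <- displacement_speed(tr$pos, tr$t)
    mr <- meandering_ratio(tr$pos)
    expect_lte(ds, cs + 1e-12)
    expect_equal(mr * cs, ds, tolerance = 1e-12)
  }
})
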