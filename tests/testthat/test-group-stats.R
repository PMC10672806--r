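test_that("identical groups give corrected p of 1 and correction caps at 1", {
  set.seed(12)
  x <- rnorm(200)
  pw <- pairwise_ranksum(list(a = x, b = x))
  expect_equal(pw$p["a", "b"], 1)
  expect_equal(diag(pw$p), c(a = 1, b = 1))
  # 4 groups -> 6 comparisons; moderate raw p values multiply past 1 and cap
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30), d = rnorm(30))
  pw4 <- pairwise_ranksum(g)
  expect_equal(pw4$n_comparisons, 6)
  expect_true(all(pw4$p >= 0 & pw4$p <= 1))
  expect_true(all(pw4$p == t(pw4$p)))
  raw <- pairwise_ranksum(g, correction = "none")
  expect_true(all(pw4$p >= raw$p))  # correction is monotone
})

test_that("well-separated samples give tiny corrected rank-sum p", {
  set.seed(7)
  a <- rnorm(200)
  b <- rnorm(200, mean = 3)
  pw <- pairwise_ranksum(list(a = a, b = b))
  expect_lt(pw$p["a", "b"], 1e-10)
})

test_that("empty groups are rejected by name", {
  expect_error(pairwise_ranksum(list(a = 1:5, bad = numeric(0))), "bad")
})

test_that("KS detects shape differences the rank-sum misses", {
  set.seed(42)
  sym <- rnorm(400)                             # unimodal, median 0
  bim <- c(rnorm(200, -3, 0.3), rnorm(200, 3, 0.3))  # bimodal, median ~0
  ks <- pairwise_ks(list(a = sym, b = bim))
  rs <- pairwise_ranksum(list(a = sym, b = bim))
  expect_lt(ks$p["a", "b"], 1e-6)
  expect_gt(rs$p["a", "b"], 0.2)
  # disjoint supports: D = 1
  ks2 <- pairwise_ks(list(lo = runif(50), hi = runif(50) + 2))
  expect_equal(ks2$stat["lo", "hi"], 1)
})

test_that("one-way ANOVA matches the textbook between/within ratio", {
  g <- list(a = c(1, 2, 3), b = c(5, 6, 10))
  res <- anova_oneway(g)
  # by hand: SSB = 37.5 (df 1), SSW = 16 (df 4) -> F = 37.5 / (16/4)
  expect_equal(res$F, 9.375)
  expect_equal(res$p, stats::pf(9.375, 1, 4, lower.tail = FALSE))
  expect_error(anova_oneway(list(a = c(2, 2), b = c(3, 3))), "degenerate")
  expect_error(anova_oneway(list(a = c(1, 2))), "2 groups")
})

test_that("ANOVA type-I error sits at the nominal level", {
  set.seed(314)
  n_sim <- 2000
  rej <- 0L
  for (i in seq_len(n_sim)) {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8), d = rnorm(8))
    if (anova_oneway(g)$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_sim, 0.03)
  expect_lt(rej / n_sim, 0.07)
})

test_that("intra/inter ANOVA groups by frame within tissue, tissue across", {
  set.seed(50)
  same <- make_frame_metrics(n_frames = 5, cells = 20, tissue = "A")
  shifted <- make_frame_metrics(n_frames = 5, cells = 20, mean = 9,
                                tissue = "B")
  m <- rbind(same, shifted)
  res <- intra_inter_anova(m, "cell_speed")
  expect_named(res$intra, c("A", "B"))
  expect_gt(res$intra$A$p, 0.01)      # homogeneous frames
  expect_lt(res$inter$p, 1e-10)       # tissues differ strongly
  # single tissue: inter absent with a warning
  expect_warning(r1 <- intra_inter_anova(same, "cell_speed"), "inter-tissue")
  expect_null(r1$inter)
  # one shifted frame: intra p small, removing it raises p
  out <- make_frame_metrics(n_frames = 5, cells = 20, shift_frame = 3)
  r2 <- suppressWarnings(intra_inter_anova(out, "cell_speed"))
  expect_lt(r2$intra$T$p, 1e-6)
  r3 <- suppressWarnings(
    intra_inter_anova(out[out$frame_id != "f03", ], "cell_speed"))
  expect_gt(r3$intra$T$p, r2$intra$T$p)
})

test_that("outlier-frame reduction removes the injected frame and raises p", {
  set.seed(77)
  m <- make_frame_metrics(n_frames = 6, cells = 15, shift_frame = 4,
                          shift = 3)
  red <- reduce_outlier_frames(m, "cell_speed")
  rep_ <- red$report$T
  expect_equal(rep_$removed[1], "f04")
  expect_false("f04" %in% red$metrics$frame_id)
  # p never decreases along accepted removals
  expect_true(all(rep_$trajectory$p_after >= rep_$trajectory$p_before))
  expect_gte(rep_$p_final, rep_$p_initial)
})

test_that("i.i.d. frames need few or no removals; ties break by frame id", {
  set.seed(123)
  m <- make_frame_metrics(n_frames = 8, cells = 30)
  red <- reduce_outlier_frames(m, "cell_speed")
  expect_lte(length(red$report$T$removed), 2)
  # exact tie: two frames with identical values mirrored around the rest
  m2 <- rbind(
    data.frame(cell_id = paste0("a", 1:4), frame_id = "f01", tissue = "T",
               cell_speed = c(1, 2, 3, 4)),
    data.frame(cell_id = paste0("b", 1:4), frame_id = "f02", tissue = "T",
               cell_speed = c(1, 2, 3, 4)),
    data.frame(cell_id = paste0("c", 1:4), frame_id = "f03", tissue = "T",
               cell_speed = c(10, 11, 12, 13)),
    data.frame(cell_id = paste0("d", 1:4), frame_id = "f04", tissue = "T",
               cell_speed = c(10, 11, 12, 13)))
  red2 <- reduce_outlier_frames(m2, "cell_speed", p_threshold = 0.9)
  rem <- red2$report$T$removed
  expect_gt(length(rem), 0)
  # f01 ties f02 and f03 ties f04; the lower id of the tied pair goes first
  expect_true(rem[1] %in% c("f01", "f03"))
})
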