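check_groups <- function(values_by_group, min_n = 1) {
  stopifnot(is.list(values_by_group), !is.null(names(values_by_group)))
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  sizes <- vapply(values_by_group, function(v) sum(is.finite(v)), integer(1))
  bad <- names(sizes)[sizes < min_n]
  if (length(bad) > 0) {
    stop("group(s) with fewer than ", min_n, " finite value(s): ",
         paste(bad, collapse = ", "))
  }
  lapply(values_by_group, function(v) v[is.finite(v)])
}

pairwise_matrix <- function(values_by_group, test_fun, test_name,
                            correction = "bonferroni") {
  correction <- match.arg(correction, c("bonferroni", "none"))
  g <- check_groups(values_by_group)
  labels <- names(g)
  k <- length(labels)
  n_comp <- k * (k - 1) / 2
  p <- matrix(1, k, k, dimnames = list(labels, labels))
  stat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      res <- suppressWarnings(test_fun(g[[i]], g[[j]]))
      praw <- res$p.value
      pc <- if (correction == "bonferroni") min(1, praw * n_comp) else praw
      p[i, j] <- p[j, i] <- pc
      stat[i, j] <- stat[j, i] <- unname(res$statistic)
    }
  }
  structure(list(labels = labels, p = p, stat = stat, test_name = test_name,
                 n_comparisons = n_comp, correction = correction),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %s, %d comparisons, %s correction\n",
              x$test_name, x$n_comparisons, x$correction))
  print(signif(x$p, 3))
  invisible(x)
}

#' Pairwise Mann-Whitney (Wilcoxon rank-sum) comparisons
#'
#' Two-sided unpaired Mann-Whitney U tests on every unordered pair of groups
#' (exact where both samples have fewer than 50 untied values, normal
#' approximation with continuity correction otherwise — the `stats::
#' wilcox.test` defaults), with Bonferroni correction: each raw p-value is
#' multiplied by the number of pairs tested and capped at 1.
#'
#' @param values_by_group named list of numeric vectors (one per group);
#'   non-finite values are dropped.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return a `pairwise_matrix`: symmetric corrected p-value matrix with unit
#'   diagonal (`$p`), the U statistics (`$stat`), test name and the number
#'   of comparisons used for correction.
#' @export
pairwise_ranksum <- function(values_by_group, correction = "bonferroni") {
  pairwise_matrix(values_by_group,
                  function(x, y) stats::wilcox.test(x, y, alternative = "two.sided"),
                  "Mann-Whitney rank sum", correction)
}

#' Pairwise two-sample Kolmogorov-Smirnov comparisons
#'
#' Compares full distributions (not just medians) for every unordered pair
#' of groups, with the same Bonferroni correction as [pairwise_ranksum()].
#' Useful where two groups share a median but differ in shape.
#'
#' @inheritParams pairwise_ranksum
#' @return a `pairwise_matrix`; `$stat` holds the KS D statistics.
#' @export
pairwise_ks <- function(values_by_group, correction = "bonferroni") {
  pairwise_matrix(values_by_group,
                  function(x, y) stats::ks.test(x, y),
                  "Kolmogorov-Smirnov", correction)
}

#' Classical one-way ANOVA
#'
#' Equal-variance one-way analysis of variance: F is the ratio of the
#' between-group to the within-group mean square, compared against the F
#' distribution. Requires at least 2 groups, each with at least 2 finite
#' values, and nonzero pooled within-group variance (otherwise a
#' degenerate-input error).
#'
#' @param values_by_group named list of numeric vectors.
#' @return object of class `anova_result`: list with `F`, `p`, `df` (numeric
#'   length 2), `group_sizes`, `groups`.
#' @export
anova_oneway <- function(values_by_group) {
  g <- check_groups(values_by_group, min_n = 2)
  within_ss <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  if (within_ss <= 0) stop("degenerate input: zero within-group variance")
  values <- unlist(g, use.names = FALSE)
  grp <- factor(rep(names(g), lengths(g)))
  ft <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  structure(list(F = unname(ft$statistic), p = ft$p.value,
                 df = unname(ft$parameter),
                 group_sizes = lengths(g), groups = names(g)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%g, %g) = %.4g, p = %.3g (%d groups)\n",
              x$df[1], x$df[2], x$F, x$p, length(x$groups)))
  invisible(x)
}

# per-tissue metric values grouped by frame, with NA/undersized frames dropped
frame_groups <- function(metrics, metric_name, tissue) {
  m <- metrics[metrics$tissue == tissue & is.finite(metrics[[metric_name]]), ]
  g <- split(m[[metric_name]], m$frame_id)
  g[lengths(g) >= 2]
}

#' Intra- and inter-tissue one-way ANOVA of a cell metric
#'
#' Intra-tissue: within each tissue, groups are imaging frames (fields) and
#' observations are that frame's per-cell metric values — a small p flags
#' frame-to-frame heterogeneity. Inter-tissue: groups are tissues with frames
#' pooled. Tissues with fewer than 2 usable frames are skipped with a
#' warning; the inter-tissue test is omitted (with a warning) when fewer than
#' 2 tissues are present.
#'
#' @param metrics per-cell metrics data.frame (see [compute_all()]).
#' @param metric_name name of the metric column to test (e.g.
#'   `"cell_speed"`).
#' @return list with `intra` (named list of `anova_result`, one per tissue)
#'   and `inter` (an `anova_result`, or `NULL`).
#' @export
intra_inter_anova <- function(metrics, metric_name = "cell_speed") {
  stopifnot(metric_name %in% names(metrics))
  tissues <- sort(unique(metrics$tissue))
  intra <- list()
  for (ti in tissues) {
    g <- frame_groups(metrics, metric_name, ti)
    if (length(g) < 2) {
      warning("tissue '", ti, "' has fewer than 2 usable frames; skipped")
      next
    }
    intra[[ti]] <- anova_oneway(g)
  }
  inter <- NULL
  by_tissue <- split(metrics[[metric_name]][is.finite(metrics[[metric_name]])],
                     metrics$tissue[is.finite(metrics[[metric_name]])])
  by_tissue <- by_tissue[lengths(by_tissue) >= 2]
  if (length(by_tissue) >= 2) {
    inter <- anova_oneway(by_tissue)
  } else {
    warning("fewer than 2 tissues with data; inter-tissue ANOVA omitted")
  }
  list(intra = intra, inter = inter)
}

#' Greedy removal of outlier imaging frames
#'
#' Within each tissue, repeatedly removes the frame whose exclusion maximally
#' increases the intra-tissue ANOVA p-value of the chosen metric, until the
#' p-value reaches `p_threshold`, a `max_frac_removed` fraction of the
#' tissue's frames has been removed, or no removal raises the p-value. Ties
#' are broken deterministically in favour of the lexicographically smaller
#' frame id. A tissue whose stop rule cannot be reached returns its
#' best-effort reduction flagged with `reached = FALSE`.
#'
#' @param metrics per-cell metrics data.frame.
#' @param metric_name metric column used for the ANOVA.
#' @param p_threshold stop once the intra-tissue p-value is at least this
#'   (default 1e-4).
#' @param max_frac_removed maximum fraction of a tissue's frames that may be
#'   removed (default 0.55).
#' @return list with `metrics` (the reduced per-cell table, outlier frames
#'   dropped) and `report`, a per-tissue list of class `reduction_report`
#'   entries: `removed` (frame ids in removal order), `trajectory`
#'   (data.frame of `step`, `removed_frame`, `p_before`, `p_after`),
#'   `retained_frames`, `retained_cells`, `p_initial`, `p_final`, `reached`.
#' @export
reduce_outlier_frames <- function(metrics, metric_name = "cell_speed",
                                  p_threshold = 1e-4,
                                  max_frac_removed = 0.55) {
  stopifnot(metric_name %in% names(metrics))
  tissues <- sort(unique(metrics$tissue))
  report <- list()
  drop_frames <- character(0)
  for (ti in tissues) {
    g0 <- frame_groups(metrics, metric_name, ti)
    n0 <- length(g0)
    kept <- sort(names(g0))
    removed <- character(0)
    traj <- data.frame(step = integer(), removed_frame = character(),
                       p_before = numeric(), p_after = numeric(),
                       stringsAsFactors = FALSE)
    reached <- FALSE
    if (n0 < 3) {
      p_cur <- if (n0 >= 2) anova_oneway(g0[kept])$p else NA_real_
      report[[ti]] <- structure(
        list(removed = removed, trajectory = traj, retained_frames = kept,
             retained_cells = sum(metrics$tissue == ti &
                                    metrics$frame_id %in% kept),
             p_initial = p_cur, p_final = p_cur,
             reached = isTRUE(p_cur >= p_threshold)),
        class = "reduction_report")
      next
    }
    p_cur <- anova_oneway(g0[kept])$p
    p_init <- p_cur
    repeat {
      if (p_cur >= p_threshold) { reached <- TRUE; break }
      if ((length(removed) + 1) / n0 > max_frac_removed) break
      if (length(kept) <= 2) break
      cand_p <- vapply(kept, function(f) {
        tryCatch(anova_oneway(g0[setdiff(kept, f)])$p,
                 error = function(e) NA_real_)
      }, numeric(1))
      if (all(is.na(cand_p))) break
      best <- which.max(cand_p)  # first max: kept is sorted, so lower id wins ties
      if (is.na(cand_p[best]) || cand_p[best] < p_cur) break
      removed <- c(removed, kept[best])
      traj <- rbind(traj, data.frame(step = length(removed),
                                     removed_frame = kept[best],
                                     p_before = p_cur,
                                     p_after = cand_p[best],
                                     stringsAsFactors = FALSE))
      p_cur <- cand_p[best]
      kept <- setdiff(kept, kept[best])
    }
    drop_frames <- c(drop_frames, paste(ti, removed, sep = "\r"))
    report[[ti]] <- structure(
      list(removed = removed, trajectory = traj, retained_frames = kept,
           retained_cells = sum(metrics$tissue == ti &
                                  metrics$frame_id %in% kept),
           p_initial = p_init, p_final = p_cur, reached = reached),
      class = "reduction_report")
  }
  keep_row <- !(paste(metrics$tissue, metrics$frame_id, sep = "\r") %in%
                  drop_frames)
  list(metrics = metrics[keep_row, , drop = FALSE], report = report)
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report> removed %d frame(s): %s\n",
              length(x$removed),
              if (length(x$removed)) paste(x$removed, collapse = ", ")
              else "(none)"))
  cat(sprintf("  p: %.3g -> %.3g (threshold reached: %s)\n",
              x$p_initial, x$p_final, x$reached))
  invisible(x)
}
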