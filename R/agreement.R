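#' Waveform and trajectory agreement statistics
#'
#' The linear fit method (LFM) regresses the test waveform on the reference
#' waveform (here: BVR on OMC) and reports the strength of linear fit (R^2),
#' the offset (a0, intercept) and the amplitude scaling (a1, slope); two
#' identical waveforms give R^2 = 1, a0 = 0, a1 = 1 and RMSE = 0. Marker
#' trajectory agreement is summarized as per-marker RMS 3D differences with
#' per-axis directional components. Note the RMS is the root of the mean
#' squared difference (reported in mm, not mm^2).
#'
#' @name agreement
NULL

#' Linear fit method between two waveforms
#'
#' Ordinary least squares of \code{test} on \code{reference}
#' (\code{test ~ a1 * reference + a0}) over the shared valid (non-missing)
#' samples.
#'
#' @param reference,test equal-length numeric waveforms (NA = outside the
#'   valid window).
#' @return list (class \code{lfm_result}): \code{r2}, \code{a0}, \code{a1},
#'   \code{n}.
#' @export
lfm <- function(reference, test) {
  if (length(reference) != length(test)) stop("waveforms differ in length")
  ok <- is.finite(reference) & is.finite(test)
  if (sum(ok) < 3) stop("need at least 3 shared valid samples")
  x <- reference[ok]; y <- test[ok]
  if (stats::sd(x) == 0) stop("constant reference waveform")
  fit <- stats::lm(y ~ x)
  # coefficient of determination computed directly: summary.lm warns on the
  # perfect fits that the identity comparisons legitimately produce
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst   # constant test: no shared variance
  structure(list(r2 = r2,
                 a0 = unname(stats::coef(fit)[1]),
                 a1 = unname(stats::coef(fit)[2]),
                 n = sum(ok)),
            class = "lfm_result")
}

#' Root mean squared error between two waveforms
#' @param w1,w2 equal-length numeric waveforms (NA = invalid samples).
#' @return RMSE over the shared valid samples (degrees for angle waveforms).
#' @export
rmse <- function(w1, w2) {
  if (length(w1) != length(w2)) stop("waveforms differ in length")
  ok <- is.finite(w1) & is.finite(w2)
  if (!any(ok)) stop("no shared valid samples")
  sqrt(mean((w1[ok] - w2[ok])^2))
}

#' RMS marker-trajectory differences with directional components
#'
#' Per marker, the root mean (over frames visible in both sets) of the
#' squared 3D distance between the two systems, plus the per-axis RMS
#' components along X (anterior-posterior), Y (medial-lateral) and Z
#' (superior-inferior).
#'
#' @param omc,bvr co-registered, synchronized \code{marker_set}s on the same
#'   frame grid.
#' @param window optional frame indices to restrict to (e.g. the span where
#'   tracking is present in all trials).
#' @return data.frame: marker, n_frames, rms_3d, rms_x, rms_y, rms_z (mm).
#' @export
rms_marker_difference <- function(omc, bvr, window = NULL) {
  common <- intersect(omc$names, bvr$names)
  if (!length(common)) stop("no common markers")
  n <- dim(omc$pos)[1]
  if (dim(bvr$pos)[1] != n) stop("marker sets differ in frame count")
  idx <- if (is.null(window)) seq_len(n) else intersect(window, seq_len(n))
  rows <- lapply(common, function(m) {
    ok <- idx[!omc$occluded[idx, m] & !bvr$occluded[idx, m]]
    if (!length(ok)) stop("no common visible frames for marker ", m)
    d <- omc$pos[ok, , m, drop = FALSE] - bvr$pos[ok, , m, drop = FALSE]
    d <- array(d, c(length(ok), 3))
    data.frame(marker = m, n_frames = length(ok),
               rms_3d = sqrt(mean(rowSums(d^2))),
               rms_x = sqrt(mean(d[, 1]^2)),
               rms_y = sqrt(mean(d[, 2]^2)),
               rms_z = sqrt(mean(d[, 3]^2)))
  })
  do.call(rbind, rows)
}

#' Aggregate per-trial agreement and run group tests
#'
#' Summarizes per-trial marker RMS differences and angle statistics by
#' condition (walking/running): group means and SDs, Shapiro-Wilk normality
#' of the RMS distributions, a Wilcoxon rank-sum test ("non-parametric
#' t-test") of walking vs running RMS, and a Kruskal-Wallis test across the
#' X/Y/Z directional components. All statistics are reported without
#' significance gatekeeping; tests that lack enough trials are skipped with
#' an explicit flag.
#'
#' @param marker_reports named list (by condition) of lists of per-trial
#'   data.frames from \code{rms_marker_difference}.
#' @param angle_reports optional named list (by condition) of lists of
#'   per-trial angle statistic data.frames (angle, r2, a0, a1, rmse).
#' @return list (class \code{agreement_report}): \code{marker_summary},
#'   \code{angle_summary}, \code{tests}.
#' @export
aggregate_and_test <- function(marker_reports, angle_reports = NULL) {
  summarize_cond <- function(trials) {
    all <- do.call(rbind, trials)
    agg_m <- stats::aggregate(rms_3d ~ marker, all, mean)
    agg_s <- stats::aggregate(rms_3d ~ marker, all, stats::sd)
    dirs <- stats::aggregate(cbind(rms_x, rms_y, rms_z) ~ marker, all, mean)
    out <- merge(merge(agg_m, agg_s, by = "marker",
                       suffixes = c("_mean", "_sd")), dirs, by = "marker")
    out
  }
  marker_summary <- lapply(marker_reports, summarize_cond)
  angle_summary <- NULL
  if (!is.null(angle_reports)) {
    angle_summary <- lapply(angle_reports, function(trials) {
      all <- do.call(rbind, trials)
      cbind(stats::aggregate(cbind(r2, a0, a1, rmse) ~ angle, all, mean),
            n = as.vector(table(all$angle)[sort(unique(all$angle))]))
    })
  }
  # per-trial mean RMS (across markers) by condition
  trial_means <- lapply(marker_reports, function(trials) {
    vapply(trials, function(df) mean(df$rms_3d), numeric(1))
  })
  tests <- list(skipped = FALSE)
  conds <- names(trial_means)
  if (length(conds) == 2 && all(lengths(trial_means) >= 2)) {
    sw <- lapply(trial_means, function(x) {
      if (length(x) >= 3 && stats::sd(x) > 0) stats::shapiro.test(x)
      else NULL
    })
    wt <- stats::wilcox.test(trial_means[[1]], trial_means[[2]],
                             exact = FALSE)
    tests$shapiro <- lapply(sw, function(s) {
      if (is.null(s)) NULL else list(W = unname(s$statistic),
                                     p = s$p.value)
    })
    tests$condition_rms <- list(statistic = unname(wt$statistic),
                                p = wt$p.value,
                                conditions = conds)
  } else {
    tests$skipped <- TRUE
  }
  # directional components across all trials and conditions
  dir_df <- do.call(rbind, lapply(conds, function(cn) {
    do.call(rbind, lapply(marker_reports[[cn]], function(df) {
      data.frame(value = c(df$rms_x, df$rms_y, df$rms_z),
                 axis = rep(c("X", "Y", "Z"), each = nrow(df)))
    }))
  }))
  if (!is.null(dir_df) && length(unique(dir_df$axis)) == 3 &&
      nrow(dir_df) >= 6) {
    kw <- stats::kruskal.test(value ~ axis, data = dir_df)
    tests$directional <- list(statistic = unname(kw$statistic),
                              p = kw$p.value)
  }
  structure(list(marker_summary = marker_summary,
                 angle_summary = angle_summary, tests = tests,
                 trial_means = trial_means),
            class = "agreement_report")
}
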