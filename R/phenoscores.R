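# Behavioral and physiology scores: climbing (SING), olfactory preference,
# dF/F calcium traces with activity metrics, and the chronic-dose
# calculator for drug feeding experiments.

#' Startle-induced negative geotaxis (SING) score
#'
#' Flies climb through five stacked tubes; the score is the tube-weighted
#' count `(n1 + 2 n2 + 3 n3 + 4 n4 + 5 n5) / (5 * total)`, ranging from
#' 0.2 (all flies stay in tube 1) to 1 (all reach tube 5).
#'
#' @param counts numeric vector of length 5 (flies per tube, bottom to
#'   top), or a data frame with columns `tube1`..`tube5` (one score per
#'   row).
#' @return A tibble `total`, `score`.
#' @export
sing_score <- function(counts) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[paste0("tube", 1:5)])
  } else {
    assert_that(length(counts) == 5, "need counts for 5 tubes")
    m <- matrix(counts, nrow = 1)
  }
  assert_that(all(m >= 0), "tube counts must be non-negative")
  total <- rowSums(m)
  assert_that(all(total > 0), "total fly count must be positive")
  tibble::tibble(total = total,
                 score = as.numeric(m %*% (1:5)) / (5 * total))
}

#' Olfactory preference index
#'
#' `(n_a - n_b) / total`: +1 when every fly chooses odor A, -1 for odor B,
#' 0 for indifference. Flies choosing neither tube dilute the index.
#'
#' @param n_a,n_b flies in the two odor tubes.
#' @param total total flies tested (>= n_a + n_b).
#' @return A tibble `n_a`, `n_b`, `total`, `index`.
#' @export
preference_index <- function(n_a, n_b, total = n_a + n_b) {
  assert_that(all(total > 0), "total fly count must be positive")
  assert_that(all(n_a + n_b <= total), "n_a + n_b cannot exceed total")
  tibble::tibble(n_a = n_a, n_b = n_b, total = total,
                 index = (n_a - n_b) / total)
}

#' Fractional fluorescence change (dF/F)
#'
#' Per ROI, the basal fluorescence F0 is either the mean of the five
#' frames preceding the stimulus (`prestim_mean5`, in vivo convention) or
#' the minimal 5-frame rolling mean over the whole trace (`min_mean5`,
#' spontaneous-activity convention); dF/F = (F - F0) / F0.
#'
#' @param traces a [generate_traces()] `trace_set`, or a frames x ROI
#'   numeric matrix.
#' @param baseline_mode `"prestim_mean5"` or `"min_mean5"`.
#' @param stim_frame stimulus-onset frame (required for prestim mode; the
#'   five frames before it form the baseline).
#' @return A frames x ROI matrix of dF/F values, with the per-ROI baseline
#'   frames attached as attribute `baseline_frames`.
#' @export
dff_trace <- function(traces, baseline_mode = c("prestim_mean5", "min_mean5"),
                      stim_frame = NULL) {
  baseline_mode <- match.arg(baseline_mode)
  F <- if (inherits(traces, "trace_set")) traces$F else as.matrix(traces)
  n_frames <- nrow(F)
  assert_that(n_frames >= 6, "need at least 6 frames for a 5-frame baseline")
  if (baseline_mode == "prestim_mean5") {
    assert_that(!is.null(stim_frame) && stim_frame >= 6,
                "prestim mode needs a stimulus frame with >= 5 frames before it")
    bl_frames <- lapply(seq_len(ncol(F)), function(j) (stim_frame - 5):(stim_frame - 1))
    F0 <- colMeans(F[(stim_frame - 5):(stim_frame - 1), , drop = FALSE])
  } else {
    # minimal 5-frame window mean per ROI; mean() per window keeps a
    # constant trace's baseline exactly equal to its level
    n_win <- n_frames - 4
    roll <- vapply(seq_len(ncol(F)), function(j) {
      vapply(seq_len(n_win), function(s) mean(F[s:(s + 4), j]), numeric(1))
    }, numeric(n_win))
    roll <- matrix(roll, nrow = n_win)
    w <- apply(roll, 2, which.min)
    F0 <- roll[cbind(w, seq_len(ncol(F)))]
    bl_frames <- lapply(seq_len(ncol(F)), function(j) w[j]:(w[j] + 4))
  }
  if (any(F0 <= 0)) stop("non-positive baseline fluorescence F0", call. = FALSE)
  dff <- sweep(sweep(F, 2, F0, "-"), 2, F0, "/")
  attr(dff, "baseline_frames") <- bl_frames
  dff
}

#' Activity fraction and maximal amplitude per ROI
#'
#' Frames with dF/F above `k_sd` times the SD of the baseline frames count
#' as active; activity is active frames / total frames, and the amplitude
#' is the maximal dF/F of the trace.
#'
#' @param dff frames x ROI dF/F matrix (e.g. from [dff_trace()]).
#' @param baseline_frames integer frame indices defining the baseline, or
#'   a per-ROI list; defaults to the attribute [dff_trace()] attaches.
#' @param k_sd activity threshold in baseline SDs.
#' @return A tibble `roi`, `threshold`, `activity`, `amplitude`,
#'   `flat_baseline` (TRUE when the baseline SD is zero and the threshold
#'   degenerates to 0).
#' @export
activity_metrics <- function(dff, baseline_frames = NULL, k_sd = 2) {
  dff <- as.matrix(dff)
  baseline_frames <- baseline_frames %||% attr(dff, "baseline_frames")
  assert_that(!is.null(baseline_frames), "baseline frames must be supplied")
  if (!is.list(baseline_frames)) {
    baseline_frames <- rep(list(as.integer(baseline_frames)), ncol(dff))
  }
  assert_that(all(unlist(baseline_frames) >= 1) &&
                all(unlist(baseline_frames) <= nrow(dff)),
              "baseline frames outside the trace")
  rows <- lapply(seq_len(ncol(dff)), function(j) {
    v <- dff[, j]
    thr <- k_sd * stats::sd(v[baseline_frames[[j]]])
    tibble::tibble(roi = j, threshold = thr,
                   activity = mean(v > thr),
                   amplitude = max(v),
                   flat_baseline = thr == 0)
  })
  dplyr::bind_rows(rows)
}

#' Daily dose from food concentration
#'
#' Chronic-feeding dose arithmetic: a compound mixed into food at
#' `concentration` (amount per ml food) eaten at `food_ul_per_day`
#' microliters per day by an animal of `body_weight_mg` milligrams gives a
#' daily dose of `concentration * food_ul_per_day / 1000 / body_weight_mg`
#' per mg body weight. Defaults are the fly nicotine-feeding regime:
#' 0.2 per ml food, ~1 ul food per day, ~0.1 mg fly.
#'
#' @param concentration_per_ml compound amount per ml of food.
#' @param food_ul_per_day food intake in microliters per day.
#' @param body_weight_mg body weight in milligrams.
#' @return Daily dose per mg body weight (same amount unit as
#'   `concentration_per_ml`).
#' @export
daily_dose <- function(concentration_per_ml = 0.2, food_ul_per_day = 1,
                       body_weight_mg = 0.1) {
  assert_that(all(body_weight_mg > 0), "body weight must be positive")
  concentration_per_ml * (food_ul_per_day / 1000) / body_weight_mg
}
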