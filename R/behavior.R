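# Freezing scoring from frame-wise activity traces.
#
# A frame is inactive when its activity score is at or below the threshold
# (ties count as inactive; configurable). Percent freezing is computed over
# sequential 10-s epochs as the percentage of inactive frames; bouts are
# maximal inactive runs of >= 2 s computed from the unbinned mask.

#' Freezing-analysis configuration
#'
#' @param activity_threshold score at or below which a frame counts as
#'   inactive. The tracking software leaves this to the analyst; there is no
#'   canonical value, so it must be chosen per dataset.
#' @param epoch_s epoch length for percent-freezing bins (default 10 s).
#' @param min_bout_s minimum duration of a freezing bout (default 2 s).
#' @param tie_inactive whether a score exactly equal to the threshold counts
#'   as inactive (default TRUE).
#' @param pre_window,post_window optional `(start_s, end_s)` windows for
#'   [pre_post_change()].
#' @return object of class `freezing_config`.
#' @export
freezing_config <- function(activity_threshold, epoch_s = 10, min_bout_s = 2,
                            tie_inactive = TRUE,
                            pre_window = NULL, post_window = NULL) {
  assert_that(activity_threshold >= 0, "activity_threshold must be >= 0")
  assert_that(epoch_s > 0, "epoch_s must be > 0")
  assert_that(min_bout_s > 0, "min_bout_s must be > 0")
  structure(list(activity_threshold = activity_threshold, epoch_s = epoch_s,
                 min_bout_s = min_bout_s, tie_inactive = tie_inactive,
                 pre_window = pre_window, post_window = post_window),
            class = "freezing_config")
}

validate_trace <- function(trace) {
  assert_that(is.list(trace) &&
                all(c("time_s", "activity_score", "frame_rate") %in% names(trace)),
              "trace needs time_s, activity_score and frame_rate")
  n <- length(trace$activity_score)
  assert_that(n > 0, "empty trace")
  assert_that(length(trace$time_s) == n, "time_s and activity_score differ in length")
  assert_that(all(is.finite(trace$activity_score)), "activity scores must be finite")
  assert_that(all(diff(trace$time_s) > 0), "time must be strictly increasing")
  if (n > 1) {
    dt <- diff(trace$time_s)
    assert_that(max(abs(dt - 1 / trace$frame_rate)) < 0.25 / trace$frame_rate,
                "frame spacing is not uniform at the stated frame rate")
  }
  invisible(trace)
}

#' Classify frames as inactive
#'
#' @param trace an activity trace (list with `time_s`, `activity_score`,
#'   `frame_rate`).
#' @param cfg a [freezing_config()].
#' @return logical vector, one element per frame; `TRUE` = inactive.
#' @export
score_inactivity <- function(trace, cfg) {
  validate_trace(trace)
  if (isTRUE(cfg$tie_inactive)) {
    trace$activity_score <= cfg$activity_threshold
  } else {
    trace$activity_score < cfg$activity_threshold
  }
}

#' Percent freezing per sequential epoch
#'
#' Epochs are back-to-back bins of `epoch_s` starting at the first frame.
#' Only complete epochs are reported in the main vector; a trailing partial
#' epoch, if any, is attached as the `"partial"` attribute (its own percent
#' and frame count) and excluded from group averages downstream.
#'
#' @param inactive logical per-frame mask from [score_inactivity()].
#' @param frame_rate frames per second.
#' @param epoch_s epoch length in seconds.
#' @return numeric vector of percentages (one per complete epoch) with
#'   attributes `epoch_s`, `start_s` (epoch start times) and optionally
#'   `partial`.
#' @export
epoch_percent_freezing <- function(inactive, frame_rate, epoch_s = 10) {
  assert_that(frame_rate > 0, "frame_rate must be > 0")
  assert_that(length(inactive) > 0, "empty inactivity mask")
  per_epoch <- round(epoch_s * frame_rate)
  assert_that(per_epoch >= 1, "epoch shorter than one frame")
  n <- length(inactive)
  n_full <- n %/% per_epoch
  pct <- numeric(n_full)
  if (n_full > 0) {
    m <- matrix(inactive[seq_len(n_full * per_epoch)], nrow = per_epoch)
    pct <- 100 * colMeans(m)
  }
  attr(pct, "epoch_s") <- epoch_s
  attr(pct, "start_s") <- (seq_len(n_full) - 1) * epoch_s
  rem <- n - n_full * per_epoch
  if (rem > 0) {
    tail_mask <- inactive[(n_full * per_epoch + 1):n]
    attr(pct, "partial") <- list(percent = 100 * mean(tail_mask), n_frames = rem)
  }
  pct
}

#' Detect freezing bouts
#'
#' Maximal runs of consecutive inactive frames lasting at least `min_bout_s`,
#' in temporal order, computed from the unbinned mask. Bout start is the time
#' of its first inactive frame; duration is the run length over the frame
#' rate.
#'
#' @inheritParams epoch_percent_freezing
#' @param min_bout_s minimum bout duration in seconds.
#' @return data.frame with columns `start_s`, `duration_s`.
#' @export
detect_bouts <- function(inactive, frame_rate, min_bout_s = 2) {
  assert_that(frame_rate > 0, "frame_rate must be > 0")
  assert_that(length(inactive) > 0, "empty inactivity mask")
  r <- rle(as.logical(inactive))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / frame_rate >= min_bout_s)
  data.frame(start_s = (starts[keep] - 1L) / frame_rate,
             duration_s = r$lengths[keep] / frame_rate)
}

#' Mean percent freezing over a time window
#'
#' Unweighted mean of the complete epochs lying fully inside
#' `[start_s, end_s]`.
#'
#' @param epoch_percent output of [epoch_percent_freezing()].
#' @param window numeric `(start_s, end_s)`.
#' @param epoch_s epoch length; taken from the input's attribute when absent.
#' @return mean percentage.
#' @export
window_mean <- function(epoch_percent, window, epoch_s = NULL) {
  epoch_s <- epoch_s %||% attr(epoch_percent, "epoch_s")
  assert_that(!is.null(epoch_s), "epoch_s unknown; pass it explicitly")
  assert_that(length(window) == 2 && window[2] > window[1],
              "window must be (start_s, end_s) with end > start")
  start_s <- attr(epoch_percent, "start_s") %||%
    ((seq_along(epoch_percent) - 1) * epoch_s)
  tol <- 1e-9
  sel <- start_s >= window[1] - tol & (start_s + epoch_s) <= window[2] + tol
  assert_that(any(sel), sprintf("window [%g, %g] contains no complete epoch",
                                window[1], window[2]))
  mean(epoch_percent[sel])
}

#' Change in freezing between two windows
#'
#' `window_mean(post) - window_mean(pre)`: e.g. the last 30 s of acquisition
#' minus the 30 s before the first tone-shock pairing.
#'
#' @inheritParams window_mean
#' @param pre_window,post_window numeric `(start_s, end_s)` windows.
#' @return change in percentage points (post minus pre).
#' @export
pre_post_change <- function(epoch_percent, pre_window, post_window,
                            epoch_s = NULL) {
  window_mean(epoch_percent, post_window, epoch_s) -
    window_mean(epoch_percent, pre_window, epoch_s)
}

#' Score freezing for one trace
#'
#' Convenience wrapper producing the full freezing result: per-frame mask,
#' epoch percentages, bout list, and any configured window means.
#'
#' @param trace an activity trace.
#' @param cfg a [freezing_config()].
#' @param windows named list of `(start_s, end_s)` windows to summarize
#'   (defaults to the config's pre/post windows when set).
#' @return object of class `freezing_result`.
#' @export
score_freezing <- function(trace, cfg, windows = NULL) {
  inactive <- score_inactivity(trace, cfg)
  pct <- epoch_percent_freezing(inactive, trace$frame_rate, cfg$epoch_s)
  bouts <- detect_bouts(inactive, trace$frame_rate, cfg$min_bout_s)
  if (is.null(windows)) {
    windows <- list()
    if (!is.null(cfg$pre_window)) windows$pre <- cfg$pre_window
    if (!is.null(cfg$post_window)) windows$post <- cfg$post_window
  }
  wm <- lapply(windows, function(w) window_mean(pct, w, cfg$epoch_s))
  structure(list(subject_id = trace$subject_id %||% NA_character_,
                 group = trace$group %||% NA_character_,
                 session = trace$session %||% NA_character_,
                 inactive = inactive, epoch_percent = pct, bouts = bouts,
                 window_means = wm),
            class = "freezing_result")
}

#' @export
print.freezing_result <- function(x, ...) {
  cat(sprintf("<freezing_result %s/%s  %d epochs, %d bouts, overall %.1f%%>\n",
              x$subject_id, x$session, length(x$epoch_percent), nrow(x$bouts),
              100 * mean(x$inactive)))
  invisible(x)
}
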