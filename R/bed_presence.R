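#' Calibrate per-resident bed-presence thresholds
#'
#' Body movements disturb the load-cell signal while the bed is occupied,
#' so over a night the windowed median weight \code{m_w} and windowed
#' standard deviation \code{sigma_w} each form two clusters (occupied
#' versus empty). Calibration runs the Otsu algorithm independently on each
#' statistic to obtain the per-resident thresholds \code{O_m_w} and
#' \code{O_sigma_w} used by [bed_presence()].
#'
#' Calibration requires windows covering both occupied and unoccupied
#' periods: if either statistic's distribution is not clearly bimodal
#' (Otsu separability below \code{min_separability}) calibration fails with
#' a diagnostic, since a threshold cut through a single cluster would be
#' arbitrary.
#'
#' @param windows data.frame of window statistics as produced by
#'   [loadcell_windows()] (columns \code{m_w}, \code{sigma_w}).
#' @param n_bins Histogram bins for Otsu (default 256).
#' @param min_separability Minimum Otsu effectiveness (between-class over
#'   total variance) for each statistic; default 0.8. A unimodal Gaussian
#'   tops out near 0.64, well-separated clusters approach 1.
#' @return List of class \code{bed_thresholds}: \code{O_m_w},
#'   \code{O_sigma_w} (kg), and the two separability diagnostics.
#' @export
calibrate_thresholds <- function(windows, n_bins = 256L,
                                 min_separability = 0.8) {
  stopifnot(is.data.frame(windows),
            all(c("m_w", "sigma_w") %in% names(windows)))
  sep_m <- tryCatch(otsu_separability(windows$m_w, n_bins),
                    error = function(e) 0)
  sep_s <- tryCatch(otsu_separability(windows$sigma_w, n_bins),
                    error = function(e) 0)
  if (sep_m < min_separability || sep_s < min_separability)
    stopf(paste0("calibration windows are not bimodal: Otsu separability ",
                 "m_w = %.3f, sigma_w = %.3f (need >= %.2f); the ",
                 "calibration period must contain both occupied and ",
                 "unoccupied intervals"),
          sep_m, sep_s, min_separability)
  structure(
    list(O_m_w = otsu_threshold(windows$m_w, n_bins),
         O_sigma_w = otsu_threshold(windows$sigma_w, n_bins),
         separability_m_w = sep_m, separability_sigma_w = sep_s,
         n_windows = nrow(windows)),
    class = "bed_thresholds")
}

#' @export
print.bed_thresholds <- function(x, ...) {
  cat("Bed-presence thresholds (Otsu-calibrated)\n")
  cat(sprintf("  O_m_w     = %.4f kg  (separability %.3f)\n",
              x$O_m_w, x$separability_m_w))
  cat(sprintf("  O_sigma_w = %.4f kg  (separability %.3f)\n",
              x$O_sigma_w, x$separability_sigma_w))
  cat(sprintf("  calibrated on %d windows\n", x$n_windows))
  invisible(x)
}

#' Evaluate the bed-presence condition
#'
#' The presence rule: the bed is occupied in a window iff both the windowed
#' standard deviation and the windowed median weight reach their
#' thresholds,
#' \deqn{Presence = (\sigma_w \ge O_{\sigma_w}) \; AND \; (m_w \ge O_{m_w}).}
#' Both comparisons are inclusive. Vectorised over windows.
#'
#' @param m_w Median weight per window (kg).
#' @param sigma_w Standard deviation per window (kg).
#' @param thresholds A \code{bed_thresholds} object (or list with
#'   \code{O_m_w}, \code{O_sigma_w}).
#' @return Logical vector: \code{TRUE} = present.
#' @export
bed_presence <- function(m_w, sigma_w, thresholds) {
  (sigma_w >= thresholds$O_sigma_w) & (m_w >= thresholds$O_m_w)
}

#' Streaming bed-exit/entrance detector
#'
#' A stateful detector evaluated once per completed window (every half
#' second at 80 Hz with 40-sample windows). It tracks the presence state
#' and emits a \code{Bout} event on a present-to-absent change and
#' \code{Bin} on absent-to-present. The first window only initialises the
#' state; no event is emitted for the initial assignment. With
#' \code{confirm > 1} a change must persist for that many consecutive
#' windows before it is emitted (debounce); the emitted timestamp is the
#' end of the first window of the confirmed run.
#'
#' If \code{engine} is given, emitted events are also published on the
#' engine channel \code{channel} (payload: list with \code{ts},
#' \code{symbol}).
#'
#' @param thresholds A \code{bed_thresholds} object.
#' @param confirm Consecutive windows required to confirm a change
#'   (default 1: every window decision counts).
#' @param engine Optional [eca_engine()] to notify.
#' @param channel Channel name for notifications (default
#'   \code{"bed_events"}).
#' @return An object of class \code{bed_detector}.
#' @seealso [detector_step()], [detect_bed_events()]
#' @export
bed_detector <- function(thresholds, confirm = 1L, engine = NULL,
                         channel = "bed_events") {
  stopifnot(is_count(confirm))
  det <- new.env(parent = emptyenv())
  det$thresholds <- thresholds
  det$confirm <- as.integer(confirm)
  det$present <- NA            # unknown until first evaluation
  det$pending_state <- NA
  det$pending_count <- 0L
  det$pending_ts <- NA
  det$last_change_ts <- NA
  det$engine <- engine
  det$channel <- channel
  class(det) <- "bed_detector"
  det
}

#' Advance the detector by one window
#'
#' @param det A [bed_detector()].
#' @param m_w,sigma_w Statistics of the completed window (kg).
#' @param ts Timestamp of the window end.
#' @return \code{NULL}, or a list \code{(ts, symbol)} with \code{symbol}
#'   \code{"Bin"} or \code{"Bout"} when a state change is confirmed.
#' @export
detector_step <- function(det, m_w, sigma_w, ts) {
  now <- bed_presence(m_w, sigma_w, det$thresholds)
  if (is.na(det$present)) {           # initial assignment, no event
    det$present <- now
    det$last_change_ts <- ts
    return(invisible(NULL))
  }
  if (now == det$present) {
    det$pending_state <- NA
    det$pending_count <- 0L
    return(invisible(NULL))
  }
  if (!identical(det$pending_state, now)) {
    det$pending_state <- now
    det$pending_count <- 1L
    det$pending_ts <- ts
  } else {
    det$pending_count <- det$pending_count + 1L
  }
  if (det$pending_count < det$confirm) return(invisible(NULL))
  det$present <- now
  det$last_change_ts <- det$pending_ts
  ev <- list(ts = det$pending_ts, symbol = if (now) "Bin" else "Bout")
  det$pending_state <- NA
  det$pending_count <- 0L
  if (!is.null(det$engine)) engine_notify(det$engine, det$channel, ev)
  ev
}

#' Detect bed entrances and exits over a stream of windows
#'
#' Runs [detector_step()] over every row of a window-statistics frame and
#' collects the emitted events. Nights are processed independently: create
#' a fresh detector per night.
#'
#' @param windows data.frame from [loadcell_windows()] (columns \code{m_w},
#'   \code{sigma_w}, \code{window_end_ts}).
#' @param thresholds A \code{bed_thresholds} object.
#' @param confirm Confirmation count, see [bed_detector()].
#' @param engine,channel Optional engine notification, see
#'   [bed_detector()].
#' @return data.frame with columns \code{ts}, \code{symbol}
#'   (\code{Bin}/\code{Bout}); zero rows if no change occurred.
#' @export
detect_bed_events <- function(windows, thresholds, confirm = 1L,
                              engine = NULL, channel = "bed_events") {
  det <- bed_detector(thresholds, confirm, engine, channel)
  out_ts <- vector("list", 0L)
  out_sym <- character(0)
  for (i in seq_len(nrow(windows))) {
    ev <- detector_step(det, windows$m_w[i], windows$sigma_w[i],
                        windows$window_end_ts[i])
    if (!is.null(ev)) {
      out_ts[[length(out_ts) + 1L]] <- ev$ts
      out_sym <- c(out_sym, ev$symbol)
    }
  }
  ts <- if (length(out_ts)) do.call(c, out_ts) else windows$window_end_ts[0]
  data.frame(ts = ts, symbol = out_sym, stringsAsFactors = FALSE)
}

#' Event-level precision, recall and F1 against ground truth
#'
#' Greedy one-to-one matching of detected to true events of the same
#' symbol within a time tolerance (nearest first). Used to score the
#' bed-exit/entrance detector against the simulator's ground truth.
#'
#' @param detected,truth data.frames with columns \code{ts}, \code{symbol}.
#' @param tol_s Matching tolerance in seconds (default 5).
#' @return List: \code{precision}, \code{recall}, \code{f1},
#'   \code{n_detected}, \code{n_truth}, \code{n_matched}.
#' @export
event_f1 <- function(detected, truth, tol_s = 5) {
  n_matched <- 0L
  for (sym in unique(c(detected$symbol, truth$symbol))) {
    d <- as.numeric(detected$ts[detected$symbol == sym])
    g <- as.numeric(truth$ts[truth$symbol == sym])
    if (!length(d) || !length(g)) next
    used_d <- rep(FALSE, length(d)); used_g <- rep(FALSE, length(g))
    pairs <- expand.grid(i = seq_along(d), j = seq_along(g))
    pairs$gap <- abs(d[pairs$i] - g[pairs$j])
    pairs <- pairs[pairs$gap <= tol_s, , drop = FALSE]
    pairs <- pairs[order(pairs$gap), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (!used_d[i] && !used_g[j]) {
        used_d[i] <- used_g[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  nd <- nrow(detected); ng <- nrow(truth)
  prec <- if (nd) n_matched / nd else NA_real_
  rec <- if (ng) n_matched / ng else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       n_detected = nd, n_truth = ng, n_matched = n_matched)
}
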