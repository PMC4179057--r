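#' Run the full monitoring pipeline on simulated nights
#'
#' Executes, end to end, the workflow the monitoring system performs on a
#' study: simulate the nights, calibrate the bed-presence thresholds on
#' the first load-cell night, detect bed entrances/exits on every
#' load-cell night, mine the event-transition model, build the windowed
#' dataset and cross-validate the early-night classifier. Artifacts are
#' written to \code{out_dir}:
#' \itemize{
#'   \item \code{events.jsonl} — raw sensor log of all nights (room/I/D
#'     events + Emfit stream),
#'   \item \code{bed_events.jsonl} — detected Bin/Bout events,
#'   \item \code{thresholds.json} — calibrated thresholds,
#'   \item \code{transitions.csv}, \code{transitions.dot} — mined model,
#'   \item \code{dataset.csv}, \code{tree.txt}, \code{tree.dot} —
#'     classifier inputs and model,
#'   \item \code{metrics.json} — all summary numbers.
#' }
#'
#' The transition-recovery error in the metrics compares the model mined
#' from detected bed events against the model mined from the ground-truth
#' bed events on the same nights (maximum absolute probability
#' difference over rows observed in both): it measures how much detector
#' imperfection perturbs the mined routine. Everything is deterministic
#' given the scenario and seed: two runs write byte-identical metrics.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario A [night_scenario()]; its seed drives everything
#'   unless \code{seed} is given.
#' @param seed Optional integer overriding the scenario seed.
#' @param loadcell_nights How many nights get a load-cell stream and bed
#'   detection (default \code{min(3, n_nights)}; the remaining nights
#'   contribute events only).
#' @param confirm Detector confirmation count (see [bed_detector()]).
#' @param confidence_threshold Edge threshold for the transition graph.
#' @param cv_k Cross-validation folds (default 10).
#' @param min_leaf,max_depth C4.5 parameters.
#' @param verbose Print progress lines?
#' @return The metrics list, invisibly.
#' @export
run_pipeline <- function(out_dir, scenario = night_scenario(),
                         seed = NULL,
                         loadcell_nights = min(3L, scenario$n_nights),
                         confirm = 1L, confidence_threshold = 0.2,
                         cv_k = 10L, min_leaf = 5L, max_depth = 10L,
                         verbose = TRUE) {
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating %d nights (seed %d)", scenario$n_nights, scenario$seed)
  lc_nights <- seq_len(loadcell_nights)
  records <- lapply(seq_len(scenario$n_nights), function(i)
    simulate_night(scenario, i, loadcell = i %in% lc_nights))

  sensor_log <- do.call(rbind, lapply(records, `[[`, "events"))
  write_event_log(sensor_log, file.path(out_dir, "events.jsonl"))

  ## -- bed presence -------------------------------------------------------
  say("calibrating thresholds on night %s", records[[1]]$night_id)
  win1 <- with(records[[1]],
               loadcell_windows(adc_to_weight(loadcell$adc_out,
                                              scenario$loadcell$ratio),
                                loadcell$ts))
  thr <- calibrate_thresholds(win1)
  jsonlite::write_json(list(O_m_w = thr$O_m_w, O_sigma_w = thr$O_sigma_w,
                            separability_m_w = thr$separability_m_w,
                            separability_sigma_w = thr$separability_sigma_w),
                       file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)

  detected <- list(); truth <- list(); misclass <- 0; nwin <- 0
  for (i in lc_nights) {
    rec <- records[[i]]
    w <- loadcell_windows(adc_to_weight(rec$loadcell$adc_out,
                                        scenario$loadcell$ratio),
                          rec$loadcell$ts)
    ev <- detect_bed_events(w, thr, confirm = confirm)
    ev$night_id <- rep(rec$night_id, nrow(ev))
    detected[[i]] <- ev
    tb <- rec$true_bed_events
    tb$night_id <- rep(rec$night_id, nrow(tb))
    truth[[i]] <- tb
    occ <- window_occupancy(rec$state_timeline, w$window_end_ts)
    misclass <- misclass + sum(bed_presence(w$m_w, w$sigma_w, thr) != occ)
    nwin <- nwin + nrow(w)
    say("night %s: %d bed events detected (%d true)", rec$night_id,
        nrow(ev), nrow(tb))
  }
  detected <- do.call(rbind, detected)
  truth <- do.call(rbind, truth)
  write_event_log(detected, file.path(out_dir, "bed_events.jsonl"))
  f1 <- event_f1(detected, truth)

  ## -- transition mining --------------------------------------------------
  say("mining transitions on %d nights", length(lc_nights))
  mine_from <- function(bed_events) {
    m <- transition_model()
    for (i in lc_nights) {
      rec <- records[[i]]
      be <- bed_events[bed_events$night_id == rec$night_id,
                       c("ts", "symbol"), drop = FALSE]
      ev <- rbind(rec$room_events[, c("ts", "symbol")], be)
      ev <- ev[order(ev$ts), , drop = FALSE]
      ev$night_id <- rec$night_id
      m <- observe_events(m, ev)
    }
    m
  }
  model_det <- mine_from(detected)
  model_true <- mine_from(truth)
  p_det <- transition_probs(model_det)
  p_true <- transition_probs(model_true)
  both <- !is.na(rowSums(p_det)) & !is.na(rowSums(p_true))
  recov <- if (any(both)) max(abs(p_det[both, ] - p_true[both, ])) else NA
  utils::write.csv(transition_table(model_det),
                   file.path(out_dir, "transitions.csv"), row.names = FALSE)
  writeLines(transition_graph_dot(model_det, confidence_threshold),
             file.path(out_dir, "transitions.dot"))

  ## -- early-night classifier ---------------------------------------------
  say("building windowed dataset over %d nights", scenario$n_nights)
  all_events <- do.call(rbind, lapply(records, night_events, bed = "true"))
  ds <- build_dataset(all_events)
  utils::write.csv(ds[, c(feature_names(), "label")],
                   file.path(out_dir, "dataset.csv"), row.names = FALSE)
  tree <- train_c45(ds, min_leaf = min_leaf, max_depth = max_depth)
  writeLines(utils::capture.output(print(tree)),
             file.path(out_dir, "tree.txt"))
  writeLines(c45_tree_dot(tree), file.path(out_dir, "tree.dot"))
  cv <- crossval_c45(ds, k = cv_k, seed = child_seed(scenario$seed, 0, "cv"),
                     min_leaf = min_leaf, max_depth = max_depth)
  baseline <- max(table(ds$label)) / nrow(ds)

  metrics <- list(
    seed = scenario$seed,
    n_nights = scenario$n_nights,
    loadcell_nights = length(lc_nights),
    detector = list(f1 = f1$f1, precision = f1$precision,
                    recall = f1$recall, n_detected = f1$n_detected,
                    n_truth = f1$n_truth,
                    window_misclassification_rate = misclass / nwin),
    thresholds = list(O_m_w = thr$O_m_w, O_sigma_w = thr$O_sigma_w),
    transitions = list(recovery_max_error = recov,
                       n_transitions = sum(model_det$counts)),
    classifier = list(n_observations = nrow(ds),
                      n_tpi = sum(ds$label == "TPI"),
                      cv_mean_accuracy = cv$mean_accuracy,
                      cv_sd_accuracy = cv$sd_accuracy,
                      majority_baseline = as.numeric(baseline)))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: artifacts in %s", out_dir)
  invisible(metrics)
}

#' Ground-truth occupancy of a window sequence
#'
#' Labels each window end-timestamp as occupied when it falls inside a
#' Bed interval of a ground-truth state timeline.
#'
#' @param timeline data.frame \code{state}, \code{enter_ts},
#'   \code{exit_ts}.
#' @param ts Window end timestamps.
#' @return Logical vector.
#' @export
window_occupancy <- function(timeline, ts) {
  bed <- timeline[timeline$state == "Bed", , drop = FALSE]
  ts <- as.numeric(ts)
  occ <- rep(FALSE, length(ts))
  for (i in seq_len(nrow(bed)))
    occ <- occ | (ts >= as.numeric(bed$enter_ts[i]) &
                    ts <= as.numeric(bed$exit_ts[i]))
  occ
}

#' Load a pipeline configuration from YAML
#'
#' The file must contain a \code{scenario} section (arguments understood
#' by [night_scenario()]; scalar fields only, the transition matrix and
#' dwell lists keep their defaults) and a \code{pipeline} section
#' (arguments of [run_pipeline()] other than \code{out_dir} and
#' \code{scenario}). Missing sections are reported by name.
#'
#' @param path YAML file path.
#' @return List with elements \code{scenario} (a [night_scenario()]) and
#'   \code{pipeline} (named list of options).
#' @export
load_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read config files")
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(c("scenario", "pipeline"), names(cfg))
  if (length(missing))
    stopf("config %s is missing section(s): %s", path,
          paste(missing, collapse = ", "))
  sc_args <- cfg$scenario
  ok <- names(sc_args) %in% names(formals(night_scenario))
  if (!all(ok))
    stopf("unknown scenario key(s): %s",
          paste(names(sc_args)[!ok], collapse = ", "))
  list(scenario = do.call(night_scenario, sc_args),
       pipeline = cfg$pipeline)
}
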