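default_transition_matrix <- function() {
  states <- c("Bed", "Ba", "K", "H", "L")
  P <- matrix(c(
    0.00, 0.70, 0.10, 0.10, 0.10,   # Bed: a bathroom visit is most likely
    0.70, 0.00, 0.10, 0.15, 0.05,   # Ba
    0.40, 0.10, 0.00, 0.20, 0.30,   # K
    0.50, 0.20, 0.20, 0.00, 0.10,   # H
    0.50, 0.10, 0.20, 0.20, 0.00),  # L
    nrow = 5, byrow = TRUE, dimnames = list(states, states))
  P
}

#' Scenario configuration for the night simulator
#'
#' Describes one monitored resident over a study of \code{n_nights} nights
#' with sensors active 10 p.m.-6 a.m.: a semi-Markov model over the states
#' \{Bed, bathroom, kitchen, hallway, living room\} with a planted
#' row-stochastic transition matrix, truncated-normal dwell times per
#' state, and truncated-normal transit gaps between states (the gap out of
#' bed defaults to 7 +/- 7 min — the time from a bed exit to the next room
#' event). Early-night behaviour (before midnight) is distinguished by a
#' much shorter bed dwell, emulating an active evening routine followed by
#' consolidated sleep; this is the planted structure the early-night
#' classifier must recover.
#'
#' The load-cell model puts \code{occupied_mean} kg on the instrumented
#' bed leg with movement noise (plus optional short bursts) while the bed
#' is occupied, against a small tare weight and near-zero noise when
#' empty, so the windowed median and standard deviation are bimodal by
#' construction. The Emfit-style bed sensor is emulated by dropping each
#' true bed-exit event with probability \code{emfit_miss_rate}
#' (default 0.6, the miss rate reported for the real device).
#'
#' All randomness derives from \code{seed}; trajectory, load-cell and
#' Emfit degradation use independent child streams, so changing only the
#' Emfit parameters leaves the ground truth untouched.
#'
#' @param n_nights Number of nights (default 14, the study duration).
#' @param seed Master seed.
#' @param base_date Calendar date of the first night's 10 p.m. boundary.
#' @param transition_matrix Row-stochastic matrix over the five states
#'   (zero diagonal; rows must sum to 1).
#' @param start_state State occupied at 10 p.m. (default living room).
#' @param dwell_min Named list of \code{c(mean, sd)} dwell minutes per
#'   state.
#' @param early_bed_dwell_min \code{c(mean, sd)} minutes for bed dwells
#'   that begin before midnight.
#' @param transit_min \code{c(mean, sd)} minutes for the gap between
#'   leaving one state and the next room event.
#' @param transit_from_bed_min Same, for gaps that follow a bed exit
#'   (default 7 +/- 7 min).
#' @param loadcell List: \code{sampling_hz}, \code{ratio} (ADC counts per
#'   kg), \code{occupied_mean}, \code{occupied_sigma},
#'   \code{burst_rate_per_min}, \code{burst_amp}, \code{burst_len_s},
#'   \code{empty_mean}, \code{empty_sigma}.
#' @param emfit_miss_rate Probability a true bed exit is missed
#'   (default 0.6).
#' @param emfit_spurious_per_night Expected number of spurious Emfit bed
#'   exits per night (Poisson; default 0).
#' @param inactivity_timeout_min Minutes of stillness before the wearable
#'   emits an inactivity (\code{I}) event, repeating while stillness
#'   lasts; \code{NULL} disables (default 5).
#' @param door_patrol_hours Hours after 10 p.m. at which a night-patrol
#'   door (\code{D}) event fires each night; default none.
#' @return Object of class \code{night_scenario}.
#' @export
night_scenario <- function(n_nights = 14L,
                           seed = 1L,
                           base_date = "2024-01-01",
                           transition_matrix = default_transition_matrix(),
                           start_state = "L",
                           dwell_min = list(Bed = c(180, 60), Ba = c(7, 4),
                                            K = c(10, 6), H = c(2, 1),
                                            L = c(25, 12)),
                           early_bed_dwell_min = c(5, 2.5),
                           transit_min = c(0.5, 0.25),
                           transit_from_bed_min = c(7, 7),
                           loadcell = list(sampling_hz = 80,
                                           ratio = -41943.0,
                                           occupied_mean = 25,
                                           occupied_sigma = 2,
                                           burst_rate_per_min = 1,
                                           burst_amp = 2,
                                           burst_len_s = 1,
                                           empty_mean = 0.4,
                                           empty_sigma = 0.02),
                           emfit_miss_rate = 0.6,
                           emfit_spurious_per_night = 0,
                           inactivity_timeout_min = 5,
                           door_patrol_hours = NULL) {
  states <- rownames(transition_matrix)
  if (is.null(states) || !identical(states, colnames(transition_matrix)))
    stopf("transition_matrix needs identical row/column state names")
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9))
    stopf("transition_matrix rows must be nonnegative and sum to 1")
  if (!start_state %in% states) stopf("unknown start_state '%s'", start_state)
  if (!all(states %in% c(names(dwell_min))))
    stopf("dwell_min must name every state")
  if (emfit_miss_rate < 0 || emfit_miss_rate > 1)
    stopf("emfit_miss_rate must be in [0,1]")
  structure(list(n_nights = as.integer(n_nights), seed = as.integer(seed),
                 base_date = base_date,
                 transition_matrix = transition_matrix,
                 states = states, start_state = start_state,
                 dwell_min = dwell_min,
                 early_bed_dwell_min = early_bed_dwell_min,
                 transit_min = transit_min,
                 transit_from_bed_min = transit_from_bed_min,
                 loadcell = loadcell,
                 emfit_miss_rate = emfit_miss_rate,
                 emfit_spurious_per_night = emfit_spurious_per_night,
                 inactivity_timeout_min = inactivity_timeout_min,
                 door_patrol_hours = door_patrol_hours),
            class = "night_scenario")
}

#' @export
print.night_scenario <- function(x, ...) {
  cat(sprintf("Night scenario: %d nights from %s, states {%s}, seed %d\n",
              x$n_nights, x$base_date, paste(x$states, collapse = ","),
              x$seed))
  cat(sprintf("  loadcell %g Hz, occupied %g kg, emfit miss rate %.2f\n",
              x$loadcell$sampling_hz, x$loadcell$occupied_mean,
              x$emfit_miss_rate))
  invisible(x)
}

night_bounds <- function(cfg, night_id) {
  anchor <- as.POSIXct(paste(as.Date(cfg$base_date) + (night_id - 1),
                             "22:00:00"), tz = "UTC")
  list(anchor = anchor, end = anchor + 8 * 3600,
       midnight = anchor + 2 * 3600,
       night_id = format(as.Date(cfg$base_date) + (night_id - 1)))
}

# Sample the semi-Markov state trajectory of one night. Returns the
# ground-truth timeline (state, enter_ts, exit_ts).
sample_timeline <- function(cfg, bounds) {
  anchor <- as.numeric(bounds$anchor); end <- as.numeric(bounds$end)
  midnight <- as.numeric(bounds$midnight)
  state <- cfg$start_state
  t <- anchor
  st <- character(0); enter <- numeric(0); exit <- numeric(0)
  repeat {
    par <- if (state == "Bed" && t < midnight) cfg$early_bed_dwell_min
           else cfg$dwell_min[[state]]
    d <- rtnorm(1, par[1] * 60, par[2] * 60)
    ex <- min(t + d, end)
    st <- c(st, state); enter <- c(enter, t); exit <- c(exit, ex)
    if (ex >= end) break
    nxt <- sample(cfg$states, 1, prob = cfg$transition_matrix[state, ])
    gpar <- if (state == "Bed") cfg$transit_from_bed_min else cfg$transit_min
    g <- rtnorm(1, gpar[1] * 60, gpar[2] * 60)
    t2 <- ex + g
    if (t2 >= end) break
    t <- t2
    state <- nxt
  }
  data.frame(state = st,
             enter_ts = as.POSIXct(enter, origin = "1970-01-01", tz = "UTC"),
             exit_ts = as.POSIXct(exit, origin = "1970-01-01", tz = "UTC"),
             stringsAsFactors = FALSE)
}

timeline_events <- function(cfg, timeline, bounds) {
  ts <- numeric(0); sym <- character(0); src <- character(0)
  end <- as.numeric(bounds$end)
  for (i in seq_len(nrow(timeline))) {
    s <- timeline$state[i]
    en <- as.numeric(timeline$enter_ts[i])
    ex <- as.numeric(timeline$exit_ts[i])
    if (s == "Bed") {
      ts <- c(ts, en); sym <- c(sym, "Bin"); src <- c(src, "loadcell")
      if (ex < end) {
        ts <- c(ts, ex); sym <- c(sym, "Bout"); src <- c(src, "loadcell")
      }
      if (!is.null(cfg$inactivity_timeout_min)) {
        tout <- cfg$inactivity_timeout_min * 60
        ti <- if (en + tout < ex) seq(en + tout, ex, by = tout) else
          numeric(0)
        ti <- ti[ti < ex]
        if (length(ti)) {
          ts <- c(ts, ti); sym <- c(sym, rep("I", length(ti)))
          src <- c(src, rep("wearable", length(ti)))
        }
      }
    } else {
      ts <- c(ts, en); sym <- c(sym, s); src <- c(src, "pir")
    }
  }
  if (!is.null(cfg$door_patrol_hours)) {
    td <- as.numeric(bounds$anchor) + cfg$door_patrol_hours * 3600
    ts <- c(ts, td); sym <- c(sym, rep("D", length(td)))
    src <- c(src, rep("door", length(td)))
  }
  ord <- order(ts)
  data.frame(ts = as.POSIXct(ts[ord], origin = "1970-01-01", tz = "UTC"),
             symbol = sym[ord], source = src[ord],
             night_id = bounds$night_id, stringsAsFactors = FALSE)
}

#' Generate the 80 Hz load-cell stream of one night
#'
#' Produces the full ADC stream over the active span: the occupied-bed
#' intervals carry \code{occupied_mean} kg with movement noise and seeded
#' short bursts, the rest a small tare weight with near-zero noise. ADC
#' values are \code{round(weight * ratio)}.
#'
#' @param bed_intervals data.frame with \code{enter_ts}, \code{exit_ts}
#'   (the Bed rows of a ground-truth timeline).
#' @param cfg A [night_scenario()].
#' @param anchor Night start (10 p.m.), POSIXct.
#' @param seed Integer seed for this stream.
#' @return data.frame with \code{ts} (POSIXct) and \code{adc_out}
#'   (integer).
#' @export
gen_loadcell <- function(bed_intervals, cfg, anchor, seed) {
  lc <- cfg$loadcell
  hz <- lc$sampling_hz
  n <- as.integer(8 * 3600 * hz)
  t0 <- as.numeric(anchor)
  with_local_seed(seed, {
    w <- lc$empty_mean + stats::rnorm(n, 0, lc$empty_sigma)
    for (i in seq_len(nrow(bed_intervals))) {
      a <- floor((as.numeric(bed_intervals$enter_ts[i]) - t0) * hz) + 1
      b <- ceiling((as.numeric(bed_intervals$exit_ts[i]) - t0) * hz)
      a <- max(a, 1L); b <- min(b, n)
      if (b < a) next
      seg <- b - a + 1L
      w[a:b] <- lc$occupied_mean + stats::rnorm(seg, 0, lc$occupied_sigma)
      mins <- seg / hz / 60
      nb <- stats::rpois(1, lc$burst_rate_per_min * mins)
      if (nb > 0) {
        blen <- max(1L, as.integer(lc$burst_len_s * hz))
        starts <- a + floor(stats::runif(nb) * max(1, seg - blen))
        for (s in starts) {
          e <- min(s + blen - 1L, b)
          w[s:e] <- w[s:e] + stats::rnorm(e - s + 1L, 0, lc$burst_amp)
        }
      }
    }
    data.frame(ts = as.POSIXct(t0 + (seq_len(n) - 1) / hz,
                               origin = "1970-01-01", tz = "UTC"),
               adc_out = as.integer(round(w * lc$ratio)))
  })
}

#' Degrade true bed-exit events into an Emfit-style stream
#'
#' Emulates the film bed sensor: each true \code{Bout} is independently
#' dropped with probability \code{miss_rate}, and optionally spurious
#' (nonexistent) bed exits are injected uniformly over the night.
#'
#' @param true_bed_events data.frame with \code{ts}, \code{symbol}; only
#'   \code{Bout} rows form the sensor's output.
#' @param miss_rate Drop probability (default 0.6).
#' @param seed Integer seed.
#' @param spurious_per_night Expected spurious exits (Poisson mean,
#'   default 0); requires \code{span}.
#' @param span Optional POSIXct length-2 vector (night start/end) for
#'   spurious placement.
#' @return data.frame \code{ts}, \code{symbol} (\code{"Bout"} only),
#'   sorted by time.
#' @export
degrade_emfit <- function(true_bed_events, miss_rate = 0.6, seed = 1L,
                          spurious_per_night = 0, span = NULL) {
  if (miss_rate < 0 || miss_rate > 1) stopf("miss_rate must be in [0,1]")
  bouts <- true_bed_events[true_bed_events$symbol == "Bout", , drop = FALSE]
  with_local_seed(seed, {
    keep <- stats::runif(nrow(bouts)) >= miss_rate
    out <- bouts[keep, c("ts", "symbol"), drop = FALSE]
    if (spurious_per_night > 0 && !is.null(span)) {
      k <- stats::rpois(1, spurious_per_night)
      if (k > 0) {
        fake <- as.numeric(span[1]) +
          stats::runif(k) * (as.numeric(span[2]) - as.numeric(span[1]))
        out <- rbind(out, data.frame(
          ts = as.POSIXct(fake, origin = "1970-01-01", tz = "UTC"),
          symbol = "Bout", stringsAsFactors = FALSE))
      }
    }
    out <- out[order(out$ts), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate one night
#'
#' Samples the resident's semi-Markov trajectory, derives every sensor
#' stream, and returns them with full ground truth. Fully reproducible
#' from \code{(cfg$seed, night_id)}; the trajectory, load-cell and Emfit
#' streams use independent child seeds.
#'
#' @param cfg A [night_scenario()].
#' @param night_id Night index (1-based).
#' @param loadcell Generate the 80 Hz load-cell stream? (default
#'   \code{TRUE}; 2,304,000 samples per night). Set \code{FALSE} when only
#'   events are needed.
#' @return Object of class \code{night_record}: \code{night_id},
#'   \code{anchor}, \code{state_timeline}, \code{room_events} (Ba/K/H/L,
#'   I, D), \code{true_bed_events}, \code{emfit_events},
#'   \code{events} (room events + Emfit stream, the raw sensor log), and
#'   \code{loadcell} (or \code{NULL}).
#' @export
simulate_night <- function(cfg, night_id, loadcell = TRUE) {
  stopifnot(inherits(cfg, "night_scenario"))
  bounds <- night_bounds(cfg, night_id)
  timeline <- with_local_seed(child_seed(cfg$seed, night_id, "trajectory"),
                              sample_timeline(cfg, bounds))
  all_ev <- timeline_events(cfg, timeline, bounds)
  bed <- all_ev$symbol %in% c("Bin", "Bout")
  true_bed <- all_ev[bed, c("ts", "symbol"), drop = FALSE]
  rownames(true_bed) <- NULL
  room <- all_ev[!bed, , drop = FALSE]
  rownames(room) <- NULL
  emfit <- degrade_emfit(true_bed, cfg$emfit_miss_rate,
                         child_seed(cfg$seed, night_id, "emfit"),
                         cfg$emfit_spurious_per_night,
                         span = c(bounds$anchor, bounds$end))
  sensor_log <- room
  if (nrow(emfit)) {
    em <- data.frame(ts = emfit$ts, symbol = emfit$symbol, source = "emfit",
                     night_id = bounds$night_id, stringsAsFactors = FALSE)
    sensor_log <- rbind(sensor_log, em)
    sensor_log <- sensor_log[order(sensor_log$ts), , drop = FALSE]
    rownames(sensor_log) <- NULL
  }
  lc <- NULL
  if (loadcell) {
    bed_iv <- timeline[timeline$state == "Bed", , drop = FALSE]
    lc <- gen_loadcell(bed_iv, cfg, bounds$anchor,
                       child_seed(cfg$seed, night_id, "loadcell"))
  }
  structure(list(night_id = bounds$night_id, anchor = bounds$anchor,
                 end = bounds$end, state_timeline = timeline,
                 room_events = room, true_bed_events = true_bed,
                 emfit_events = emfit, events = sensor_log,
                 loadcell = lc),
            class = "night_record")
}

#' @export
print.night_record <- function(x, ...) {
  cat(sprintf("Night %s: %d states, %d room/I/D events, %d true bed events",
              x$night_id, nrow(x$state_timeline), nrow(x$room_events),
              nrow(x$true_bed_events)),
      if (!is.null(x$loadcell)) sprintf(", %d load-cell samples",
                                        nrow(x$loadcell)) else "", "\n",
      sep = "")
  invisible(x)
}

#' Simulate a whole study
#'
#' @param cfg A [night_scenario()].
#' @param nights Night indices (default \code{1:cfg$n_nights}).
#' @param loadcell Generate load-cell streams? (default \code{FALSE};
#'   they are large and only the bed-presence service needs them).
#' @return List of [simulate_night()] records.
#' @export
simulate_nights <- function(cfg, nights = seq_len(cfg$n_nights),
                            loadcell = FALSE) {
  lapply(nights, function(i) simulate_night(cfg, i, loadcell = loadcell))
}

#' Assemble the event stream a service consumes
#'
#' Combines room/I/D events with a chosen source of bed events: the
#' ground truth, the degraded Emfit stream, or none.
#'
#' @param record A [simulate_night()] record.
#' @param bed One of \code{"true"}, \code{"emfit"}, \code{"none"}.
#' @return data.frame \code{ts}, \code{symbol}, \code{night_id}, sorted.
#' @export
night_events <- function(record, bed = c("true", "emfit", "none")) {
  bed <- match.arg(bed)
  ev <- record$room_events[, c("ts", "symbol")]
  if (bed == "true") {
    ev <- rbind(ev, record$true_bed_events[, c("ts", "symbol")])
  } else if (bed == "emfit" && nrow(record$emfit_events)) {
    ev <- rbind(ev, record$emfit_events[, c("ts", "symbol")])
  }
  ev <- ev[order(ev$ts), , drop = FALSE]
  ev$night_id <- record$night_id
  rownames(ev) <- NULL
  ev
}

#' Planted event-level transition matrix of a scenario
#'
#' Maps the scenario's state transition matrix to the event alphabet under
#' the simulator's emission rules (room events fire at state entry, Bin at
#' bed entry, Bout at bed exit): a bed exit is followed by the next
#' state's room event, a room event by the next room event or by Bin when
#' the resident returns to bed, and Bin is always followed by Bout. Valid
#' when inactivity, door and spurious-Emfit events are disabled and the
#' state matrix has a zero diagonal; rows for symbols the simulator then
#' never emits as predecessors (I, D, and the room columns that cannot
#' occur) are \code{NA}.
#'
#' @param cfg A [night_scenario()].
#' @return 8x8 matrix over [event_alphabet()] with \code{NA} rows where
#'   undefined.
#' @export
expected_event_matrix <- function(cfg) {
  A <- event_alphabet()
  P <- matrix(NA_real_, 8, 8, dimnames = list(A, A))
  S <- cfg$transition_matrix
  rooms <- setdiff(cfg$states, "Bed")
  # Bout -> next state's entry event
  P["Bout", ] <- 0
  for (s in rooms) P["Bout", s] <- S["Bed", s]
  P["Bout", "Bin"] <- S["Bed", "Bed"]
  # room -> room or Bin
  for (r in rooms) {
    P[r, ] <- 0
    for (s in rooms) P[r, s] <- S[r, s]
    P[r, "Bin"] <- S[r, "Bed"]
  }
  P["Bin", ] <- 0
  P["Bin", "Bout"] <- 1
  P
}
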