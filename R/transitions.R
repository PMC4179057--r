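#' Online first-order event-transition model
#'
#' Creates an empty transition model over the nighttime event alphabet.
#' The model accumulates, online, (i) a count matrix of first-order
#' transitions between consecutive events and (ii) per-pair streaming
#' statistics (Welford mean/variance) of the inter-event transition time in
#' seconds. The transition probability \eqn{P_{ij} = P(e_j \mid e_i)} — the
#' confidence of the association \eqn{e_i \to e_j} — is the row-normalised
#' count.
#'
#' Consecutive identical symbols closer than \code{debounce_gap_s} are
#' merged into one event (a passive-infrared sensor retriggers while a
#' person stays in the room); the merged event keeps the first firing's
#' timestamp. Self-transitions separated by more than the gap are counted.
#' Nights are independent: the first event of a new \code{night_id} has no
#' predecessor.
#'
#' @param alphabet Event symbols (default [event_alphabet()]).
#' @param debounce_gap_s Merge window for repeated identical symbols, in
#'   seconds (default 30).
#' @return Object of class \code{transition_model}.
#' @seealso [observe_event()], [observe_events()],
#'   [transition_probability()], [transition_graph_dot()]
#' @export
transition_model <- function(alphabet = event_alphabet(),
                             debounce_gap_s = 30) {
  k <- length(alphabet)
  zero <- matrix(0, k, k, dimnames = list(alphabet, alphabet))
  structure(
    list(alphabet = alphabet,
         counts = matrix(0L, k, k, dimnames = list(alphabet, alphabet)),
         t_mean = zero, t_m2 = zero,
         last_symbol = NA_character_, last_ts = NA_real_,
         last_night = NA_character_,
         debounce_gap_s = debounce_gap_s),
    class = "transition_model")
}

#' Fold one event into a transition model
#'
#' Events must arrive in nondecreasing timestamp order within a night.
#' If a predecessor exists in the same night (after debouncing), the count
#' \code{counts[prev, symbol]} is incremented and the elapsed time
#' \code{ts - prev_ts} is folded into the pair's online mean/variance
#' accumulator.
#'
#' @param model A [transition_model()].
#' @param ts Event timestamp (POSIXct or numeric seconds).
#' @param symbol Event symbol, one of the model's alphabet.
#' @param night_id Night identifier; transitions never cross nights.
#' @return The updated model.
#' @export
observe_event <- function(model, ts, symbol, night_id = "night") {
  stopifnot(inherits(model, "transition_model"))
  if (!symbol %in% model$alphabet)
    stopf("unknown symbol '%s' (alphabet: %s)", symbol,
          paste(model$alphabet, collapse = ","))
  ts <- as.numeric(ts)
  night_id <- as.character(night_id)
  if (identical(night_id, model$last_night)) {
    if (!is.na(model$last_ts) && ts < model$last_ts)
      stopf("out-of-order timestamp within night '%s': %f after %f",
            night_id, ts, model$last_ts)
    if (identical(symbol, model$last_symbol) &&
        ts - model$last_ts <= model$debounce_gap_s) {
      # PIR retrigger: merge, keep the first firing's timestamp
      return(model)
    }
    if (!is.na(model$last_symbol)) {
      i <- model$last_symbol; j <- symbol
      model$counts[i, j] <- model$counts[i, j] + 1L
      dt <- ts - model$last_ts
      n <- model$counts[i, j]
      delta <- dt - model$t_mean[i, j]
      model$t_mean[i, j] <- model$t_mean[i, j] + delta / n
      model$t_m2[i, j] <- model$t_m2[i, j] + delta * (dt - model$t_mean[i, j])
    }
  } else {
    model$last_night <- night_id   # new night: reset chain
  }
  model$last_symbol <- symbol
  model$last_ts <- ts
  model
}

#' Fold a whole event log into a transition model
#'
#' @param model A [transition_model()].
#' @param events data.frame with columns \code{ts}, \code{symbol} and
#'   optionally \code{night_id} (a single night is assumed otherwise).
#'   Rows must be time-ordered within each night.
#' @return The updated model.
#' @export
observe_events <- function(model, events) {
  nid <- if ("night_id" %in% names(events)) as.character(events$night_id)
         else rep("night", nrow(events))
  ts <- as.numeric(events$ts)
  sym <- as.character(events$symbol)
  for (i in seq_len(nrow(events)))
    model <- observe_event(model, ts[i], sym[i], nid[i])
  model
}

#' Transition probability and per-pair time statistics
#'
#' \code{transition_probability} returns \eqn{P(e_j \mid e_i)}; it is an
#' error to ask about a row that was never observed.
#' \code{transition_time_stats} returns the pair's observation count,
#' online mean and sample standard deviation (\code{NA} when fewer than
#' two observations) of the transition time in seconds.
#' \code{transition_probs} returns the full row-normalised matrix with
#' \code{NA} rows where nothing was observed.
#'
#' @param model A [transition_model()].
#' @param from,to Event symbols.
#' @return See above.
#' @export
transition_probability <- function(model, from, to) {
  row_sum <- sum(model$counts[from, ])
  if (row_sum == 0)
    stopf("event '%s' was never observed as a predecessor", from)
  model$counts[from, to] / row_sum
}

#' @rdname transition_probability
#' @export
transition_time_stats <- function(model, from, to) {
  n <- model$counts[from, to]
  list(n = as.integer(n),
       mean = if (n >= 1) model$t_mean[from, to] else NA_real_,
       sd = if (n >= 2) sqrt(model$t_m2[from, to] / (n - 1)) else NA_real_)
}

#' @rdname transition_probability
#' @export
transition_probs <- function(model) {
  rs <- rowSums(model$counts)
  p <- model$counts / ifelse(rs == 0, NA_real_, rs)
  p[rs == 0, ] <- NA_real_
  p
}

#' @export
print.transition_model <- function(x, ...) {
  rs <- rowSums(x$counts)
  cat(sprintf("Transition model over {%s}\n",
              paste(x$alphabet, collapse = ",")))
  cat(sprintf("  %d transitions observed, %d active rows, debounce %gs\n",
              sum(x$counts), sum(rs > 0), x$debounce_gap_s))
  invisible(x)
}

#' @export
summary.transition_model <- function(object, ...) {
  df <- transition_table(object)
  cat("Observed transitions (p = confidence, times in s):\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' Tabulate observed transitions
#'
#' One row per observed pair, in deterministic alphabet order, with count,
#' probability and transition-time statistics.
#'
#' @param model A [transition_model()].
#' @return data.frame: \code{from}, \code{to}, \code{n}, \code{p},
#'   \code{mu_t}, \code{sigma_t}.
#' @export
transition_table <- function(model) {
  rows <- list()
  rs <- rowSums(model$counts)
  for (i in model$alphabet) {
    if (rs[i] == 0) next
    for (j in model$alphabet) {
      n <- model$counts[i, j]
      if (n == 0) next
      st <- transition_time_stats(model, i, j)
      rows[[length(rows) + 1L]] <-
        data.frame(from = i, to = j, n = as.integer(n), p = n / rs[i],
                   mu_t = st$mean, sigma_t = st$sd,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(from = character(0), to = character(0),
                      n = integer(0), p = numeric(0),
                      mu_t = numeric(0), sigma_t = numeric(0)))
  do.call(rbind, rows)
}

#' Export the transition graph as DOT
#'
#' Renders the directed graph whose edges are the transitions with
#' confidence \eqn{P_{ij} \ge} \code{confidence_threshold}, each labelled
#' with the probability and the mean/standard deviation of the transition
#' time. Node and edge ordering follow the alphabet, so the output is
#' deterministic. The default threshold 0.2 hides weak associations and
#' leaves the resident's habitual nighttime routes.
#'
#' @param model A [transition_model()].
#' @param confidence_threshold Minimum edge confidence (default 0.2).
#' @return A single character string of DOT source.
#' @export
transition_graph_dot <- function(model, confidence_threshold = 0.2) {
  tab <- transition_table(model)
  tab <- tab[tab$p >= confidence_threshold, , drop = FALSE]
  nodes <- model$alphabet[model$alphabet %in% unique(c(tab$from, tab$to))]
  lines <- c("digraph transitions {", "  rankdir=LR;",
             sprintf("  \"%s\";", nodes))
  if (nrow(tab)) {
    lab <- sprintf("p=%.2f, mu_t=%.1fs%s", tab$p, tab$mu_t,
                   ifelse(is.na(tab$sigma_t), "",
                          sprintf(", sigma_t=%.1fs", tab$sigma_t)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                              tab$from, tab$to, lab))
  }
  paste(c(lines, "}"), collapse = "\n")
}
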