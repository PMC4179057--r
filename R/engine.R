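#' In-process active-rule engine
#'
#' Creates an empty engine holding tables, AFTER-INSERT row triggers and
#' publish/subscribe notification channels. The engine reproduces, in
#' process, the active-database substrate that ambient-assisted-living
#' services are built on: sensor adapters insert rows, triggers evaluate
#' event-condition-action (ECA) rules inline, and actions notify listeners
#' on named channels.
#'
#' Semantics are single-threaded and synchronous: triggers run inline in
#' insert order, notifications are delivered immediately in subscription
#' order. This makes every run deterministic.
#'
#' @return An object of class \code{eca_engine}.
#' @seealso [engine_create_table()], [engine_insert()],
#'   [engine_register_trigger()], [engine_notify()]
#' @export
#' @examples
#' eng <- eca_engine()
#' engine_create_table(eng, "weight_fifo",
#'                     columns = c("adc_out", "ts"), fifo_capacity = 40)
eca_engine <- function() {
  eng <- new.env(parent = emptyenv())
  eng$tables <- new.env(parent = emptyenv())
  eng$triggers <- list()          # id -> rule record, registration order
  eng$next_trigger_id <- 1L
  eng$channels <- new.env(parent = emptyenv())
  eng$next_listener_id <- 1L
  class(eng) <- "eca_engine"
  eng
}

#' @export
print.eca_engine <- function(x, ...) {
  cat("<eca_engine>\n")
  cat("  tables:  ", paste(ls(x$tables), collapse = ", "), "\n")
  cat("  triggers:", length(x$triggers), "\n")
  cat("  channels:", paste(ls(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Create a table in the engine
#'
#' @param engine An [eca_engine()].
#' @param name Table name; must be unused.
#' @param columns Character vector of column names.
#' @param fifo_capacity Optional positive integer. When set, the table is a
#'   FIFO table: it retains only the newest \code{fifo_capacity} rows and the
#'   engine-assigned \code{sample_id} wraps around in
#'   \code{1..fifo_capacity}; otherwise \code{sample_id} is a monotone
#'   counter.
#' @return The table handle, invisibly.
#' @export
engine_create_table <- function(engine, name, columns, fifo_capacity = NULL) {
  stopifnot(inherits(engine, "eca_engine"))
  if (exists(name, envir = engine$tables, inherits = FALSE))
    stopf("table '%s' already exists", name)
  if (!is.null(fifo_capacity) && !is_count(fifo_capacity))
    stopf("fifo_capacity must be a positive integer")
  tbl <- new.env(parent = emptyenv())
  tbl$name <- name
  tbl$columns <- as.character(columns)
  tbl$fifo_capacity <- if (is.null(fifo_capacity)) NULL else
    as.integer(fifo_capacity)
  tbl$rows <- list()
  tbl$n_inserted <- 0L
  tbl$trigger_ids <- integer(0)
  assign(name, tbl, envir = engine$tables)
  invisible(tbl)
}

get_table <- function(engine, name) {
  if (!exists(name, envir = engine$tables, inherits = FALSE))
    stopf("unknown table '%s'", name)
  get(name, envir = engine$tables)
}

#' Register an AFTER-INSERT trigger
#'
#' Registers an ECA rule on a table: after every insert, \code{condition} is
#' evaluated on the new row (including its engine-assigned
#' \code{sample_id}); when it returns \code{TRUE} the \code{action} is
#' executed once with the new row. Triggers on a table run in registration
#' order. A failing action does not undo the insert; remaining triggers
#' still run and the first error is re-raised afterwards.
#'
#' @param engine An [eca_engine()].
#' @param table Name of an existing table.
#' @param condition Side-effect-free predicate \code{function(row)}; use
#'   \code{NULL} for an unconditional trigger.
#' @param action \code{function(row)} executed for each qualifying insert.
#' @return The trigger id (integer).
#' @export
engine_register_trigger <- function(engine, table, condition = NULL, action) {
  stopifnot(inherits(engine, "eca_engine"), is.function(action))
  tbl <- get_table(engine, table)
  if (!is.null(condition)) stopifnot(is.function(condition))
  id <- engine$next_trigger_id
  engine$next_trigger_id <- id + 1L
  engine$triggers[[as.character(id)]] <-
    list(id = id, table = table, condition = condition, action = action)
  tbl$trigger_ids <- c(tbl$trigger_ids, id)
  id
}

#' Deregister a trigger
#' @param engine An [eca_engine()].
#' @param id Trigger id returned by [engine_register_trigger()].
#' @return \code{TRUE} invisibly.
#' @export
engine_deregister_trigger <- function(engine, id) {
  key <- as.character(id)
  rule <- engine$triggers[[key]]
  if (is.null(rule)) stopf("unknown trigger id %s", key)
  tbl <- get_table(engine, rule$table)
  tbl$trigger_ids <- setdiff(tbl$trigger_ids, rule$id)
  engine$triggers[[key]] <- NULL
  invisible(TRUE)
}

#' Insert a row and fire triggers
#'
#' Appends a row (a named list matching the table's columns), applies FIFO
#' eviction, then evaluates every AFTER-INSERT trigger on the table in
#' registration order. The stored row carries the engine-assigned
#' \code{sample_id}: for FIFO tables it cycles \code{1..fifo_capacity}
#' (the wrap-around the half-second bed-presence rule keys on), for
#' unbounded tables it increments without bound.
#'
#' @param engine An [eca_engine()].
#' @param table Table name.
#' @param row Named list; names must equal the table's columns.
#' @return The stored row, including \code{sample_id}.
#' @export
engine_insert <- function(engine, table, row) {
  tbl <- get_table(engine, table)
  if (!setequal(names(row), tbl$columns))
    stopf("row columns {%s} do not match table '%s' schema {%s}",
          paste(names(row), collapse = ","), table,
          paste(tbl$columns, collapse = ","))
  tbl$n_inserted <- tbl$n_inserted + 1L
  row$sample_id <- if (is.null(tbl$fifo_capacity)) tbl$n_inserted else
    ((tbl$n_inserted - 1L) %% tbl$fifo_capacity) + 1L
  tbl$rows[[length(tbl$rows) + 1L]] <- row
  if (!is.null(tbl$fifo_capacity) && length(tbl$rows) > tbl$fifo_capacity)
    tbl$rows <- tbl$rows[-1L]

  first_error <- NULL
  for (id in tbl$trigger_ids) {
    rule <- engine$triggers[[as.character(id)]]
    fire <- if (is.null(rule$condition)) TRUE else
      isTRUE(rule$condition(row))
    if (fire) {
      err <- tryCatch({ rule$action(row); NULL }, error = identity)
      if (!is.null(err) && is.null(first_error)) first_error <- err
    }
  }
  if (!is.null(first_error)) stop(first_error)
  row
}

#' Read the current rows of a table
#' @param engine An [eca_engine()].
#' @param table Table name.
#' @return List of stored rows, oldest first.
#' @export
engine_rows <- function(engine, table) {
  get_table(engine, table)$rows
}

get_channel <- function(engine, name) {
  if (!exists(name, envir = engine$channels, inherits = FALSE)) {
    ch <- new.env(parent = emptyenv())
    ch$subscribers <- list()     # listener id -> callback, subscription order
    assign(name, ch, envir = engine$channels)
  }
  get(name, envir = engine$channels)
}

#' Publish/subscribe notification channels
#'
#' \code{engine_notify} delivers a payload exactly once to each current
#' subscriber of a channel, in subscription order; a failing callback is
#' reported as a warning and does not affect other subscribers.
#' \code{engine_listen} subscribes a callback and returns a listener id;
#' \code{engine_unlisten} removes a subscription by id or by the callback
#' itself. Channels are created on first use.
#'
#' @param engine An [eca_engine()].
#' @param channel Channel name.
#' @param payload Arbitrary payload passed to each callback.
#' @param callback \code{function(payload)}.
#' @param id Listener id (from \code{engine_listen}) or the callback.
#' @return \code{engine_notify}: number of subscribers notified, invisibly.
#'   \code{engine_listen}: listener id. \code{engine_unlisten}: \code{TRUE}
#'   invisibly.
#' @export
engine_notify <- function(engine, channel, payload) {
  ch <- get_channel(engine, channel)
  for (cb in ch$subscribers) {
    tryCatch(cb(payload), error = function(e)
      warning(sprintf("subscriber callback on '%s' failed: %s",
                      channel, conditionMessage(e)), call. = FALSE))
  }
  invisible(length(ch$subscribers))
}

#' @rdname engine_notify
#' @export
engine_listen <- function(engine, channel, callback) {
  stopifnot(is.function(callback))
  ch <- get_channel(engine, channel)
  id <- engine$next_listener_id
  engine$next_listener_id <- id + 1L
  ch$subscribers[[as.character(id)]] <- callback
  id
}

#' @rdname engine_notify
#' @export
engine_unlisten <- function(engine, channel, id) {
  ch <- get_channel(engine, channel)
  if (is.function(id)) {
    keep <- !vapply(ch$subscribers, function(cb) identical(cb, id), logical(1))
    ch$subscribers <- ch$subscribers[keep]
  } else {
    ch$subscribers[[as.character(id)]] <- NULL
  }
  invisible(TRUE)
}
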