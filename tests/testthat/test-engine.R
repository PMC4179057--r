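test_that("FIFO tables evict oldest rows and wrap the sample counter", {
  eng <- eca_engine()
  engine_create_table(eng, "weight_fifo", c("adc_out", "ts"),
                      fifo_capacity = 40)
  for (i in 1:41) engine_insert(eng, "weight_fifo",
                                list(adc_out = i, ts = i))
  rows <- engine_rows(eng, "weight_fifo")
  expect_length(rows, 40)
  expect_equal(rows[[1]]$adc_out, 2)          # oldest row evicted
  expect_equal(rows[[40]]$sample_id, 1L)      # 41st insert wraps to 1

  # FIFO conservation across arbitrary n
  eng2 <- eca_engine()
  engine_create_table(eng2, "f", "x", fifo_capacity = 7)
  for (n in 1:20) {
    engine_insert(eng2, "f", list(x = n))
    rows <- engine_rows(eng2, "f")
    expect_length(rows, min(n, 7))
    expect_equal(rows[[length(rows)]]$sample_id, ((n - 1) %% 7) + 1)
  }
})

test_that("unbounded tables keep all rows with a monotone sample_id", {
  eng <- eca_engine()
  engine_create_table(eng, "events", c("symbol"))
  for (i in 1:5) engine_insert(eng, "events", list(symbol = "Ba"))
  rows <- engine_rows(eng, "events")
  expect_length(rows, 5)
  expect_equal(vapply(rows, `[[`, numeric(1), "sample_id"), 1:5)
})

test_that("table registration rejects duplicates and bad capacities", {
  eng <- eca_engine()
  engine_create_table(eng, "t", "x")
  expect_error(engine_create_table(eng, "t", "x"), "already exists")
  expect_error(engine_create_table(eng, "u", "x", fifo_capacity = 0),
               "positive integer")
  expect_error(engine_insert(eng, "nope", list(x = 1)), "unknown table")
  expect_error(engine_insert(eng, "t", list(y = 1)), "schema")
})

test_that("the wrap-around trigger fires exactly on every 40th insertion", {
  eng <- eca_engine()
  engine_create_table(eng, "weight_fifo", c("adc_out", "ts"),
                      fifo_capacity = 40)
  fired_at <- integer(0)
  n_inserted <- 0
  engine_register_trigger(eng, "weight_fifo",
                          condition = function(row) row$sample_id == 40,
                          action = function(row)
                            fired_at <<- c(fired_at, n_inserted))
  for (i in 1:39) {
    n_inserted <- n_inserted + 1
    engine_insert(eng, "weight_fifo", list(adc_out = i, ts = i))
  }
  expect_length(fired_at, 0)                 # 39th insert: no firing
  n_inserted <- n_inserted + 1
  engine_insert(eng, "weight_fifo", list(adc_out = 40, ts = 40))
  expect_equal(fired_at, 40L)                # 40th insert fires
  for (i in 41:80) {
    n_inserted <- n_inserted + 1
    engine_insert(eng, "weight_fifo", list(adc_out = i, ts = i))
  }
  expect_equal(fired_at, c(40L, 80L))        # 80 inserts: exactly 2 firings
})

test_that("triggers run in registration order and can be deregistered", {
  eng <- eca_engine()
  engine_create_table(eng, "t", "x")
  log <- character(0)
  id1 <- engine_register_trigger(eng, "t", NULL,
                                 function(row) log <<- c(log, "a"))
  id2 <- engine_register_trigger(eng, "t", NULL,
                                 function(row) log <<- c(log, "b"))
  engine_insert(eng, "t", list(x = 1))
  expect_equal(log, c("a", "b"))
  engine_deregister_trigger(eng, id1)
  engine_insert(eng, "t", list(x = 2))
  expect_equal(log, c("a", "b", "b"))
  engine_deregister_trigger(eng, id2)
  engine_insert(eng, "t", list(x = 3))
  expect_equal(log, c("a", "b", "b"))
  expect_error(engine_register_trigger(eng, "nope", NULL, identity),
               "unknown table")
})

test_that("a failing action neither blocks later triggers nor the insert", {
  eng <- eca_engine()
  engine_create_table(eng, "t", "x")
  ran <- FALSE
  engine_register_trigger(eng, "t", NULL, function(row) stop("boom"))
  engine_register_trigger(eng, "t", NULL, function(row) ran <<- TRUE)
  expect_error(engine_insert(eng, "t", list(x = 1)), "boom")
  expect_true(ran)                            # second trigger still ran
  expect_length(engine_rows(eng, "t"), 1)     # insert not rolled back
})

test_that("identical insert sequences produce identical firing sequences", {
  run_once <- function() {
    eng <- eca_engine()
    engine_create_table(eng, "f", "x", fifo_capacity = 5)
    fires <- integer(0)
    engine_register_trigger(eng, "f", function(r) r$sample_id %in% c(2, 5),
                            function(r) fires <<- c(fires, r$x))
    for (i in 1:23) engine_insert(eng, "f", list(x = i))
    fires
  }
  expect_identical(run_once(), run_once())
})

test_that("channels deliver exactly once per subscriber, in order", {
  eng <- eca_engine()
  expect_silent(engine_notify(eng, "empty", "x"))   # 0 subscribers: no-op
  got <- list()
  engine_listen(eng, "ch", function(p) got$a <<- c(got$a, p))
  id_b <- engine_listen(eng, "ch", function(p) got$b <<- c(got$b, p))
  engine_notify(eng, "ch", "one")
  expect_equal(got$a, "one")
  expect_equal(got$b, "one")
  engine_unlisten(eng, "ch", id_b)
  engine_notify(eng, "ch", "two")
  expect_equal(got$a, c("one", "two"))
  expect_equal(got$b, "one")
})

test_that("a failing subscriber is isolated and reported as a warning", {
  eng <- eca_engine()
  ok <- FALSE
  engine_listen(eng, "ch", function(p) stop("dead subscriber"))
  engine_listen(eng, "ch", function(p) ok <<- TRUE)
  expect_warning(engine_notify(eng, "ch", "x"), "dead subscriber")
  expect_true(ok)
})

test_that("a bed-exit trigger action reaches channel subscribers", {
  # end-to-end: FIFO table -> trigger -> detector -> channel -> recorder
  eng <- eca_engine()
  engine_create_table(eng, "weight_fifo", c("weight", "ts"),
                      fifo_capacity = 40)
  thr <- list(O_m_w = 10, O_sigma_w = 0.5)
  det <- bed_detector(thr, engine = eng, channel = "bed_events")
  received <- list()
  engine_listen(eng, "bed_events",
                function(ev) received[[length(received) + 1]] <<- ev)
  buf <- new.env(); buf$w <- numeric(0)
  engine_register_trigger(
    eng, "weight_fifo",
    condition = function(row) row$sample_id == 40,
    action = function(row) {
      rows <- engine_rows(eng, "weight_fifo")
      w <- vapply(rows, `[[`, numeric(1), "weight")
      st <- window_stats(w, 40, row$ts)
      detector_step(det, st$m_w, st$sigma_w, st$window_end_ts)
    })
  set.seed(42)
  stream <- c(rnorm(80, 25, 2), rnorm(80, 0.4, 0.01))  # in bed, then out
  for (i in seq_along(stream))
    engine_insert(eng, "weight_fifo", list(weight = stream[i], ts = i))
  expect_length(received, 1)
  expect_equal(received[[1]]$symbol, "Bout")
})
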