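# Shared fixture builders for the test suite.

ts0 <- as.POSIXct("2024-01-01 22:00:00", tz = "UTC")

make_events <- function(offsets_s, symbols, night_id = "2024-01-01",
                        origin = ts0) {
  data.frame(ts = origin + offsets_s, symbol = symbols,
             night_id = rep_len(night_id, length(offsets_s)),
             stringsAsFactors = FALSE)
}

# Naive Otsu oracle: for every interior boundary of the same uniform
# histogram grid, partition the raw values at the boundary and recompute
# the between-class variance from first principles.
otsu_bruteforce <- function(values, n_bins = 256L) {
  lo <- min(values); hi <- max(values)
  width <- (hi - lo) / n_bins
  best_t <- NA; best_v <- -Inf
  for (t in seq_len(n_bins - 1L)) {
    thr <- lo + t * width
    below <- values[values < thr]; above <- values[values >= thr]
    if (!length(below) || !length(above)) next
    w0 <- length(below) / length(values); w1 <- 1 - w0
    v <- w0 * w1 * (mean(below) - mean(above))^2
    if (v > best_v + 1e-15) { best_v <- v; best_t <- thr }
  }
  best_t
}

# Event-level Markov chain with known matrix, for parameter-recovery
# tests that bypass the full night simulator.
simulate_chain_events <- function(P, n, seed, gap_mean_s = 60,
                                  night_id = "chain") {
  stopifnot(all(abs(rowSums(P) - 1) < 1e-9))
  syms <- rownames(P)
  withr::with_seed(seed, {
    s <- character(n)
    s[1] <- sample(syms, 1)
    for (i in 2:n) s[i] <- sample(syms, 1, prob = P[s[i - 1], ])
    gaps <- stats::rexp(n - 1, 1 / gap_mean_s) + 31  # > debounce gap
    make_events(c(0, cumsum(gaps)), s, night_id = night_id)
  })
}

# Two-cluster window-statistics frame mimicking a night with separable
# occupied/empty clusters.
make_bimodal_windows <- function(n_each = 300, m_lo = 0.4, m_hi = 25,
                                 s_lo = 0.02, s_hi = 2, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      m_w = c(rnorm(n_each, m_lo, 0.02), rnorm(n_each, m_hi, 0.2)),
      mean_w = 0,
      sigma_w = c(abs(rnorm(n_each, s_lo, 0.005)),
                  rnorm(n_each, s_hi, 0.2)),
      window_end_ts = ts0 + seq_len(2 * n_each) * 0.5,
      n = 40L)
  })
}

entropy2 <- function(y) {
  p <- table(y) / length(y); p <- p[p > 0]
  -sum(p * log2(p))
}


# independent re-scan of one node: every attribute, every candidate cut,
# entropy from first principles
oracle_best <- function(data, y, features, min_leaf) {
  n <- length(y)
  cand <- list()
  for (f in features) {
    x <- data[[f]]
    if (is.numeric(x)) {
      sv <- sort(unique(x))
      best <- NULL
      if (length(sv) >= 2) for (k in 1:(length(sv) - 1)) {
        thr <- (sv[k] + sv[k + 1]) / 2
        l <- x <= thr
        if (sum(l) < min_leaf || sum(!l) < min_leaf) next
        g <- entropy2(y) - mean(l) * entropy2(y[l]) -
          mean(!l) * entropy2(y[!l])
        if (is.null(best) || g > best$gain + 1e-12)
          best <- list(gain = g, si = entropy2(l), attr = f, thr = thr)
      }
      if (!is.null(best)) cand[[length(cand) + 1]] <- best
    } else {
      xv <- droplevels(factor(x))
      if (nlevels(xv) < 2) next
      if (sum(table(xv) >= min_leaf) < 2) next
      g <- entropy2(y) - sum(vapply(levels(xv), function(v)
        mean(xv == v) * entropy2(y[xv == v]), numeric(1)))
      cand[[length(cand) + 1]] <- list(gain = g, si = entropy2(xv),
                                       attr = f, thr = NULL)
    }
  }
  cand <- Filter(function(c) c$gain > 1e-12, cand)
  if (!length(cand)) return(NULL)
  gains <- vapply(cand, `[[`, numeric(1), "gain")
  cand <- cand[gains >= mean(gains) - 1e-12]
  ratios <- vapply(cand, function(c) c$gain / c$si, numeric(1))
  cand[[which.max(ratios)]]
}

check_tree_nodes <- function(node, data, y, features, min_leaf) {
  if (node$leaf) return(invisible(TRUE))
  ob <- oracle_best(data, y, features, min_leaf)
  expect_equal(node$attr, ob$attr)
  if (!is.null(node$threshold)) expect_equal(node$threshold, ob$thr)
  if (!is.null(node$threshold)) {
    sel <- list(data[[node$attr]] <= node$threshold,
                data[[node$attr]] > node$threshold)
  } else {
    sel <- lapply(node$values, function(v) data[[node$attr]] == v)
  }
  # child sample counts sum to the parent's
  expect_equal(sum(vapply(node$children, `[[`, numeric(1), "n")), node$n)
  for (k in seq_along(node$children))
    if (any(sel[[k]]) && !node$children[[k]]$leaf)
      check_tree_nodes(node$children[[k]], data[sel[[k]], , drop = FALSE],
                       y[sel[[k]]], features, min_leaf)
  invisible(TRUE)
}

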