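#' Feature names of the early-night behaviour classifier
#'
#' The 15 features computed per sliding window: the symbols of the last
#' four events in the window (most recent first; \code{N} when fewer events
#' are available), the inter-event times between the latest event and each
#' of the three preceding ones, and the count of each of the eight event
#' types. The absence of events is expressed by \code{N} in the last-event
#' slots and all-zero counts, not by a ninth count.
#'
#' @param alphabet Event alphabet (default [event_alphabet()]).
#' @return Character vector of 15 column names.
#' @export
feature_names <- function(alphabet = event_alphabet()) {
  c(paste0("last", 1:4), paste0("et", 1:3), paste0("n_", alphabet))
}

#' Extract the feature vector of one sliding window
#'
#' Considers the events with timestamps in
#' \code{[window_start, window_start + width_min)}. \code{last1} is the
#' symbol of the latest event in the window, \code{last2} the one before,
#' and so on; slots beyond the available events hold \code{N}.
#' \code{et}k is the elapsed time in seconds between the latest event and
#' the k-th previous one; when fewer than k+1 events exist it is coded as
#' the window width in seconds (a "nothing happened for the whole window"
#' sentinel, with the matching \code{N} slot marking the absence).
#'
#' @param events data.frame with \code{ts} (POSIXct or numeric seconds) and
#'   \code{symbol}; sorted by \code{ts}.
#' @param window_start Window start timestamp.
#' @param width_min Window width in minutes (default 20).
#' @param alphabet Event alphabet (default [event_alphabet()]).
#' @return One-row data.frame with the 15 feature columns; last-event
#'   slots are factors with levels \code{c(alphabet, "N")}.
#' @export
extract_features <- function(events, window_start, width_min = 20,
                             alphabet = event_alphabet()) {
  ts <- as.numeric(events$ts)
  start <- as.numeric(window_start)
  width_s <- width_min * 60
  in_w <- ts >= start & ts < start + width_s
  wts <- ts[in_w]
  wsym <- as.character(events$symbol)[in_w]
  ord <- order(wts)
  wts <- wts[ord]; wsym <- wsym[ord]
  m <- length(wsym)

  levs <- c(alphabet, "N")
  last <- rep("N", 4)
  if (m > 0) last[seq_len(min(m, 4))] <- rev(wsym)[seq_len(min(m, 4))]
  et <- rep(width_s, 3)
  for (k in 1:3) if (m >= k + 1) et[k] <- wts[m] - wts[m - k]
  cnt <- as.integer(table(factor(wsym, levels = alphabet)))

  out <- data.frame(last1 = factor(last[1], levels = levs),
                    last2 = factor(last[2], levels = levs),
                    last3 = factor(last[3], levels = levs),
                    last4 = factor(last[4], levels = levs),
                    et1 = et[1], et2 = et[2], et3 = et[3],
                    stringsAsFactors = FALSE)
  for (i in seq_along(alphabet)) out[[paste0("n_", alphabet[i])]] <- cnt[i]
  out
}

# 22:00 UTC boundary at or before the earliest timestamp of a night.
night_anchor <- function(ts) {
  d <- as.Date(as.POSIXct(min(as.numeric(ts)), origin = "1970-01-01",
                          tz = "UTC") - 6 * 3600, tz = "UTC")
  as.POSIXct(paste(d, "22:00:00"), tz = "UTC")
}

#' Build the labelled windowed dataset from a multi-night event log
#'
#' Slides a window of \code{width_min} minutes with step \code{step_min}
#' over each night's active span (10 p.m. to 6 a.m.), extracting one
#' feature vector per window position per night. The label is \code{TPI}
#' (early night) when the window starts before midnight and \code{!TPI}
#' otherwise; with the default 20-minute grid anchored at 10 p.m. no
#' window straddles midnight. 14 nights at the default grid give
#' 14 x 24 = 336 observations.
#'
#' @param events data.frame with \code{ts}, \code{symbol}, \code{night_id}.
#' @param width_min Window width in minutes (default 20).
#' @param step_min Window step in minutes (default = width:
#'   non-overlapping).
#' @param alphabet Event alphabet.
#' @return data.frame: \code{night_id}, \code{window_start}, 15 feature
#'   columns, and \code{label} (factor \code{TPI}/\code{!TPI}).
#' @export
build_dataset <- function(events, width_min = 20, step_min = width_min,
                          alphabet = event_alphabet()) {
  stopifnot(all(c("ts", "symbol", "night_id") %in% names(events)))
  out <- list()
  for (nid in unique(as.character(events$night_id))) {
    ev <- events[as.character(events$night_id) == nid, , drop = FALSE]
    anchor <- night_anchor(ev$ts)
    starts <- seq(from = 0, to = 8 * 60 - width_min, by = step_min) * 60
    for (s in starts) {
      w0 <- anchor + s
      fv <- extract_features(ev, w0, width_min, alphabet)
      fv$night_id <- nid
      fv$window_start <- w0
      fv$label <- factor(if (s < 2 * 3600) "TPI" else "!TPI",
                         levels = c("TPI", "!TPI"))
      out[[length(out) + 1L]] <- fv
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[, c("night_id", "window_start", feature_names(alphabet), "label")]
}

## ---- C4.5 decision tree -------------------------------------------------

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

class_counts <- function(y) {
  tab <- table(y)
  as.integer(tab)
}

# Best binary split of a numeric attribute: threshold at midpoints between
# sorted distinct values; both children must hold >= min_leaf cases.
# Returns NULL or list(gain, gain_ratio, threshold).
best_numeric_split <- function(x, y, min_leaf) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  levs <- levels(y)
  hy <- entropy_bits(table(y))
  # cumulative class counts after each position
  cum <- apply(sapply(levs, function(l) cumsum(y == l)), 2, as.numeric)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  cut_at <- which(diff(x) > 0)              # split between i and i+1
  cut_at <- cut_at[cut_at >= min_leaf & (n - cut_at) >= min_leaf]
  if (!length(cut_at)) return(NULL)
  tot <- cum[n, ]
  best <- NULL
  hl <- vapply(cut_at, function(i) entropy_bits(cum[i, ]), numeric(1))
  hr <- vapply(cut_at, function(i) entropy_bits(tot - cum[i, ]), numeric(1))
  nl <- cut_at; nr <- n - cut_at
  gain <- hy - (nl / n) * hl - (nr / n) * hr
  k <- which.max(gain)                      # first max -> smaller threshold
  split_info <- entropy_bits(c(nl[k], nr[k]))
  thr <- (x[cut_at[k]] + x[cut_at[k] + 1]) / 2
  list(gain = gain[k],
       gain_ratio = if (split_info > 0) gain[k] / split_info else 0,
       threshold = thr)
}

# Multiway split of a categorical attribute: one branch per value observed
# at the node; valid when at least two branches hold >= min_leaf cases.
best_categorical_split <- function(x, y, min_leaf) {
  x <- droplevels(factor(x))
  vals <- levels(x)
  if (length(vals) < 2) return(NULL)
  sizes <- as.integer(table(x))
  if (sum(sizes >= min_leaf) < 2) return(NULL)
  n <- length(x)
  hy <- entropy_bits(table(y))
  hk <- vapply(vals, function(v) entropy_bits(table(y[x == v])), numeric(1))
  gain <- hy - sum((sizes / n) * hk)
  split_info <- entropy_bits(sizes)
  list(gain = gain,
       gain_ratio = if (split_info > 0) gain / split_info else 0,
       values = vals)
}

# C4.5 split selection at one node: per-attribute best candidate, then
# Quinlan's mean-gain filter, then max gain ratio; ties broken by attribute
# declaration order (earlier wins).
c45_select_split <- function(data, y, features, min_leaf) {
  cands <- list()
  for (f in features) {
    x <- data[[f]]
    cand <- if (is.numeric(x)) best_numeric_split(x, y, min_leaf)
            else best_categorical_split(x, y, min_leaf)
    if (!is.null(cand) && cand$gain > 1e-12) {
      cand$attr <- f
      cands[[length(cands) + 1L]] <- cand
    }
  }
  if (!length(cands)) return(NULL)
  gains <- vapply(cands, `[[`, numeric(1), "gain")
  eligible <- gains >= mean(gains) - 1e-12
  cands <- cands[eligible]
  ratios <- vapply(cands, `[[`, numeric(1), "gain_ratio")
  cands[[which.max(ratios)]]                # first max = declaration order
}

c45_grow <- function(data, y, features, min_leaf, max_depth, depth) {
  counts <- table(y)
  maj <- names(counts)[which.max(counts)]
  leaf <- list(leaf = TRUE, label = maj, counts = counts,
               n = length(y), depth = depth)
  if (length(unique(y[!is.na(y)])) <= 1 || length(y) < 2 * min_leaf ||
      depth >= max_depth)
    return(leaf)
  sp <- c45_select_split(data, y, features, min_leaf)
  if (is.null(sp)) return(leaf)

  if (!is.null(sp$threshold)) {
    idx <- list(data[[sp$attr]] <= sp$threshold,
                data[[sp$attr]] > sp$threshold)
    branch_values <- NULL
  } else {
    idx <- lapply(sp$values, function(v) data[[sp$attr]] == v)
    branch_values <- sp$values
  }
  children <- lapply(idx, function(sel) {
    if (!any(sel)) return(list(leaf = TRUE, label = maj, counts = counts * 0,
                               n = 0L, depth = depth + 1L))
    c45_grow(data[sel, , drop = FALSE], droplevels(y[sel]) |>
               factor(levels = levels(y)),
             features, min_leaf, max_depth, depth + 1L)
  })
  sizes <- vapply(children, `[[`, numeric(1), "n")
  list(leaf = FALSE, attr = sp$attr, threshold = sp$threshold,
       values = branch_values, children = children,
       majority_child = which.max(sizes), label = maj,
       counts = counts, n = length(y), depth = depth)
}

#' Train a C4.5 decision tree
#'
#' Recursive partitioning with gain-ratio split selection: at each node the
#' candidate split of every attribute is scored (numeric attributes: the
#' binary cut at a midpoint between sorted distinct values with maximal
#' information gain; categorical attributes: one branch per observed
#' value), candidates whose information gain falls below the mean gain of
#' all candidates are discarded, and among the rest the split with the
#' highest gain ratio (gain divided by the split's intrinsic information)
#' is chosen. Ties are broken by attribute declaration order, then toward
#' the smaller threshold. Growth stops on class purity, when a node holds
#' fewer than \code{2 * min_leaf} cases, at \code{max_depth}, or when no
#' split has positive gain. No post-pruning is applied. Single-class data
#' yield a single-leaf tree.
#'
#' @param data data.frame holding the feature columns and the label column.
#' @param label Name of the label column (a factor; default
#'   \code{"label"}).
#' @param features Feature column names; defaults to every column except
#'   the label and the bookkeeping columns \code{night_id} /
#'   \code{window_start}.
#' @param min_leaf Minimum cases per child of a binary split, and minimum
#'   for a categorical branch to count toward split validity (default 5).
#' @param max_depth Maximum tree depth (default 10; the root is depth 0).
#' @return Object of class \code{c45_tree}.
#' @seealso [predict.c45_tree()], [crossval_c45()]
#' @export
train_c45 <- function(data, label = "label",
                      features = setdiff(names(data),
                                         c(label, "night_id",
                                           "window_start")),
                      min_leaf = 5L, max_depth = 10L) {
  y <- data[[label]]
  if (!is.factor(y)) y <- factor(y)
  stopifnot(length(features) >= 1, all(features %in% names(data)))
  root <- c45_grow(data[, features, drop = FALSE], y, features,
                   as.integer(min_leaf), as.integer(max_depth), 0L)
  structure(list(root = root, features = features, label = label,
                 classes = levels(y), min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth)),
            class = "c45_tree")
}

c45_route <- function(node, row) {
  while (!node$leaf) {
    x <- row[[node$attr]]
    child <- if (!is.null(node$threshold)) {
      if (is.na(x)) node$majority_child
      else if (x <= node$threshold) 1L else 2L
    } else {
      k <- match(as.character(x), node$values)
      if (is.na(k)) node$majority_child else k
    }
    node <- node$children[[child]]
  }
  node
}

#' Predict with a C4.5 tree
#'
#' Routes each observation to a leaf and returns its label. An unseen (or
#' missing) categorical value follows the majority child — the child that
#' received the most training cases.
#'
#' @param object A [train_c45()] tree.
#' @param newdata data.frame containing the tree's feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stopf("newdata lacks feature column(s): %s", paste(miss, collapse = ","))
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata)))
    out[i] <- c45_route(object$root, newdata[i, , drop = FALSE])$label
  factor(out, levels = object$classes)
}

c45_node_text <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$leaf)
    return(sprintf("%s=> %s (n=%d)", pad, node$label, node$n))
  lines <- character(0)
  if (!is.null(node$threshold)) {
    conds <- sprintf("%s %s %.4g", node$attr, c("<=", ">"), node$threshold)
  } else {
    conds <- sprintf("%s = %s", node$attr, node$values)
  }
  for (k in seq_along(node$children))
    lines <- c(lines, sprintf("%s%s", pad, conds[k]),
               c45_node_text(node$children[[k]], indent + 1))
  lines
}

#' @export
print.c45_tree <- function(x, ...) {
  cat(sprintf("C4.5 decision tree: %d features, classes {%s}\n",
              length(x$features), paste(x$classes, collapse = ", ")))
  cat(paste(c45_node_text(x$root, 0), collapse = "\n"), "\n")
  invisible(x)
}

c45_node_dot <- function(node, id, lines) {
  if (node$leaf) {
    lines <- c(lines, sprintf(
      "  n%d [shape=box,label=\"%s\\nn=%d\"];", id, node$label, node$n))
    return(list(lines = lines, next_id = id + 1L))
  }
  lines <- c(lines, sprintf("  n%d [label=\"%s\"];", id, node$attr))
  labs <- if (!is.null(node$threshold))
    sprintf("%s %.4g", c("<=", ">"), node$threshold) else node$values
  nid <- id + 1L
  for (k in seq_along(node$children)) {
    lines <- c(lines, sprintf("  n%d -> n%d [label=\"%s\"];", id, nid,
                              labs[k]))
    res <- c45_node_dot(node$children[[k]], nid, lines)
    lines <- res$lines; nid <- res$next_id
  }
  list(lines = lines, next_id = nid)
}

#' Export a C4.5 tree as DOT
#' @param tree A [train_c45()] tree.
#' @return Character string of DOT source.
#' @export
c45_tree_dot <- function(tree) {
  res <- c45_node_dot(tree$root, 0L, "digraph c45 {")
  paste(c(res$lines, "}"), collapse = "\n")
}

#' Stratified k-fold cross-validation of the C4.5 classifier
#'
#' Assigns observations to \code{k} folds stratified by class (fold sizes
#' differ by at most one per class), reproducibly from \code{seed}, and
#' reports per-fold and mean hold-out accuracy.
#'
#' @inheritParams train_c45
#' @param k Number of folds (default 10); must not exceed the number of
#'   observations.
#' @param seed Integer seed driving the fold assignment.
#' @return List of class \code{c45_cv}: \code{fold_accuracy},
#'   \code{mean_accuracy}, \code{sd_accuracy}, \code{folds} (assignment
#'   vector), \code{k}, \code{seed}.
#' @export
crossval_c45 <- function(data, k = 10L, seed = 1L, label = "label",
                         features = setdiff(names(data),
                                            c(label, "night_id",
                                              "window_start")),
                         min_leaf = 5L, max_depth = 10L) {
  n <- nrow(data)
  if (k > n) stopf("k = %d exceeds the %d observations", k, n)
  y <- data[[label]]
  if (!is.factor(y)) y <- factor(y)
  folds <- integer(n)
  with_local_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- data[folds != f, , drop = FALSE]
    te <- data[folds == f, , drop = FALSE]
    tree <- train_c45(tr, label = label, features = features,
                      min_leaf = min_leaf, max_depth = max_depth)
    pred <- predict(tree, te)
    acc[f] <- mean(as.character(pred) == as.character(te[[label]]))
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), folds = folds,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "c45_cv")
}

#' @export
print.c45_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d): mean accuracy %.3f (sd %.3f)\n",
              x$k, x$seed, x$mean_accuracy, x$sd_accuracy))
  cat("  folds:", sprintf("%.3f", x$fold_accuracy), "\n")
  invisible(x)
}
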