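test_that("feature extraction follows the window definition", {
  # empty window
  fv <- extract_features(make_events(numeric(0), character(0)), ts0)
  expect_equal(ncol(fv), 15)
  expect_equal(as.character(unlist(fv[paste0("last", 1:4)])),
               rep("N", 4))
  expect_true(all(fv[paste0("n_", event_alphabet())] == 0))
  expect_equal(fv$et1, 1200)                  # sentinel = window width (s)

  # two events: Ba then K
  ev <- make_events(c(60, 400), c("Ba", "K"))
  fv <- extract_features(ev, ts0)
  expect_equal(as.character(fv$last1), "K")
  expect_equal(as.character(fv$last2), "Ba")
  expect_equal(as.character(fv$last3), "N")
  expect_equal(fv$et1, 340)
  expect_equal(fv$n_Ba, 1L)
  expect_equal(fv$n_K, 1L)
  expect_equal(sum(fv[paste0("n_", event_alphabet())]), 2)

  # events outside [start, start + width) are ignored
  ev2 <- make_events(c(-1, 0, 1199, 1200), rep("H", 4))
  fv2 <- extract_features(ev2, ts0)
  expect_equal(fv2$n_H, 2L)

  # Et ordering when all slots are defined
  fv3 <- extract_features(make_events(c(0, 100, 250, 450, 700),
                                      c("L", "K", "H", "Ba", "Bin")), ts0)
  expect_true(fv3$et1 <= fv3$et2 && fv3$et2 <= fv3$et3)
  expect_equal(c(fv3$et1, fv3$et2, fv3$et3), c(250, 450, 600))
})

test_that("the windowed dataset has the documented size and labels", {
  ev <- do.call(rbind, lapply(1:2, function(n)
    make_events(c(600, 3600 * 4), c("K", "Ba"),
                night_id = sprintf("2024-01-%02d", n),
                origin = ts0 + (n - 1) * 86400)))
  ds <- build_dataset(ev)
  expect_equal(nrow(ds), 48)                  # 24 windows per night
  expect_equal(sum(ds$label == "TPI"), 12)    # 6 early windows per night
  expect_equal(setdiff(names(ds),
                       c("night_id", "window_start", "label")),
               feature_names())
  # no window straddles midnight on the default grid
  off <- (as.numeric(ds$window_start) -
            as.numeric(ds$window_start[1])) %% 86400
  expect_true(all(off %% 1200 == 0))
  expect_true(all(off != 7200 - 600))
})

test_that("14 simulated nights yield 336 observations", {
  cfg <- night_scenario(seed = 3)
  recs <- simulate_nights(cfg)
  ev <- do.call(rbind, lapply(recs, night_events, bed = "true"))
  ds <- build_dataset(ev)
  expect_equal(nrow(ds), 14 * 24)
  expect_gte(nrow(ds), 300)
})

test_that("gain ratio matches a hand-computed six-row table", {
  # A splits 6 rows into (2+,1-) and (1+,2-): H(3+,3-) = 1 bit,
  # gain = 1 - H(1/3) ~ 0.0817, split info = 1 => ratio = gain.
  toy <- data.frame(A = factor(rep(c("a", "b"), each = 3)),
                    B = factor(c("x", "x", "y", "x", "y", "y")),
                    label = factor(c("+", "+", "-", "+", "-", "-")))
  expect_equal(entropy2(toy$label), 1)
  tree <- train_c45(toy, features = "A", min_leaf = 1)
  sp <- nightwatch:::best_categorical_split(toy$A, toy$label, 1)
  expect_equal(sp$gain, 1 - (log2(3) - 2 / 3), tolerance = 1e-12)
  expect_equal(sp$gain_ratio, sp$gain, tolerance = 1e-12)

  # B is class-perfect: gain 1, split info 1, ratio 1; chosen over A
  tree2 <- train_c45(toy, features = c("A", "B"), min_leaf = 1)
  expect_false(tree2$root$leaf)
  expect_equal(tree2$root$attr, "B")
  expect_equal(mean(predict(tree2, toy) == toy$label), 1)
  expect_equal(tree2$root$depth, 0)
  expect_true(all(vapply(tree2$root$children, `[[`, logical(1), "leaf")))

  # numeric split: 1..6 labelled +++--- cuts at 3.5 with gain 1
  num <- data.frame(x = 1:6,
                    label = factor(rep(c("+", "-"), each = 3)))
  sp <- nightwatch:::best_numeric_split(num$x, num$label, 1)
  expect_equal(sp$threshold, 3.5)
  expect_equal(sp$gain, 1)
})

test_that("every chosen split survives an exhaustive node re-scan", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      n <- 80
      d <- data.frame(
        u = round(runif(n), 2),
        v = sample(0:4, n, replace = TRUE),
        g = factor(sample(c("p", "q", "r"), n, replace = TRUE)),
        label = factor(sample(c("TPI", "!TPI"), n, replace = TRUE,
                              prob = c(0.4, 0.6))))
      # plant structure so the tree is non-trivial
      d$label[d$u > 0.6 & d$v >= 2] <- "TPI"
      tree <- train_c45(d, min_leaf = 3, max_depth = 5)
      check_tree_nodes(tree$root, d[tree$features], d$label,
                       tree$features, 3)
    }
  })
})

test_that("the tree is invariant to observation order", {
  withr::with_seed(65, {
    n <- 60
    d <- data.frame(u = runif(n), g = factor(sample(letters[1:3], n, TRUE)),
                    label = factor(sample(c("+", "-"), n, TRUE)))
    d$label[d$u > 0.5] <- "+"
    t1 <- train_c45(d, min_leaf = 3)
    d2 <- d[sample(n), ]
    t2 <- train_c45(d2, min_leaf = 3)
    expect_equal(t1$root$attr, t2$root$attr)
    expect_equal(capture.output(print(t1)), capture.output(print(t2)))
  })
})

test_that("unseen categorical values route to the majority child", {
  d <- data.frame(g = factor(rep(c("a", "b", "c"), times = c(6, 3, 3))),
                  label = factor(rep(c("+", "-", "+"), times = c(6, 3, 3))))
  tree <- train_c45(d, min_leaf = 1)
  expect_equal(tree$root$attr, "g")
  nd <- data.frame(g = factor("zz"))
  # majority child is the 'a' branch (6 cases) labelled '+'
  expect_equal(as.character(predict(tree, nd)), "+")
  expect_error(predict(tree, data.frame(x = 1)), "lacks feature")
})

test_that("single-class data give a single-leaf tree", {
  d <- data.frame(x = 1:10, label = factor(rep("TPI", 10),
                                           levels = c("TPI", "!TPI")))
  tree <- train_c45(d)
  expect_true(tree$root$leaf)
  expect_equal(as.character(predict(tree, d)), rep("TPI", 10))
})

test_that("planted kitchen-only-early structure is found at the root", {
  # identical event-time geometry early and late; only the room differs
  # (kitchen before midnight, bathroom after), so timing features carry
  # no signal and the split must land on a kitchen-bearing feature
  ev <- do.call(rbind, lapply(1:6, function(n) {
    org <- ts0 + (n - 1) * 86400
    offs <- as.vector(outer(c(100, 400, 900), seq(0, 8 * 3600 - 1200,
                                                  by = 1200), "+"))
    sym <- ifelse(offs < 7200, "K", "Ba")
    make_events(sort(offs), sym[order(offs)],
                night_id = sprintf("k%02d", n), origin = org)
  }))
  ds <- build_dataset(ev)
  tree <- train_c45(ds)
  kitchenish <- tree$root$attr == "n_K" ||
    (!is.null(tree$root$values) && "K" %in% tree$root$values)
  expect_true(kitchenish)
  expect_equal(mean(predict(tree, ds) == ds$label), 1)
})

test_that("stratified folds partition the data", {
  cfg <- night_scenario(seed = 9, n_nights = 4)
  ds <- build_dataset(do.call(rbind, lapply(simulate_nights(cfg),
                                            night_events, bed = "true")))
  cv <- crossval_c45(ds, k = 10, seed = 42)
  expect_length(cv$folds, nrow(ds))
  expect_equal(sort(unique(cv$folds)), 1:10)
  sizes <- table(cv$folds)
  expect_lte(diff(range(sizes)), 2)           # per-class balance, 2 classes
  for (cl in levels(ds$label)) {
    szc <- table(cv$folds[ds$label == cl])
    expect_lte(diff(range(szc)), 1)
  }
  # reproducible from the seed
  cv2 <- crossval_c45(ds, k = 10, seed = 42)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$fold_accuracy, cv2$fold_accuracy)
  expect_error(crossval_c45(ds[1:5, ], k = 10), "exceeds")
})

test_that("cross-validation scores separable and shuffled data sanely", {
  # perfectly separable planted dataset
  withr::with_seed(70, {
    n <- 100
    d <- data.frame(x = c(rnorm(n / 2, 0), rnorm(n / 2, 10)),
                    label = factor(rep(c("TPI", "!TPI"), each = n / 2)))
    cv <- crossval_c45(d, k = 10, seed = 1)
    expect_equal(cv$mean_accuracy, 1.0)
  })
  # label-shuffled data score near the majority rate
  cfg <- night_scenario(seed = 17, n_nights = 6)
  ds <- build_dataset(do.call(rbind, lapply(simulate_nights(cfg),
                                            night_events, bed = "true")))
  ds$label <- withr::with_seed(8, sample(ds$label))
  cv <- crossval_c45(ds, k = 10, seed = 2)
  baseline <- max(table(ds$label)) / nrow(ds)
  expect_lte(abs(cv$mean_accuracy - baseline), 0.1)
})

test_that("the classifier beats the majority baseline on planted nights", {
  cfg <- night_scenario(seed = 5)
  ds <- build_dataset(do.call(rbind, lapply(simulate_nights(cfg),
                                            night_events, bed = "true")))
  cv <- crossval_c45(ds, k = 10, seed = 99)
  baseline <- max(table(ds$label)) / nrow(ds)
  expect_gte(cv$mean_accuracy, baseline + 0.10)
})
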