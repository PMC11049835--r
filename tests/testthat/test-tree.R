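test_that("gini impurity follows the class-probability definition", {
  expect_equal(gini_impurity(0, 10), 0)
  expect_equal(gini_impurity(5, 5), 0.5)
  expect_equal(gini_impurity(150, 100), 0.48)  # 1 - (0.6^2 + 0.4^2)
  expect_error(gini_impurity(0, 0), "at least one")
})

test_that("best_split finds the separating midpoint of a clean partition", {
  s <- best_split(c(1, 2, 3, 10, 11, 12), rep(c("low", "high"), each = 3))
  expect_equal(s$threshold, 6.5)
  expect_equal(s$weighted_gini, 0)
  expect_null(best_split(rep(4, 6), rep(c("low", "high"), each = 3)))
  expect_null(best_split(1:6, rep("low", 6)))
})

test_that("best_split equals exhaustive search on random instances", {
  set.seed(200)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    values <- if (i %% 3 == 0) sample(1:8, n, replace = TRUE) else runif(n)
    labels <- sample(c("low", "high"), n, replace = TRUE)
    ml <- sample(1:3, 1)
    got <- best_split(values, labels, min_leaf = ml)
    want <- brute_best_split(values, labels, min_leaf = ml)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$weighted_gini, want$weighted_gini)
    }
  }
})

test_that("every accepted split reduces the weighted impurity", {
  set.seed(201)
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    l <- node$children$left; r <- node$children$right
    nl <- l$n_low + l$n_high; nr <- r$n_low + r$n_high
    wg <- (nl * l$gini + nr * r$gini) / (nl + nr)
    expect_lt(wg, node$gini)
    walk(l); walk(r)
  }
  for (i in 1:10) {
    n <- 80
    x <- data.frame(itd = runif(n), cta = runif(n))
    labels <- ifelse(x$cta + rnorm(n, 0, 0.2) > 0.5, "low", "high")
    if (length(unique(labels)) < 2) next
    walk(gini_tree(x, labels, max_depth = 3, min_leaf = 2)$root)
  }
})

test_that("fitted root agrees with the reference CART implementation", {
  set.seed(202)
  for (i in 1:5) {
    n <- 120
    x <- data.frame(itd = round(runif(n), 2), cta = round(runif(n), 2))
    labels <- ifelse(x$cta + rnorm(n, 0, 0.15) > 0.5, "low", "high")
    if (min(table(labels)) < 10) next
    ours <- gini_tree(x, labels, max_depth = 1, min_leaf = 5)
    ref <- rpart::rpart(factor(labels) ~ itd + cta, data = x,
                        method = "class", parms = list(split = "gini"),
                        control = rpart::rpart.control(minsplit = 10,
                                                       minbucket = 5, cp = 0,
                                                       maxdepth = 1, xval = 0))
    expect_identical(ours$root$feature, rownames(ref$splits)[1])
    expect_equal(ours$root$threshold, unname(ref$splits[1, "index"]),
                 tolerance = 1e-6)
  }
})

test_that("prediction routes rows to leaves; ties predict low", {
  x <- data.frame(itd = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9, 0.75, 0.15),
                  cta = c(0.5, 0.4, 0.6, 0.5, 0.4, 0.6, 0.55, 0.45))
  labels <- c("high", "high", "high", "low", "low", "low", "low", "high")
  tr <- gini_tree(x, labels, max_depth = 1, min_leaf = 1)
  expect_identical(tr$root$feature, "itd")
  pred <- predict(tr, data.frame(itd = c(0.05, 0.95), cta = c(0.5, 0.5)))
  expect_identical(pred, c("high", "low"))
  # a perfectly balanced leaf predicts the low class
  tie <- gini_tree(data.frame(itd = c(1, 1), cta = c(1, 1)), c("low", "high"))
  expect_identical(tie$root$prediction, "low")
  expect_null(tie$root$children)
  # single-class input gives a depth-0 leaf for that class
  leaf <- gini_tree(data.frame(itd = 1:4, cta = 4:1), rep("high", 4))
  expect_null(leaf$root$children)
  expect_identical(predict(leaf, data.frame(itd = 2, cta = 2)), "high")
})

test_that("trees accept measurement tables and serialize to JSON", {
  set.seed(203)
  meas <- data.frame(class = rep(c("low", "high"), each = 40),
                     itd = runif(80),
                     cta = c(rbeta(40, 9, 16), rbeta(40, 10, 38)),
                     qc_pass = rep(c(TRUE, FALSE), 40))
  tr <- gini_tree(meas)
  expect_equal(tr$n, 40)
  js <- jsonlite::fromJSON(tree_to_json(tr))
  expect_true(all(c("n_low", "n_high", "gini", "prediction") %in% names(js)))
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tr, path)
  expect_true(file.exists(path))
  # children counts sum to the parent's
  if (!is.null(tr$root$children)) {
    kids <- tr$root$children
    expect_equal(kids$left$n_low + kids$right$n_low, tr$root$n_low)
    expect_equal(kids$left$n_high + kids$right$n_high, tr$root$n_high)
  }
})
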