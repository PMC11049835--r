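# From-scratch binary classification tree with the Gini splitting criterion.

#' Gini impurity of a two-class node
#'
#' One minus the sum of squared class probabilities; 0 for a pure node, 0.5
#' for a balanced two-class node.
#'
#' @param n_low,n_high Class counts, `n_low + n_high >= 1`.
#' @return Impurity in `[0, 0.5]`.
#' @export
gini_impurity <- function(n_low, n_high) {
  n <- n_low + n_high
  if (n < 1) stop("node must contain at least one sample", call. = FALSE)
  p_low <- n_low / n
  1 - p_low^2 - (1 - p_low)^2
}

#' Best Gini split of one feature
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' values; the returned threshold minimizes the size-weighted mean child
#' impurity of the `(<= t, > t)` partition, ties broken by the smallest
#' threshold. `min_leaf` restricts candidates to splits leaving at least
#' that many samples on each side.
#'
#' @param values Numeric feature values.
#' @param labels Class labels with two levels (`"low"`/`"high"`).
#' @param min_leaf Minimum child size.
#' @return List with `threshold` and `weighted_gini`, or `NULL` when no
#'   split exists (single class, all values equal, or `min_leaf`
#'   unsatisfiable).
#' @export
best_split <- function(values, labels, min_leaf = 1L) {
  n <- length(values)
  if (n < 2L || length(unique(labels)) < 2L) return(NULL)
  ord <- order(values)
  v <- values[ord]
  is_low <- labels[ord] == "low"
  n_low <- sum(is_low)
  cum_low <- cumsum(is_low)
  i <- seq_len(n - 1L)
  boundary <- which(v[i] < v[i + 1L])          # between distinct values
  boundary <- boundary[boundary >= min_leaf & (n - boundary) >= min_leaf]
  if (length(boundary) == 0L) return(NULL)
  nl <- boundary                                # left child sizes
  ll <- cum_low[boundary]                       # low-class counts on the left
  gini_l <- 1 - (ll / nl)^2 - ((nl - ll) / nl)^2
  nr <- n - nl
  lr <- n_low - ll
  gini_r <- 1 - (lr / nr)^2 - ((nr - lr) / nr)^2
  wg <- (nl * gini_l + nr * gini_r) / n
  # ties broken by the smallest threshold; the tolerance keeps exact ties
  # that differ only by accumulated floating-point error together
  best <- which(wg <= min(wg) + 1e-12)[1L]
  list(threshold = (v[boundary[best]] + v[boundary[best] + 1L]) / 2,
       weighted_gini = wg[best])
}

build_node <- function(x, labels, depth, max_depth, min_leaf) {
  n_low <- sum(labels == "low"); n_high <- sum(labels == "high")
  node <- list(n_low = n_low, n_high = n_high,
               gini = gini_impurity(n_low, n_high),
               prediction = if (n_high > n_low) "high" else "low")
  if (depth >= max_depth || node$gini == 0 ||
      (n_low + n_high) < 2L * min_leaf)
    return(node)
  cands <- lapply(names(x), function(f) best_split(x[[f]], labels, min_leaf))
  ok <- !vapply(cands, is.null, TRUE)
  if (!any(ok)) return(node)
  wg <- vapply(cands[ok], `[[`, 0, "weighted_gini")
  pick <- which(ok)[which.min(wg)]              # feature ties: first column
  sp <- cands[[pick]]
  if (sp$weighted_gini >= node$gini - 1e-12) return(node)
  f <- names(x)[pick]
  left <- x[[f]] <= sp$threshold
  node$feature <- f
  node$threshold <- sp$threshold
  node$children <- list(
    left  = build_node(x[left, , drop = FALSE], labels[left],
                       depth + 1L, max_depth, min_leaf),
    right = build_node(x[!left, , drop = FALSE], labels[!left],
                       depth + 1L, max_depth, min_leaf))
  node
}

#' Fit a Gini decision tree on per-cell (ITD, CTA) measurements
#'
#' Greedy recursive binary partitioning: at each node the (feature,
#' threshold) pair minimizing the size-weighted child Gini impurity is
#' chosen among midpoint thresholds; recursion stops at `max_depth`, node
#' purity, `min_leaf`, or when no split reduces the impurity. No pruning.
#' Leaves predict their majority class, ties going to `"low"`.
#'
#' @param x Data frame of numeric features (e.g. columns `itd`, `cta`), or
#'   a measurement table from [measure_cells()] (QC-passing rows are used
#'   and the `class` column supplies `labels`).
#' @param labels Class labels (`"low"`/`"high"`); taken from `x$class` if
#'   omitted.
#' @param max_depth Maximum depth (root = depth 0 splits once at
#'   `max_depth = 1`); default 2, a shallow clinically readable tree.
#' @param min_leaf Minimum samples per leaf.
#' @return Object of class `gini_tree` with elements `root`, `features`,
#'   `n`, `call`.
#' @export
gini_tree <- function(x, labels = NULL, max_depth = 2L, min_leaf = 5L) {
  cl <- match.call()
  x <- as.data.frame(x)
  if (is.null(labels)) {
    if (!"class" %in% names(x))
      stop("`labels` missing and no `class` column in `x`", call. = FALSE)
    if ("qc_pass" %in% names(x)) x <- x[x$qc_pass, ]
    labels <- x$class
    x <- x[, intersect(c("itd", "cta"), names(x)), drop = FALSE]
  }
  if (!all(labels %in% c("low", "high")))
    stop("labels must be 'low' or 'high'", call. = FALSE)
  if (ncol(x) < 1L) stop("no features", call. = FALSE)
  if (!all(vapply(x, is.numeric, TRUE))) stop("features must be numeric",
                                              call. = FALSE)
  if (nrow(x) < 1L) stop("no samples", call. = FALSE)
  root <- build_node(x, as.character(labels), 0L,
                     as.integer(max_depth), as.integer(min_leaf))
  structure(list(root = root, features = names(x), n = nrow(x), call = cl),
            class = "gini_tree")
}

#' @export
predict.gini_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  route <- function(node, row) {
    while (!is.null(node$children)) {
      node <- if (row[[node$feature]] <= node$threshold)
        node$children$left else node$children$right
    }
    node$prediction
  }
  vapply(seq_len(nrow(newdata)), function(i) route(object$root, newdata[i, ]),
         "")
}

format_node <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  head <- sprintf("%sn=%d (low %d / high %d), gini %.3f -> %s",
                  pad, node$n_low + node$n_high, node$n_low, node$n_high,
                  node$gini, node$prediction)
  if (is.null(node$children)) return(head)
  c(sprintf("%s, split %s <= %.4g", head, node$feature, node$threshold),
    format_node(node$children$left, indent + 1L),
    format_node(node$children$right, indent + 1L))
}

#' @export
print.gini_tree <- function(x, ...) {
  cat(sprintf("<gini_tree> %d samples, features: %s\n", x$n,
              paste(x$features, collapse = ", ")))
  cat(format_node(x$root), sep = "\n")
  invisible(x)
}

#' @export
summary.gini_tree <- function(object, ...) {
  r <- object$root
  cat(sprintf("Gini decision tree on %d cells\n", object$n))
  if (is.null(r$children)) {
    cat("  (single leaf)\n")
  } else {
    cat(sprintf("  root split: %s <= %.4g (weighted child gini via split; node gini %.3f)\n",
                r$feature, r$threshold, r$gini))
  }
  invisible(object)
}

node_to_list <- function(node) {
  out <- list(n_low = node$n_low, n_high = node$n_high, gini = node$gini,
              prediction = node$prediction)
  if (!is.null(node$children)) {
    out$feature <- node$feature
    out$threshold <- node$threshold
    out$children <- list(left = node_to_list(node$children$left),
                         right = node_to_list(node$children$right))
  }
  out
}

#' Serialize a fitted tree to JSON
#'
#' @param tree A `gini_tree`.
#' @param path Optional file to write.
#' @return JSON string (invisibly when `path` is given).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "gini_tree"))
  js <- jsonlite::toJSON(node_to_list(tree$root), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
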