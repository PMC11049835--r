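# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_presets <- function() cached("presets", default_presets())

# One clean rendered low-score cell plus its truth, fixed seed.
clean_cell <- function(seed = 101, noise_scale = 1, class = "low_score",
                       n_spots_override = NULL) {
  set.seed(seed)
  truth <- sample_cell_truth(test_presets()[[class]])
  img <- render_cell_image(truth,
                           render_config(noise_scale = noise_scale,
                                         n_spots_override = n_spots_override))
  list(truth = truth, image = img)
}

# Noiseless axis-independent test ellipse built from scratch (independent of
# the package's mask code): semi-axes in px, angle in radians.
ellipse_image <- function(a = 27, b = 18, theta = 0, size = 128,
                          bg = 500, fg = 3000) {
  ctr <- (size - 1) / 2
  rr <- matrix(0:(size - 1), size, size)
  cc <- matrix(0:(size - 1), size, size, byrow = TRUE)
  u <- (cc - ctr) * cos(theta) + (rr - ctr) * sin(theta)
  v <- -(cc - ctr) * sin(theta) + (rr - ctr) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ch <- matrix(bg, size, size)
  ch[inside] <- fg
  px <- array(bg, dim = c(size, size, 3))
  px[, , 1] <- ch
  list(image = calibrated_image(px), mask = inside)
}

# Brute-force weighted-Gini split search, written independently of the
# package implementation: direct counting at every midpoint.
brute_best_split <- function(values, labels, min_leaf = 1) {
  sv <- sort(unique(values))
  if (length(sv) < 2 || length(unique(labels)) < 2) return(NULL)
  thr <- (sv[-length(sv)] + sv[-1]) / 2
  g <- function(lab) {
    if (length(lab) == 0) return(0)
    p <- mean(lab == "low")
    1 - p^2 - (1 - p)^2
  }
  best <- NULL
  for (t in thr) {
    l <- labels[values <= t]; r <- labels[values > t]
    if (length(l) < min_leaf || length(r) < min_leaf) next
    wg <- (length(l) * g(l) + length(r) * g(r)) / length(values)
    if (is.null(best) || wg < best$weighted_gini - 1e-15)
      best <- list(threshold = t, weighted_gini = wg)
  }
  best
}

# Full default-design dataset (5 subjects x 50 cells, seed 1), rendered and
# measured once for the acceptance checks.
acceptance_run <- function() {
  cached("acceptance_run", {
    ds <- generate_dataset(default_design(seed = 1))
    list(truth = ds$truth, meas = measure_cells(ds))
  })
}

# Truth-only datasets for seeds 1..20 (statistical properties across seeds).
truth_only_runs <- function() {
  cached("truth_only_runs", lapply(1:20, function(s)
    generate_dataset(default_design(seed = s), render = FALSE)$truth))
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every split of
# the pooled values into an x-group; U counted directly over (x, y) pairs.
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  count_u <- function(xs, ys) {
    u <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
    min(u, length(xs) * length(ys) - u)
  }
  u_obs <- count_u(x, y)
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(idx)
    count_u(pooled[idx], pooled[-idx]))
  mean(u_all <= u_obs + 1e-9)
}
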