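# Nonparametric two-group comparison of per-cell metrics.

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midranks as `min(U_x, U_y)`. With `n_x + n_y <= 12`
#' and no ties the p-value is exact, by full enumeration of all rank
#' assignments (`p = P(min-U <= observed)`, two-sided since the min
#' convention folds both tails); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric vectors, each non-empty and finite.
#' @param exact_max_n Largest pooled n for the exact-enumeration path.
#' @return List with `u` (min-convention U), `z`, `p_two_sided`, `exact`.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("empty group", call. = FALSE)
  if (!all(is.finite(c(x, y)))) stop("values must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- min(ux, uy)
  ties <- any(duplicated(pooled))
  if (n <= exact_max_n && !ties) {
    # enumerate every assignment of ranks 1..n to the x-group; the min-U
    # convention already folds both tails, so P(U' <= u) is two-sided
    combos <- utils::combn(n, nx)
    u_all <- colSums(combos) - nx * (nx + 1) / 2
    u_all <- pmin(u_all, nx * ny - u_all)
    p <- mean(u_all <= u)
    return(list(u = u, z = 0, p_two_sided = p, exact = TRUE))
  }
  mu <- nx * ny / 2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sd_u <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
  if (sd_u == 0) return(list(u = u, z = 0, p_two_sided = 1, exact = FALSE))
  z <- if (u == mu) 0 else (u - mu + 0.5) / sd_u  # u <= mu by construction
  p <- min(1, 2 * stats::pnorm(z))
  list(u = u, z = z, p_two_sided = p, exact = FALSE)
}

#' Median and percentile interval of per-cell values
#'
#' The interval is the 2.5th-97.5th percentile range of the values
#' themselves (linear interpolation), i.e. the spread of single cells — not
#' a confidence interval of the median.
#'
#' @param values Numeric, non-empty.
#' @param probs Two percentile probabilities.
#' @return List with `median` and `interval` (length 2).
#' @export
summarize_metric <- function(values, probs = c(0.025, 0.975)) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("no values to summarize", call. = FALSE)
  list(median = stats::median(values),
       interval = unname(stats::quantile(values, probs, type = 7)))
}

#' Compare one metric between the low- and high-score groups
#'
#' Cells failing QC are excluded; cells are pooled per class (subject-level
#' clustering is deliberately ignored, matching the study design of pooling
#' 50 analyzable cells per subject).
#'
#' @param measurements Data frame from [measure_cells()] (columns `class`,
#'   `qc_pass` and the metric), or a truth table with `true_<metric>`
#'   columns.
#' @param metric `"itd"` or `"cta"`.
#' @return Object of class `group_comparison`.
#' @export
compare_groups <- function(measurements, metric = c("itd", "cta")) {
  metric <- match.arg(metric)
  df <- as.data.frame(measurements)
  col <- if (metric %in% names(df)) metric else paste0("true_", metric)
  if (!col %in% names(df)) stop(sprintf("no column for metric '%s'", metric),
                                call. = FALSE)
  if ("qc_pass" %in% names(df)) df <- df[df$qc_pass, ]
  lo <- df[[col]][df$class == "low"]
  hi <- df[[col]][df$class == "high"]
  if (length(lo) == 0L || length(hi) == 0L)
    stop("both classes must be present among QC-passing cells", call. = FALSE)
  mw <- mann_whitney_u(lo, hi)
  s_lo <- summarize_metric(lo); s_hi <- summarize_metric(hi)
  structure(list(metric = metric, n_low = length(lo), n_high = length(hi),
                 u_statistic = mw$u, z_value = mw$z,
                 p_two_sided = mw$p_two_sided, exact = mw$exact,
                 median_low = s_lo$median, median_high = s_hi$median,
                 interval_low = s_lo$interval, interval_high = s_hi$interval),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: low n=%d median %.3f [%.3f, %.3f] vs high n=%d median %.3f [%.3f, %.3f]\n",
              toupper(x$metric), x$n_low, x$median_low, x$interval_low[1L],
              x$interval_low[2L], x$n_high, x$median_high,
              x$interval_high[1L], x$interval_high[2L]))
  cat(sprintf("  Mann-Whitney U = %.1f, z = %.2f, two-sided p %s\n",
              x$u_statistic, x$z_value,
              if (x$p_two_sided < 1e-12) "< 1e-12"
              else format(x$p_two_sided, digits = 3)))
  invisible(x)
}

#' Per-subject summary table
#'
#' Transparency companion to the pooled analysis: median ITD/CTA and cell
#' counts per subject.
#'
#' @param measurements Data frame from [measure_cells()].
#' @return Data frame, one row per subject.
#' @export
subject_summary <- function(measurements) {
  df <- measurements[measurements$qc_pass, ]
  ids <- unique(measurements$subject_id)
  do.call(rbind, lapply(ids, function(s) {
    d <- df[df$subject_id == s, ]
    data.frame(subject_id = s,
               class = measurements$class[measurements$subject_id == s][1L],
               n_cells = sum(measurements$subject_id == s),
               n_qc_pass = nrow(d),
               median_itd = if (nrow(d)) stats::median(d$itd) else NA_real_,
               median_cta = if (nrow(d)) stats::median(d$cta) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
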