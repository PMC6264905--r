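#' Construct a growth curve
#'
#' Bundles one well's OD595 time series with its strain, condition and
#' replicate labels, validating the invariants the downstream rate
#' estimators rely on.
#'
#' @param times Numeric vector, minutes since inoculation, strictly increasing.
#' @param od Numeric vector of OD595 readings aligned to `times`, all >= 0.
#' @param strain_id,condition Labels.
#' @param replicate Integer replicate index (>= 1).
#' @return An object of class `growth_curve`.
#' @examples
#' gc <- growth_curve(seq(0, 600, 10), seq(0.1, 0.71, 0.01), "anc", "YPD_28C")
#' max_growth_rate(gc)
#' @export
growth_curve <- function(times, od, strain_id = "strain", condition = "condition",
                         replicate = 1L) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od)) {
    stop("'times' and 'od' must have the same length", call. = FALSE)
  }
  ok <- is.finite(times)
  if (any(diff(times[ok]) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(od[is.finite(od)] < 0)) {
    stop("'od' readings must be non-negative", call. = FALSE)
  }
  if (!is.numeric(replicate) || replicate < 1) {
    stop("'replicate' must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(times = times, od = od, strain_id = as.character(strain_id),
         condition = as.character(condition), replicate = as.integer(replicate)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s / %s (rep %d): %d readings, %.0f-%.0f min\n",
              x$strain_id, x$condition, x$replicate, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Sliding-window growth rates from an OD time series
#'
#' Computes one growth rate per contiguous window of `window` readings
#' (stride 1). Each rate is the least-squares slope of OD (optionally
#' log OD) against time in hours, i.e. OD595 per hour. Windows containing
#' any non-finite reading are skipped with a message rather than imputed.
#'
#' @param curve A [growth_curve()].
#' @param window Window size in readings (default 10, i.e. 90 minutes at
#'   the standard 10-minute sampling interval).
#' @param log_od If `TRUE`, regress `log(od)` on time, giving the
#'   exponential-phase specific growth rate per hour instead of the linear
#'   OD slope. All windowed OD values must then be positive.
#' @param method `"regression"` (ordinary least squares within the window,
#'   the default) or `"endpoint"` (last minus first reading over the window
#'   span).
#' @param baseline Constant OD subtracted from every reading before slope
#'   estimation (default 0; slopes are unaffected, but `log_od` is not).
#' @param od_ceiling If non-`NULL`, the series is truncated after the first
#'   reading exceeding this OD (e.g. to stop before the diauxic shift).
#' @return Data frame with columns `window_start` (minutes), `rate`
#'   (OD595/hour) and `n_points`, one row per retained window.
#' @export
sliding_window_rates <- function(curve, window = 10L, log_od = FALSE,
                                 method = c("regression", "endpoint"),
                                 baseline = 0, od_ceiling = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 2L) stop("'window' must be at least 2 points", call. = FALSE)

  times <- curve$times
  od <- curve$od - baseline
  if (!is.null(od_ceiling)) {
    over <- which(od > od_ceiling)
    if (length(over) > 0L && over[1] > 1L) {
      keep <- seq_len(over[1])
      times <- times[keep]
      od <- od[keep]
    }
  }
  n <- length(times)
  if (n < window) {
    stop(sprintf(
      "curve '%s' has %d points but the %d-point window requires at least %d",
      curve$strain_id, n, window, window), call. = FALSE)
  }

  y <- if (log_od) {
    if (any(od[is.finite(od)] <= 0)) {
      stop("log_od = TRUE requires strictly positive OD values", call. = FALSE)
    }
    log(od)
  } else {
    od
  }
  th <- times / 60  # hours

  starts <- seq_len(n - window + 1L)
  rate <- numeric(length(starts))
  keep <- logical(length(starts))
  for (i in starts) {
    idx <- i:(i + window - 1L)
    yi <- y[idx]
    xi <- th[idx]
    if (any(!is.finite(yi))) next
    keep[i] <- TRUE
    if (method == "endpoint") {
      rate[i] <- (yi[window] - yi[1]) / (xi[window] - xi[1])
    } else {
      xc <- xi - mean(xi)
      rate[i] <- sum(xc * yi) / sum(xc * xc)
    }
  }
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(sprintf("sliding_window_rates: skipped %d window(s) with missing readings in '%s'",
                    n_skipped, curve$strain_id))
  }
  data.frame(
    window_start = times[starts[keep]],
    rate = rate[keep],
    n_points = window
  )
}

#' Maximal growth rate of a curve
#'
#' The maximum of the sliding-window rates is taken as the fitness value of
#' the well; ties are broken in favour of the earliest window.
#'
#' @inheritParams sliding_window_rates
#' @param ... Passed on to [sliding_window_rates()].
#' @return A list of class `fitness_value` with elements `rate` (OD595/hour),
#'   `window_start` (minutes), `n_points`, `strain_id`, `condition`,
#'   `replicate`.
#' @export
max_growth_rate <- function(curve, window = 10L, ...) {
  rates <- sliding_window_rates(curve, window = window, ...)
  if (nrow(rates) == 0L) {
    stop("no usable windows in curve '", curve$strain_id, "'", call. = FALSE)
  }
  i <- which.max(rates$rate)  # which.max returns the first maximum
  structure(
    list(rate = rates$rate[i], window_start = rates$window_start[i],
         n_points = rates$n_points[i], strain_id = curve$strain_id,
         condition = curve$condition, replicate = curve$replicate),
    class = "fitness_value"
  )
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf("<fitness_value> %s / %s (rep %d): %.4f OD595/h (window at %.0f min)\n",
              x$strain_id, x$condition, x$replicate, x$rate, x$window_start))
  invisible(x)
}

#' Percent fitness improvement over an ancestor
#'
#' Computes (F_x / F_a - 1) x 100 where F_x is the fitness (maximal growth
#' rate) of an evolved or reconstituted clone and F_a that of the ancestral
#' strain measured in the same condition.
#'
#' @param f_evolved,f_ancestor Either `fitness_value` objects from
#'   [max_growth_rate()] or bare positive rates.
#' @return Data frame with `strain_id`, `condition` and
#'   `improvement_percent`.
#' @export
fitness_improvement <- function(f_evolved, f_ancestor) {
  fx <- if (inherits(f_evolved, "fitness_value")) f_evolved$rate else as.numeric(f_evolved)
  fa <- if (inherits(f_ancestor, "fitness_value")) f_ancestor$rate else as.numeric(f_ancestor)
  stop_if_not_scalar_number(fx, "f_evolved")
  if (!is.numeric(fa) || length(fa) != 1L || !is.finite(fa) || fa <= 0) {
    stop("ancestor fitness must be a positive number", call. = FALSE)
  }
  data.frame(
    strain_id = if (inherits(f_evolved, "fitness_value")) f_evolved$strain_id else NA_character_,
    condition = if (inherits(f_evolved, "fitness_value")) f_evolved$condition else NA_character_,
    improvement_percent = (fx / fa - 1) * 100
  )
}

#' One-tailed Welch t test (unequal variances)
#'
#' Two-sample t statistic with the Welch-Satterthwaite degrees of freedom,
#' as used to compare fitness improvements between groups of evolved
#' populations.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values with nonzero
#'   variance).
#' @param alternative `"less"` (mean of `group_a` smaller) or `"greater"`.
#' @return List with `t`, `df` and one-tailed `p`.
#' @export
welch_t_one_tailed <- function(group_a, group_b, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("degenerate input: both groups have zero variance", call. = FALSE)
  }
  fit <- stats::t.test(group_a, group_b, alternative = alternative,
                       var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' One-tailed paired t test
#'
#' Classical paired t test on within-pair differences (df = n_pairs - 1),
#' as used for the same clones measured with two different plasmids.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2 pairs), or `x`
#'   may be a two-column matrix/data frame of pairs with `y` omitted.
#' @param alternative `"less"` or `"greater"` for the mean of `x - y`.
#' @return List with `t`, `df` and one-tailed `p`.
#' @export
paired_t_one_tailed <- function(x, y = NULL, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(y)) {
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop("'x' must have two columns when 'y' is omitted", call. = FALSE)
    y <- x[, 2]
    x <- x[, 1]
  }
  if (length(x) != length(y)) stop("pairs must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::var(d) == 0) {
    stop("degenerate input: zero variance of paired differences", call. = FALSE)
  }
  fit <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control across a vector of p-values.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Shapiro-Wilk normality check
#'
#' Convenience utility mirroring the normality checks reported alongside
#' the t tests; never gates any computation in this package.
#'
#' @param x Numeric vector (3 to 5000 values).
#' @return List with `W` and `p`.
#' @export
shapiro_check <- function(x) {
  fit <- stats::shapiro.test(x)
  list(W = unname(fit$statistic), p = unname(fit$p.value))
}
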