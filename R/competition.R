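#' Generations per serial transfer
#'
#' Number of doublings implied by regrowth after a fold-dilution:
#' log2(dilution_factor). A daily 1,000-fold dilution therefore corresponds
#' to about 10 generations per day.
#'
#' @param dilution_factor Fold dilution per transfer (> 1).
#' @return Generations per transfer.
#' @export
generations_per_transfer <- function(dilution_factor) {
  stop_if_not_scalar_number(dilution_factor, "dilution_factor")
  if (dilution_factor <= 1) {
    stop("'dilution_factor' must be greater than 1", call. = FALSE)
  }
  log2(dilution_factor)
}

#' Serial-transfer regime description
#'
#' @param bottleneck_size Cells transferred at each dilution (N0 > 0).
#' @param dilution_factor Fold dilution per transfer (> 1).
#' @param generations_per_cycle Generations per transfer; defaults to
#'   `log2(dilution_factor)`.
#' @return List of class `transfer_regime`.
#' @export
transfer_regime <- function(bottleneck_size, dilution_factor = 1000,
                            generations_per_cycle = generations_per_transfer(dilution_factor)) {
  stop_if_not_scalar_number(bottleneck_size, "bottleneck_size", positive = TRUE)
  stop_if_not_scalar_number(generations_per_cycle, "generations_per_cycle", positive = TRUE)
  structure(
    list(bottleneck_size = bottleneck_size, dilution_factor = dilution_factor,
         generations_per_cycle = generations_per_cycle),
    class = "transfer_regime"
  )
}

#' Effective population size of a serial-transfer regime
#'
#' Ne = N0 x g, where N0 is the bottleneck (initial) population size and g
#' the number of generations during a single growth cycle.
#'
#' @param regime A [transfer_regime()], or the bottleneck size N0 when `g`
#'   is supplied directly.
#' @param g Generations per cycle (only when `regime` is a bare N0).
#' @return Effective population size in cells.
#' @export
effective_population_size <- function(regime, g = NULL) {
  if (inherits(regime, "transfer_regime")) {
    return(regime$bottleneck_size * regime$generations_per_cycle)
  }
  stop_if_not_scalar_number(regime, "N0", positive = TRUE)
  stop_if_not_scalar_number(g, "g", positive = TRUE)
  regime * g
}

#' Construct a two-color competition trajectory
#'
#' @param generations Non-negative, increasing sampling times in generations.
#' @param green_freq Green-subpopulation frequencies in \[0, 1\] aligned to
#'   `generations`.
#' @param line_id Label for the evolving line.
#' @return Object of class `competition_trajectory`.
#' @export
competition_trajectory <- function(generations, green_freq, line_id = "line") {
  generations <- as.numeric(generations)
  green_freq <- as.numeric(green_freq)
  if (length(generations) == 0L) stop("empty trajectory", call. = FALSE)
  if (length(generations) != length(green_freq)) {
    stop("'generations' and 'green_freq' must have the same length", call. = FALSE)
  }
  if (any(diff(generations) <= 0)) stop("'generations' must be increasing", call. = FALSE)
  if (any(generations < 0)) stop("'generations' must be non-negative", call. = FALSE)
  if (any(green_freq < 0 | green_freq > 1)) {
    stop("'green_freq' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(line_id = as.character(line_id), generations = generations,
                 green_freq = green_freq),
            class = "competition_trajectory")
}

#' Detect fixation of either color in a competition trajectory
#'
#' Fixation is called at the earliest sampled generation where the frequency
#' of either subpopulation exceeds the threshold (strictly), evaluated on
#' sampled points only (no interpolation, matching discrete flow-cytometry
#' time points). In `sustained` mode the call additionally requires every
#' subsequent sample of the same color to remain above the threshold.
#'
#' @param traj A [competition_trajectory()].
#' @param threshold Fixation frequency threshold in (0.5, 1); default 0.95.
#' @param sustained If `TRUE`, require the crossing to persist to the end of
#'   the trajectory.
#' @return `NULL` if neither color fixes; otherwise a list with `generation`
#'   and `color` (`"green"` or `"red"`).
#' @export
detect_fixation <- function(traj, threshold = 0.95, sustained = FALSE) {
  stopifnot(inherits(traj, "competition_trajectory"))
  if (threshold <= 0.5 || threshold >= 1) {
    stop("'threshold' must lie in (0.5, 1)", call. = FALSE)
  }
  f <- traj$green_freq
  hit_green <- f > threshold
  hit_red <- (1 - f) > threshold
  if (sustained) {
    # a crossing counts only if all later samples of that color stay above
    sustain <- function(hits) {
      ok <- rev(cumprod(rev(hits))) == 1
      which(ok)[1]
    }
    ig <- if (any(hit_green)) sustain(hit_green) else NA_integer_
    ir <- if (any(hit_red)) sustain(hit_red) else NA_integer_
  } else {
    ig <- if (any(hit_green)) which(hit_green)[1] else NA_integer_
    ir <- if (any(hit_red)) which(hit_red)[1] else NA_integer_
  }
  if (is.na(ig) && is.na(ir)) return(NULL)
  if (is.na(ir) || (!is.na(ig) && ig <= ir)) {
    list(generation = traj$generations[ig], color = "green")
  } else {
    list(generation = traj$generations[ir], color = "red")
  }
}

#' Summarise fixation across a set of competition trajectories
#'
#' @param trajs List of [competition_trajectory()] objects.
#' @param by_generation Count a line as fixed if its fixation generation is
#'   <= this value.
#' @param threshold,sustained Passed to [detect_fixation()].
#' @return List with `n_fixed`, `n_total`, `fraction` and a per-line data
#'   frame `calls` (`line_id`, `fixed_color`, `fixation_generation`).
#' @export
fixation_summary <- function(trajs, by_generation, threshold = 0.95,
                             sustained = FALSE) {
  if (length(trajs) == 0L) stop("need at least one trajectory", call. = FALSE)
  calls <- lapply(trajs, function(tr) {
    fx <- detect_fixation(tr, threshold = threshold, sustained = sustained)
    data.frame(
      line_id = tr$line_id,
      fixed_color = if (is.null(fx)) NA_character_ else fx$color,
      fixation_generation = if (is.null(fx)) NA_real_ else fx$generation
    )
  })
  calls <- do.call(rbind, calls)
  fixed <- !is.na(calls$fixation_generation) &
    calls$fixation_generation <= by_generation
  list(n_fixed = sum(fixed), n_total = nrow(calls),
       fraction = sum(fixed) / nrow(calls), calls = calls)
}
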