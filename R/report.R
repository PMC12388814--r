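#' Select the cells with the longest cultivation periods
#'
#' In each experiment only a handful of cells stay stably attached through
#' the run, so the presentation rule keeps the `k` tracks with the longest
#' duration (end minus attachment). Ties are broken by larger last observed
#' volume, then by smaller cell id. If fewer than `k` tracks exist, all are
#' returned with a warning.
#'
#' @param tracks A tracks tibble.
#' @param k Number of cells to keep (default 3).
#' @return The tracks tibble restricted to the selected cells.
#' @export
select_presented_cells <- function(tracks, k = 3) {
  stopifnot(is.data.frame(tracks), k >= 1)
  vol_col <- if ("volume_um3_smoothed" %in% names(tracks))
    "volume_um3_smoothed" else if ("volume_um3" %in% names(tracks))
      "volume_um3" else NULL
  per_cell <- tracks |>
    as_tibble() |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_t_min, .by_group = TRUE) |>
    summarise(
      duration = if ("end_t_min" %in% names(tracks))
        first(.data$end_t_min) - first(.data$attachment_t_min)
      else max(.data$frame_t_min) - min(.data$frame_t_min),
      end_volume = if (!is.null(vol_col)) last(.data[[vol_col]]) else 0,
      .groups = "drop")
  if (nrow(per_cell) < k) {
    warn(sprintf("Only %d tracks available; returning all (k = %d).",
                 nrow(per_cell), k))
    return(as_tibble(tracks))
  }
  keep <- per_cell |>
    arrange(desc(.data$duration), desc(.data$end_volume), .data$cell_id) |>
    slice(seq_len(k)) |>
    pull(.data$cell_id)
  filter(as_tibble(tracks), .data$cell_id %in% keep)
}

#' Select cells with a matched initial volume
#'
#' Cross-condition growth-rate comparisons require cells starting from a
#' similar size; this keeps tracks whose first (smoothed, if available)
#' volume lies within `tol` of `target` (default 27 um^3, the matched
#' initial volume used for the shear comparison).
#'
#' @param tracks A tracks tibble.
#' @param target Target initial volume, um^3.
#' @param tol Absolute tolerance, um^3 (`Inf` keeps everything).
#' @return The tracks tibble restricted to matching cells (possibly empty).
#' @export
select_matched_initial_volume <- function(tracks, target = 27, tol = 5) {
  stopifnot(is.data.frame(tracks), tol >= 0)
  vol_col <- if ("volume_um3_smoothed" %in% names(tracks))
    "volume_um3_smoothed" else "volume_um3"
  keep <- tracks |>
    as_tibble() |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_t_min, .by_group = TRUE) |>
    summarise(v0 = first(.data[[vol_col]]), .groups = "drop") |>
    filter(abs(.data$v0 - target) <= tol) |>
    pull(.data$cell_id)
  filter(as_tibble(tracks), .data$cell_id %in% keep)
}

#' Aggregate growth fits and division metrics for one flow condition
#'
#' Computes, per flow-rate condition, the arithmetic mean and sample
#' standard deviation of each growth-model coefficient and of R^2, plus
#' division-volume summaries (max and mean) and the list of growth periods
#' (kept whole for box-plot export). Standard deviations are reported only
#' for n >= 2 (NA otherwise).
#'
#' @param fits A per-cell fits tibble (from [fit_growth()]), >= 1 row.
#' @param divisions A divisions tibble (from [detect_division()]) or `NULL`.
#' @param flow_rate The condition's flow rate, uL min^-1.
#' @return A one-row tibble: `flow_rate`, `n_cells`, `{a,b,c,d,r2}_mean`,
#'   `{a,b,c,d,r2}_sd`, `division_volume_max`, `division_volume_mean`,
#'   `growth_period_median_min`, `n_divisions`, and list-columns
#'   `division_volumes`, `growth_periods_min`.
#' @export
summarize_condition <- function(fits, divisions = NULL, flow_rate = NA_real_) {
  stopifnot(is.data.frame(fits))
  if (nrow(fits) == 0) abort("`fits` must contain at least one cell.")
  n <- nrow(fits)
  stat <- function(x) c(mean = mean(x), sd = if (n >= 2) sd(x) else NA_real_)
  cols <- c("a", "b", "c", "d", "r2")
  stats <- map(cols, function(cl) stat(fits[[cl]]))
  names(stats) <- cols
  div_vol <- if (!is.null(divisions) && nrow(divisions))
    divisions$volume_at_division_um3 else numeric(0)
  periods <- if (!is.null(divisions) && nrow(divisions))
    divisions$growth_period_min else numeric(0)
  out <- tibble(flow_rate = flow_rate, n_cells = n)
  for (cl in cols) {
    out[[paste0(cl, "_mean")]] <- unname(stats[[cl]]["mean"])
    out[[paste0(cl, "_sd")]] <- unname(stats[[cl]]["sd"])
  }
  out$division_volume_max <- if (length(div_vol)) max(div_vol) else NA_real_
  out$division_volume_mean <- if (length(div_vol)) mean(div_vol) else NA_real_
  out$growth_period_median_min <- if (length(periods)) median(periods) else
    NA_real_
  out$n_divisions <- length(div_vol)
  out$division_volumes <- list(div_vol)
  out$growth_periods_min <- list(periods)
  out
}

#' Find the flow rate optimising a growth metric
#'
#' Two optimality notions are supported: the flow rate whose condition shows
#' the largest maximum volume at division (`"max_division_volume"`), and the
#' flow rate with the smallest median growth period
#' (`"min_growth_period"`, the median being robust to the censored and lost
#' tracks typical of flow-chamber runs). Ties return all tied flow rates.
#'
#' @param summaries A tibble of per-condition rows from
#'   [summarize_condition()].
#' @param metric `"max_division_volume"` or `"min_growth_period"`.
#' @return The optimising flow rate(s), uL min^-1.
#' @export
find_optimal_flow <- function(summaries,
                              metric = c("max_division_volume",
                                         "min_growth_period")) {
  metric <- arg_match(metric)
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  val <- if (metric == "max_division_volume")
    summaries$division_volume_max else summaries$growth_period_median_min
  if (all(is.na(val))) {
    abort(sprintf("Metric `%s` unavailable: no division events recorded.",
                  metric))
  }
  opt <- if (metric == "max_division_volume") max(val, na.rm = TRUE) else
    min(val, na.rm = TRUE)
  sort(summaries$flow_rate[!is.na(val) & val == opt])
}

#' Flow-rate to energy-dissipation-rate lookup
#'
#' The turbulence intensity a cell experiences is characterised by the
#' energy-dissipation rate epsilon (m^2 s^-3), obtained for this chamber
#' geometry from a CFD study. Only a lookup is provided here: exact values at
#' anchor flows, linear interpolation in between, and an error outside the
#' anchor span (the CFD relation is unknown there). The default map anchors
#' the interior point 270 uL min^-1 at 5.62e-5 m^2 s^-3 and assigns the
#' study-range endpoints (6.2e-6 and 7.5e-5 m^2 s^-3) to the lowest and
#' highest flows of the experimental grid (30 and 420 uL min^-1) — that
#' endpoint assignment is an explicit assumption, overridable with a
#' user-supplied anchor table.
#'
#' @param anchors A data frame with columns `flow` (uL min^-1) and `epsilon`
#'   (m^2 s^-3), >= 2 rows, strictly increasing flows.
#' @return `epsilon_map()`: an object of class `epsilon_map`.
#' @export
epsilon_map <- function(anchors = tibble(flow = c(30, 270, 420),
                                         epsilon = c(6.2e-6, 5.62e-5,
                                                     7.5e-5))) {
  stopifnot(is.data.frame(anchors),
            all(c("flow", "epsilon") %in% names(anchors)),
            nrow(anchors) >= 2)
  anchors <- arrange(as_tibble(anchors), .data$flow)
  if (any(diff(anchors$flow) <= 0)) abort("Anchor flows must be distinct.")
  if (any(anchors$epsilon <= 0)) abort("Epsilon values must be > 0.")
  structure(list(anchors = anchors, mode = "linear"), class = "epsilon_map")
}

#' @rdname epsilon_map
#' @param flow Flow rate(s), uL min^-1; must lie within the anchor span.
#' @param map An `epsilon_map`.
#' @return `flow_to_epsilon()`: epsilon values, m^2 s^-3.
#' @examples
#' flow_to_epsilon(270)  # 5.62e-5
#' @export
flow_to_epsilon <- function(flow, map = epsilon_map()) {
  stopifnot(inherits(map, "epsilon_map"), is.numeric(flow))
  a <- map$anchors
  if (any(flow < min(a$flow) | flow > max(a$flow))) {
    abort(sprintf("Flow outside the anchor span [%g, %g]: the relation is unknown there.",
                  min(a$flow), max(a$flow)))
  }
  approx(a$flow, a$epsilon, xout = flow, method = "linear")$y
}
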