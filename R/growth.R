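#' Exponential smoothing of a volume series
#'
#' Single (first-order) exponential smoothing,
#' `S_t = alpha * Y_t + (1 - alpha) * S_(t-1)`, initialised with
#' `S_1 = Y_1`. It damps the frame-to-frame fluctuation that image noise
#' induces in apparent cell volume. A constant series is a fixed point; as
#' `alpha -> 1` the smoothed series tends to the raw series. `alpha` must lie
#' strictly in (0, 1); the package default is 0.1, suited to series whose
#' fluctuation is mild relative to the growth signal.
#'
#' @param y Numeric series (non-empty, finite).
#' @param alpha Smoothing weight in (0, 1).
#' @return The smoothed series, same length as `y`.
#' @examples
#' exp_smooth(c(10, 20, 30), alpha = 0.5)  # 10, 15, 22.5
#' @export
exp_smooth <- function(y, alpha = 0.1) {
  stopifnot(is.numeric(y))
  if (length(y) == 0) abort("`y` must be non-empty.")
  if (!all(is.finite(y))) abort("`y` must be finite.")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly in (0, 1).")
  }
  as.numeric(stats::filter(alpha * y, 1 - alpha, method = "recursive",
                           init = y[1]))
}

#' Add a smoothed-volume column to tracks
#'
#' Applies [exp_smooth()] per cell (ordered by time) to the raw volume
#' column.
#'
#' @param tracks A tracks tibble with `cell_id`, `frame_t_min`,
#'   `volume_um3`.
#' @inheritParams exp_smooth
#' @return The tracks tibble with an added `volume_um3_smoothed` column.
#' @export
smooth_volumes <- function(tracks, alpha = 0.1) {
  stopifnot(is.data.frame(tracks), "volume_um3" %in% names(tracks))
  tracks |>
    as_tibble() |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_t_min, .by_group = TRUE) |>
    mutate(volume_um3_smoothed = exp_smooth(.data$volume_um3, alpha)) |>
    ungroup()
}

#' Fit the cubic growth model to a volume series
#'
#' Ordinary least squares of `V(t) = a t^3 + b t^2 + c t + d` (t in minutes,
#' V in um^3). Coefficient `d` is the modelled initial volume; `c t` captures
#' linear (environmental) forcing and the higher-order terms internal
#' (enzymatic) kinetics. Internally the time axis is rescaled before solving
#' so that exact cubic inputs are recovered to near machine precision even on
#' long (multi-thousand-minute) grids. `R^2 = 1 - SS_res / SS_tot` with
#' `SS_tot` about the mean; for a zero-variance target `R^2` is reported as 1
#' by convention and flagged (`zero_variance = TRUE`).
#'
#' @param times Times in minutes (>= 4 distinct values).
#' @param volumes Volumes in um^3, same length.
#' @return An object of class `growth_fit` with elements `coefficients`
#'   (named `a`, `b`, `c`, `d`), `std_errors`, `r_squared`, `n`,
#'   `zero_variance`, and the fitted data.
#' @export
fit_cubic <- function(times, volumes) {
  stopifnot(is.numeric(times), is.numeric(volumes),
            length(times) == length(volumes))
  if (length(times) < 4) abort("At least 4 points are required.")
  if (anyDuplicated(times)) abort("Times must be distinct (rank-deficient design).")
  if (!all(is.finite(times)) || !all(is.finite(volumes))) {
    abort("Times and volumes must be finite.")
  }
  Tsc <- max(abs(times), 1)
  s <- times / Tsc
  fit <- lm(volumes ~ s + I(s^2) + I(s^3))
  beta <- coef(fit)
  scale_pow <- Tsc^(0:3)
  cf <- c(a = unname(beta[4]) / scale_pow[4],
          b = unname(beta[3]) / scale_pow[3],
          c = unname(beta[2]) / scale_pow[2],
          d = unname(beta[1]))
  se_raw <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  se <- c(a = unname(se_raw[4]) / scale_pow[4],
          b = unname(se_raw[3]) / scale_pow[3],
          c = unname(se_raw[2]) / scale_pow[2],
          d = unname(se_raw[1]))
  ss_tot <- sum((volumes - mean(volumes))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  zero_var <- ss_tot <= .Machine$double.eps * max(1, sum(volumes^2))
  r2 <- if (zero_var) 1 else 1 - ss_res / ss_tot
  structure(
    list(coefficients = cf, std_errors = se, r_squared = r2,
         n = length(times), zero_variance = zero_var,
         data = tibble(t_min = times, volume_um3 = volumes,
                       fitted = unname(stats::fitted(fit)))),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<growth_fit> V(t) = %.3g t^3 + %.3g t^2 + %.3g t + %.4g   (R^2 = %.4f, n = %d)\n",
    cf["a"], cf["b"], cf["c"], cf["d"], x$r_squared, x$n))
  if (x$zero_variance) cat("  note: zero-variance target, R^2 = 1 by convention\n")
  invisible(x)
}

#' @rdname fit_cubic
#' @param x,object A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$std_errors))
}

#' @rdname fit_cubic
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n, zero_variance = x$zero_variance)
}

#' @rdname fit_cubic
#' @param newtimes Times (minutes) at which to evaluate the fitted cubic;
#'   defaults to the fitted times.
#' @export
predict.growth_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) newtimes <- object$data$t_min
  cf <- object$coefficients
  cf[["a"]] * newtimes^3 + cf[["b"]] * newtimes^2 + cf[["c"]] * newtimes +
    cf[["d"]]
}

#' @rdname fit_cubic
#' @export
augment.growth_fit <- function(x, ...) {
  mutate(x$data, .resid = .data$volume_um3 - .data$fitted)
}

#' Fit the growth model to every tracked cell
#'
#' Per cell, re-origins time at the cell's attachment (first detection) and
#' fits [fit_cubic()] to the smoothed volume series (the analysis default) or
#' the raw series. Cells with fewer than 4 points are skipped with a warning.
#'
#' @param tracks A tracks tibble (with `volume_um3_smoothed` when
#'   `use_smoothed = TRUE`; computed with the default alpha if absent).
#' @param use_smoothed Fit the smoothed (`TRUE`, default) or raw series.
#' @param alpha Smoothing weight used if smoothing must be (re)computed.
#' @return A tibble with one row per cell: `cell_id`, `a`, `b`, `c`, `d`,
#'   `r2`, `n`, and a list-column `fit` of `growth_fit` objects.
#' @export
fit_growth <- function(tracks, use_smoothed = TRUE, alpha = 0.1) {
  stopifnot(is.data.frame(tracks))
  if (use_smoothed && !"volume_um3_smoothed" %in% names(tracks)) {
    tracks <- smooth_volumes(tracks, alpha)
  }
  col <- if (use_smoothed) "volume_um3_smoothed" else "volume_um3"
  res <- tracks |>
    as_tibble() |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_t_min, .by_group = TRUE) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 4) return(NULL)
      t0 <- if ("attachment_t_min" %in% names(d)) d$attachment_t_min[1] else
        min(d$frame_t_min)
      f <- fit_cubic(d$frame_t_min - t0, d[[col]])
      tibble(cell_id = key$cell_id,
             a = f$coefficients[["a"]], b = f$coefficients[["b"]],
             c = f$coefficients[["c"]], d = f$coefficients[["d"]],
             r2 = f$r_squared, n = f$n, fit = list(f))
    }) |> compact()
  if (!length(res)) {
    warn("No cell had the >= 4 points needed for fitting.")
    return(tibble(cell_id = integer(), a = numeric(), b = numeric(),
                  c = numeric(), d = numeric(), r2 = numeric(),
                  n = integer(), fit = list()))
  }
  bind_rows(res)
}

#' Instantaneous growth rate of a fitted curve
#'
#' The model derivative `dV/dt = 3 a t^2 + 2 b t + c`, in um^3 per minute.
#'
#' @param fit A `growth_fit`, or a numeric vector `(a, b, c, d)`.
#' @param t Times in minutes.
#' @return Growth rates, um^3 min^-1.
#' @export
growth_rate <- function(fit, t) {
  cf <- if (inherits(fit, "growth_fit")) fit$coefficients else {
    stopifnot(is.numeric(fit), length(fit) == 4)
    setNames(as.numeric(fit), c("a", "b", "c", "d"))
  }
  3 * cf[["a"]] * t^2 + 2 * cf[["b"]] * t + cf[["c"]]
}

#' Detect division events and extract division metrics
#'
#' A division is declared at the time the tracker reported a split event
#' (`end_event == "division"`). For tracks without tracker events (e.g.
#' single-object series), a fallback detector declares division at the first
#' time the volume drops by at least `drop_fraction` (default 0.30) relative
#' to its running maximum. The volume at division is the volume immediately
#' before the division time, taken from the smoothed series by default (the
#' growth curves the analysis presents are smoothed) or the raw series. The
#' growth period is the time from attachment to division, also reported in
#' days (minutes / 1440).
#'
#' @param tracks A tracks tibble.
#' @param drop_fraction Relative drop triggering the fallback detector.
#' @param volume_source `"smoothed"` (default) or `"raw"`.
#' @param alpha Smoothing weight used if smoothing must be computed.
#' @return A tibble with one row per dividing cell: `cell_id`,
#'   `division_t_min`, `volume_at_division_um3`, `growth_period_min`,
#'   `growth_period_d`. Cells without a division are omitted.
#' @export
detect_division <- function(tracks, drop_fraction = 0.30,
                            volume_source = c("smoothed", "raw"),
                            alpha = 0.1) {
  volume_source <- arg_match(volume_source)
  stopifnot(is.data.frame(tracks))
  if (volume_source == "smoothed" &&
      !"volume_um3_smoothed" %in% names(tracks)) {
    tracks <- smooth_volumes(tracks, alpha)
  }
  col <- if (volume_source == "smoothed") "volume_um3_smoothed" else
    "volume_um3"
  tracks |>
    as_tibble() |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_t_min, .by_group = TRUE) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 2) return(NULL)
      att <- if ("attachment_t_min" %in% names(d)) d$attachment_t_min[1] else
        min(d$frame_t_min)
      v <- d[[col]]
      if ("end_event" %in% names(d) && d$end_event[1] == "division") {
        t_div <- d$end_t_min[1]
        v_div <- v[length(v)]   # last observation precedes the split frame
      } else {
        run_max <- cummax(v)
        drop_idx <- which(v <= (1 - drop_fraction) * run_max)
        if (!length(drop_idx)) return(NULL)
        i <- drop_idx[1]
        t_div <- d$frame_t_min[i]
        v_div <- run_max[i - 1]
      }
      period <- t_div - att
      tibble(cell_id = key$cell_id, division_t_min = t_div,
             volume_at_division_um3 = v_div,
             growth_period_min = period,
             growth_period_d = period / 1440)
    }) |> compact() |> bind_rows() |>
    (\(x) if (nrow(x)) x else
      tibble(cell_id = integer(), division_t_min = numeric(),
             volume_at_division_um3 = numeric(),
             growth_period_min = numeric(), growth_period_d = numeric()))()
}

#' Lag-phase end time of a growth curve
#'
#' The lag (adaptation) phase is the initial near-horizontal stretch of a
#' growth curve; it is operationalised as ending at the first time the
#' smoothed volume strictly exceeds `(1 + rise_fraction)` times its initial
#' value (default rise 10%). Returns `NA` for cells that never rise.
#'
#' @param tracks A tracks tibble.
#' @param rise_fraction Fractional rise ending the lag phase.
#' @param volume_source `"smoothed"` (default) or `"raw"`.
#' @param alpha Smoothing weight used if smoothing must be computed.
#' @return A tibble: `cell_id`, `lag_end_t_min` (NA if no rise).
#' @export
lag_phase <- function(tracks, rise_fraction = 0.10,
                      volume_source = c("smoothed", "raw"), alpha = 0.1) {
  volume_source <- arg_match(volume_source)
  stopifnot(rise_fraction >= 0)
  if (volume_source == "smoothed" &&
      !"volume_um3_smoothed" %in% names(tracks)) {
    tracks <- smooth_volumes(tracks, alpha)
  }
  col <- if (volume_source == "smoothed") "volume_um3_smoothed" else
    "volume_um3"
  tracks |>
    as_tibble() |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_t_min, .by_group = TRUE) |>
    summarise(lag_end_t_min = {
      v <- .data[[col]]
      i <- which(v > (1 + rise_fraction) * v[1])
      if (length(i)) .data$frame_t_min[i[1]] else NA_real_
    }, .groups = "drop")
}
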