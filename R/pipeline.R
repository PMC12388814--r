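#' Study flow-rate grid
#'
#' The experimental grid: a static control (0) plus twelve pumped flow rates
#' from 30 to 420 uL min^-1.
#'
#' @return Numeric vector of flow rates, uL min^-1.
#' @export
study_flow_rates <- function() {
  c(0, 30, 60, 90, 120, 150, 180, 210, 240, 270, 300, 360, 420)
}

# Dose-response bump encoding the shear optimum at 270 uL min^-1.
shear_bump <- function(flow_rate, peak = 270, width = 70) {
  exp(-((flow_rate - peak) / width)^2)
}

#' Build a synthetic scene for one shear condition
#'
#' Encodes a shear dose-response with its optimum at 270 uL min^-1: the bump
#' `u = exp(-((flow - 270) / 70)^2)` scales both the linear growth
#' coefficient, `c = c0 * (0.3 + 2.7 u)` um^3 min^-1, and the division-size
#' multiple, `k = 2 + u`, so cells at the optimal shear grow fastest and
#' divide largest. Each cell starts at its initial volume `d` and divides
#' when `V` reaches `k * d`, i.e. at `t = d (k - 1) / c`; hence within a
#' condition a larger initial volume gives a larger volume at division, and
#' across conditions both the maximum division volume and the (inverse)
#' growth period peak at 270 uL min^-1.
#'
#' @param flow_rate Flow rate, uL min^-1.
#' @param seed Scene RNG seed.
#' @param d_values Initial volumes of the cells, um^3.
#' @param c0 Baseline linear growth coefficient, um^3 min^-1.
#' @param area_noise_sd Relative apparent-area noise per cell.
#' @param image_shape,background_sd,foreground_sd Passed to [scene_spec()].
#' @return A [scene_spec()] whose cells carry the condition's growth law and
#'   division times.
#' @export
shear_scene <- function(flow_rate, seed = 1L, d_values = c(20, 30, 45),
                        c0 = 0.06, area_noise_sd = 0.01,
                        image_shape = c(160L, 160L),
                        background_sd = 5, foreground_sd = 5) {
  u <- shear_bump(flow_rate)
  c_lin <- c0 * (0.3 + 2.7 * u)
  k_div <- 2 + u
  layout <- list(c(45.3, 45.2), c(45.7, 115.4), c(115.2, 80.6))
  orient <- c(0, pi / 3, -pi / 4)
  stopifnot(length(d_values) <= length(layout))
  cells <- imap(d_values, function(d0, i) {
    cell_spec(centroid = layout[[i]],
              growth_coeffs = c(0, 0, c_lin, d0),
              orientation = orient[i],
              division_time = d0 * (k_div - 1) / c_lin,
              area_noise_sd = area_noise_sd)
  })
  scene_spec(image_shape = image_shape, cells = cells,
             background_sd = background_sd, foreground_sd = foreground_sd,
             rng_seed = seed)
}

#' Run the full analysis for one imaged condition
#'
#' Chains the pipeline on an existing time-lapse: segment each frame with the
#' classifier, convert detections to physical measurements, link tracks,
#' smooth, fit the growth model, detect divisions, and summarise.
#'
#' @param timelapse A [generate_timelapse()] object (or real frames packed
#'   the same way).
#' @param classifier A trained [train_pixel_classifier()].
#' @param flow_rate Condition label, uL min^-1.
#' @param cal A [calibration()]; defaults to the time-lapse's pixel ratio.
#' @param alpha Smoothing weight.
#' @param min_area,threshold Segmentation parameters.
#' @param max_displacement Tracking gate, pixels.
#' @param volume_model 2D-to-3D volume rule.
#' @param k_presented Number of longest-cultivated cells retained per
#'   condition before summarising.
#' @return A list with `tracks`, `fits`, `divisions` and the one-row
#'   `summary` tibble.
#' @export
analyze_condition <- function(timelapse, classifier, flow_rate = NA_real_,
                              cal = NULL, alpha = 0.1, min_area = 5,
                              threshold = 0.5, max_displacement = 15,
                              volume_model = c("spheroid",
                                               "equivalent_sphere"),
                              k_presented = 3) {
  volume_model <- arg_match(volume_model)
  if (is.null(cal)) {
    cal <- if (inherits(timelapse, "timelapse"))
      calibration(timelapse$scene$pixel_ratio) else calibration()
  }
  detections <- segment_timelapse(timelapse, classifier,
                                  threshold = threshold, min_area = min_area)
  tracks <- detections |>
    measure_cells(cal = cal, model = volume_model) |>
    track_cells(max_displacement = max_displacement) |>
    smooth_volumes(alpha = alpha) |>
    select_presented_cells(k = k_presented)
  fits <- fit_growth(tracks)
  divisions <- detect_division(tracks)
  list(tracks = tracks, fits = fits, divisions = divisions,
       summary = summarize_condition(fits, divisions, flow_rate))
}

#' Simulate and analyse a full shear cohort
#'
#' Generates one synthetic time-lapse per flow condition with
#' [shear_scene()], trains a single pixel classifier on labelled pixels
#' sampled from the first condition's opening frames, runs
#' [analyze_condition()] on every condition, and stacks the per-condition
#' summaries. The cohort uses a 20-minute frame cadence over 0-2600 min —
#' coarser than the 5-minute camera interval, chosen so a 13-condition
#' cohort stays a desk-scale computation while every division still falls
#' well inside the observation window.
#'
#' @param flow_rates Flow conditions to simulate (default the study grid).
#' @param seed Master seed; all per-condition scenes and the classifier
#'   derive their seeds from it.
#' @param t_end,interval Simulation window and frame cadence, minutes.
#' @param n_train_pixels Labelled pixels per class for classifier training.
#' @param ... Passed on to [shear_scene()].
#' @return A list with `summaries` (one row per condition), `divisions`
#'   (long, with `flow_rate`), `fits` (long, with `flow_rate`) and the
#'   trained `classifier`.
#' @export
run_shear_cohort <- function(flow_rates = study_flow_rates(), seed = 1L,
                             t_end = 2600, interval = 20,
                             n_train_pixels = 600, ...) {
  seed <- as.integer(seed)
  # train one classifier on the first condition's opening frames
  scene0 <- shear_scene(flow_rates[1], seed = seed, ...)
  tl0 <- generate_timelapse(scene0, 0, 2 * interval, interval)
  samples <- sample_training_pixels(tl0$frames, tl0$masks,
                                    n_per_class = n_train_pixels,
                                    rng_seed = seed) |>
    split_samples(rng_seed = seed)
  classifier <- train_pixel_classifier(samples, rng_seed = seed)
  res <- imap(flow_rates, function(f, i) {
    scene <- shear_scene(f, seed = frame_seed(seed, 1000 * i), ...)
    tl <- generate_timelapse(scene, 0, t_end, interval)
    out <- analyze_condition(tl, classifier, flow_rate = f)
    out$divisions$flow_rate <- if (nrow(out$divisions)) f else numeric(0)
    out$fits$flow_rate <- if (nrow(out$fits)) f else numeric(0)
    out[c("summary", "divisions", "fits")]
  })
  list(summaries = bind_rows(map(res, "summary")),
       divisions = bind_rows(map(res, "divisions")),
       fits = bind_rows(map(res, "fits")) |> select(-dplyr::any_of("fit")),
       classifier = classifier)
}
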