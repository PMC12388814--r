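# Shared fixtures, all generated in code at test time.

# A small scene with one growing cell; noise configurable.
one_cell_scene <- function(seed = 11, bg_sd = 0, fg_sd = 0,
                           coeffs = c(0, 0, 0.05, 27),
                           division_time = NULL, loss_time = NULL,
                           area_noise_sd = 0, shape = c(120L, 120L)) {
  scene_spec(
    image_shape = shape,
    cells = list(cell_spec(centroid = c(60.35, 60.15), growth_coeffs = coeffs,
                           orientation = pi / 6,
                           division_time = division_time,
                           loss_time = loss_time,
                           area_noise_sd = area_noise_sd)),
    background_sd = bg_sd, foreground_sd = fg_sd, rng_seed = seed
  )
}

# Randomised multi-cell scene (1-3 cells), deterministic in `seed`.
random_scene <- function(seed, bg_sd = 0, fg_sd = 0) {
  set.seed(seed)
  anchors <- list(c(35, 35), c(35, 85), c(85, 60))
  n <- sample(1:3, 1)
  cells <- lapply(seq_len(n), function(i) {
    cell_spec(centroid = anchors[[i]] + runif(2, -6, 6),
              growth_coeffs = c(0, 0, 0, runif(1, 15, 60)),
              orientation = runif(1, -pi / 2, pi / 2))
  })
  scene_spec(image_shape = c(120L, 120L), cells = cells,
             background_sd = bg_sd, foreground_sd = fg_sd, rng_seed = seed)
}

# One classifier shared across tests, trained on a noisy rendered scene.
shared_classifier <- local({
  clf <- NULL
  function() {
    if (is.null(clf)) {
      sc <- random_scene(101, bg_sd = 8, fg_sd = 8)
      fr <- render_frame(sc, 0)
      samples <- sample_training_pixels(fr$frame, fr$mask, 150,
                                        rng_seed = 5) |>
        split_samples(rng_seed = 5)
      clf <<- train_pixel_classifier(samples, rng_seed = 5)
    }
    clf
  }
})

# Detections table for a stationary object, on a uniform grid.
stationary_detections <- function(n_frames = 10, interval = 5,
                                  row = 20, col = 30, area = 100) {
  tibble::tibble(
    frame_t_min = seq(0, by = interval, length.out = n_frames),
    det_id = 1L, centroid_row = row, centroid_col = col,
    area_px2 = area, major_px = 12, minor_px = 10, orientation_rad = 0
  )
}
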