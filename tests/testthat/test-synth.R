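test_that("an empty scene renders pure background with an empty mask", {
  sc <- scene_spec(image_shape = c(32L, 32L), cells = list(),
                   background_sd = 3, foreground_sd = 3, rng_seed = 4)
  fr <- render_frame(sc, 0)
  expect_identical(dim(fr$frame), c(32L, 32L, 3L))
  expect_true(all(fr$mask == 0L))
  expect_equal(nrow(fr$truth), 0L)
  expect_true(all(abs(fr$frame[, , 1] - 40) < 5 * 4))
})

test_that("a noise-free render matches the analytic ellipse area within 2%", {
  sc <- one_cell_scene(coeffs = c(0, 0, 0, 40))
  fr <- render_frame(sc, 0)
  ax <- axes_from_volume(40, aspect = sc$aspect, cal = calibration(0.30))
  analytic <- pi * ax$a_px * ax$b_px
  expect_lt(abs(sum(fr$mask > 0) - analytic) / analytic, 0.02)
})

test_that("a constant growth polynomial keeps the true volume fixed", {
  sc <- one_cell_scene(coeffs = c(0, 0, 0, 27))
  for (t in c(0, 5, 500, 8175)) {
    expect_equal(render_frame(sc, t)$truth$true_volume_um3, 27)
  }
})

test_that("rendering is bit-identical for identical scene and time", {
  sc <- one_cell_scene(seed = 9, bg_sd = 6, fg_sd = 6, area_noise_sd = 0.05)
  a <- render_frame(sc, 35)
  b <- render_frame(sc, 35)
  expect_identical(a$frame, b$frame)
  expect_identical(a$mask, b$mask)
})

test_that("a cell whose ellipse exceeds the frame is an identified error", {
  sc <- scene_spec(image_shape = c(40L, 40L),
                   cells = list(cell_spec(c(3, 3), c(0, 0, 0, 50))),
                   background_sd = 0, foreground_sd = 0)
  expect_error(render_frame(sc, 0), "Cell 1")
})

test_that("non-positive volumes on the grid are an error", {
  sc <- one_cell_scene(coeffs = c(0, 0, -1, 20))
  expect_error(render_frame(sc, 30), "non-positive volume")
})

test_that("the 5-min cadence over the longest growth period gives 1636 frames", {
  sc <- scene_spec(image_shape = c(8L, 8L), cells = list(),
                   background_sd = 1, foreground_sd = 1)
  tl <- generate_timelapse(sc, 0, 8175, 5)
  expect_length(tl$times, 1636L)
})

test_that("a non-dividing interval truncates to the largest multiple, warning", {
  sc <- scene_spec(image_shape = c(8L, 8L), cells = list(),
                   background_sd = 1, foreground_sd = 1)
  expect_warning(tl <- generate_timelapse(sc, 0, 23, 5), "largest multiple")
  expect_equal(max(tl$times), 20)
})

test_that("a lost cell is present up to, and absent from, its loss time", {
  sc <- one_cell_scene(loss_time = 100)
  tl <- generate_timelapse(sc, 0, 150, 5)
  present <- tapply(tl$truth$t_min, tl$truth$t_min, length)
  expect_true(all(tl$truth$t_min <= 95))
  expect_equal(tl$events$event, "lost")
  expect_equal(tl$events$t_min, 100)
})

test_that("initial volumes are reproduced exactly in the ground truth", {
  sc <- scene_spec(
    image_shape = c(120L, 120L),
    cells = list(cell_spec(c(35, 35), c(0, 0, 0, 19.99)),
                 cell_spec(c(85, 85), c(0, 0, 0, 47.28))),
    background_sd = 0, foreground_sd = 0
  )
  fr <- render_frame(sc, 0)
  expect_equal(sort(fr$truth$true_volume_um3), c(19.99, 47.28))
})

test_that("division replaces the parent by two smaller daughters and is logged", {
  sc <- one_cell_scene(coeffs = c(0, 0, 0.1, 30), division_time = 60)
  tl <- generate_timelapse(sc, 0, 100, 10)
  expect_equal(tl$events$event[1], "division")
  expect_equal(tl$events$t_min[1], 60)
  v_parent <- 30 + 0.1 * 60
  after <- tl$truth[tl$truth$t_min == 60, ]
  expect_equal(nrow(after), 2L)        # parent gone, two daughters
  expect_true(all(after$cell_id != 1L))
  expect_lte(sum(after$true_volume_um3), v_parent)
  before <- tl$truth[tl$truth$t_min == 50, ]
  expect_equal(before$cell_id, 1L)
})

test_that("measuring a noise-free render returns the generating volume (<3%)", {
  sc <- one_cell_scene(coeffs = c(0, 0, 0.02, 27))
  cal <- calibration(sc$pixel_ratio)
  for (t in seq(0, 1000, by = 200)) {
    fr <- render_frame(sc, t)
    det <- extract_cells(matrix(as.integer(fr$mask > 0), nrow(fr$mask)),
                         frame_time = t)
    v <- estimate_volume(det$major_px, det$minor_px, det$area_px2, cal)
    expect_lt(abs(v - fr$truth$true_volume_um3) / fr$truth$true_volume_um3,
              0.03)
  }
})

test_that("training-pixel sampling is balanced, deterministic, and guarded", {
  sc <- one_cell_scene(bg_sd = 5, fg_sd = 5)
  fr <- render_frame(sc, 0)
  s1 <- sample_training_pixels(fr$frame, fr$mask, 120, rng_seed = 3)
  expect_equal(nrow(s1), 240L)
  expect_equal(unname(table(s1$label)), c(120L, 120L), ignore_attr = TRUE)
  s2 <- sample_training_pixels(fr$frame, fr$mask, 120, rng_seed = 3)
  expect_identical(s1, s2)
  expect_error(sample_training_pixels(fr$frame, fr$mask, 0), "> 0")
  expect_error(sample_training_pixels(fr$frame, fr$mask, 1e7), "available")
})

test_that("scene invariants are enforced at construction", {
  expect_error(cell_spec(c(10, 10), c(0, 0, 0, -1)), "must be > 0")
  expect_error(cell_spec(c(10, 10), c(0, 0, 0, 5), division_time = 10,
                         loss_time = 20), "mutually exclusive")
  expect_error(scene_spec(cells = list(cell_spec(c(500, 5), c(0, 0, 0, 5)))),
               "outside")
  expect_error(
    scene_spec(cells = list(cell_spec(c(50, 50), c(0, 0, 0, 40)),
                            cell_spec(c(52, 52), c(0, 0, 0, 40)))),
    "overlap")
  expect_error(scene_spec(background_mean = 100, foreground_mean = 110,
                          background_sd = 5, foreground_sd = 5),
               "4 sd")
})
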