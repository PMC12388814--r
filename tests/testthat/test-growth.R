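test_that("exponential smoothing reproduces hand-computed recursions", {
  expect_equal(exp_smooth(c(27, 27, 27), 0.1), c(27, 27, 27))
  expect_equal(exp_smooth(c(0, 10), 0.1), c(0, 1.0))
  expect_equal(exp_smooth(c(10, 20, 30), 0.5), c(10, 15, 22.5))
})

test_that("smoothing validates its inputs", {
  expect_error(exp_smooth(numeric(0)), "non-empty")
  expect_error(exp_smooth(c(1, NA)), "finite")
  expect_error(exp_smooth(1:3, alpha = 0), "strictly")
  expect_error(exp_smooth(1:3, alpha = 1), "strictly")
})

test_that("smoothing stays within the series bounds; alpha -> 1 recovers it", {
  set.seed(42)
  for (i in 1:50) {
    y <- rnorm(30, 50, 20)
    s <- exp_smooth(y, runif(1, 0.01, 0.99))
    expect_gte(min(s), min(y) - 1e-12)
    expect_lte(max(s), max(y) + 1e-12)
  }
  y <- rnorm(100, 30, 5)
  expect_equal(exp_smooth(y, 1 - 1e-9), y, tolerance = 1e-6)
})

test_that("exact cubic series are recovered to 1e-6 relative error", {
  set.seed(7)
  t <- seq(0, 4000, by = 5)
  for (i in 1:20) {
    cf <- c(a = runif(1, -2e-10, 5e-10), b = runif(1, -1e-3, 4e-3),
            c = runif(1, 0, 0.02), d = runif(1, 15, 60))
    v <- cf["a"] * t^3 + cf["b"] * t^2 + cf["c"] * t + cf["d"]
    if (min(v) <= 0) next
    f <- fit_cubic(t, v)
    expect_lt(max(abs(f$coefficients - cf) / pmax(abs(cf), 1e-12)), 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("a constant series fits as V = d with R^2 = 1 by flagged convention", {
  f <- fit_cubic(seq(0, 30, 5), rep(27, 7))
  expect_equal(unname(f$coefficients["d"]), 27, tolerance = 1e-9)
  expect_lt(max(abs(f$coefficients[c("a", "b", "c")])), 1e-9)
  expect_equal(f$r_squared, 1)
  expect_true(f$zero_variance)
})

test_that("fit_cubic rejects deficient designs", {
  expect_error(fit_cubic(1:3, 1:3), "4 points")
  expect_error(fit_cubic(c(0, 5, 5, 10), c(1, 2, 3, 4)), "distinct")
})

test_that("growth_fit methods are broom-shaped", {
  t <- seq(0, 100, 10)
  f <- fit_cubic(t, 2e-6 * t^3 + 1e-4 * t^2 + 0.05 * t + 27)
  td <- tidy(f)
  expect_equal(td$term, c("a", "b", "c", "d"))
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  g <- glance(f)
  expect_equal(g$n, length(t))
  expect_equal(predict(f, 0), unname(f$coefficients["d"]), tolerance = 1e-6)
  expect_equal(nrow(augment(f)), length(t))
})

test_that("growth_rate is the model derivative", {
  expect_equal(growth_rate(c(0, 0, 0.3, 10), c(0, 50)), c(0.3, 0.3))
  expect_equal(growth_rate(c(0, 0, 0, 10), 123), 0)
  expect_equal(growth_rate(c(1, 1, 1, 0), 2), 17)
})

test_that("the fallback division detector keys on the running-maximum drop", {
  mono <- tibble::tibble(cell_id = 1L, frame_t_min = seq(0, 45, 5),
                         volume_um3 = seq(20, 65, 5))
  expect_equal(nrow(detect_division(mono, volume_source = "raw")), 0L)
  drop <- tibble::tibble(cell_id = 1L, frame_t_min = seq(0, 20, 5),
                         volume_um3 = c(60, 80, 100, 45, 46))
  div <- detect_division(drop, volume_source = "raw")
  expect_equal(div$division_t_min, 15)
  expect_equal(div$volume_at_division_um3, 100)
  expect_equal(div$growth_period_min, 15)
})

test_that("growth periods convert to days as minutes / 1440", {
  tr <- tibble::tibble(cell_id = 1L, frame_t_min = c(0, 720, 1440),
                       volume_um3 = c(50, 100, 20))
  div <- detect_division(tr, volume_source = "raw")
  expect_equal(div$growth_period_d, 1)
})

test_that("cubic coefficient d is recovered under 5% noise (median < 10%)", {
  t <- seq(0, 8000, by = 40)
  cf <- c(2e-11, -2e-8, 0.012, 25)    # realistic 25 -> ~130 um^3 trajectory
  v0 <- cf[1] * t^3 + cf[2] * t^2 + cf[3] * t + cf[4]
  set.seed(99)
  errs <- replicate(25, {
    v <- v0 * (1 + rnorm(length(t), 0, 0.05))
    f <- fit_cubic(t, exp_smooth(v, 0.1))
    abs(f$coefficients[["d"]] - 25) / 25
  })
  expect_lt(median(errs), 0.10)
})

test_that("lag phase ends at the first fractional rise of the curve", {
  tr <- tibble::tibble(cell_id = 1L, frame_t_min = seq(0, 15, 5),
                       volume_um3 = c(27, 27, 30, 33))
  expect_equal(lag_phase(tr, 0.10, volume_source = "raw")$lag_end_t_min, 10)
  expect_equal(lag_phase(tr, 0, volume_source = "raw")$lag_end_t_min, 10)
  const <- tibble::tibble(cell_id = 1L, frame_t_min = seq(0, 15, 5),
                          volume_um3 = rep(27, 4))
  expect_true(is.na(lag_phase(const, volume_source = "raw")$lag_end_t_min))
})

test_that("fitting on smoothed vs raw series is an explicit choice", {
  t <- seq(0, 2000, 20)
  v <- 25 + 0.05 * t
  tr <- tibble::tibble(cell_id = 1L, frame_t_min = t, volume_um3 = v)
  f_raw <- fit_growth(tr, use_smoothed = FALSE)
  f_sm <- fit_growth(tr, use_smoothed = TRUE, alpha = 0.1)
  expect_equal(f_raw$d, 25, tolerance = 1e-8, ignore_attr = TRUE)
  # smoothing lags a rising series, so the smoothed fit differs
  expect_false(isTRUE(all.equal(f_raw$c, f_sm$c, tolerance = 1e-4)))
})
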