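make_track <- function(id, t, v, att = min(t), end = max(t),
                       event = "censored") {
  tibble::tibble(cell_id = id, frame_t_min = t, volume_um3 = v,
                 attachment_t_min = att, end_t_min = end, end_event = event)
}

test_that("the k longest-cultivated tracks are selected, with tie-breaks", {
  durations <- c(10, 50, 30, 50, 5)
  tracks <- dplyr::bind_rows(lapply(seq_along(durations), function(i) {
    make_track(i, seq(0, durations[i], 5), 20 + i + seq(0, durations[i], 5))
  }))
  sel <- select_presented_cells(tracks, k = 3)
  per <- sel |> dplyr::group_by(cell_id) |>
    dplyr::summarise(dur = max(frame_t_min) - min(frame_t_min))
  expect_equal(sort(per$dur), c(30, 50, 50))
  expect_equal(nrow(select_presented_cells(tracks, k = 1) |>
                      dplyr::distinct(cell_id)), 1L)
  two <- dplyr::filter(tracks, cell_id <= 2)
  expect_warning(all_back <- select_presented_cells(two, k = 3), "Only 2")
  expect_equal(dplyr::n_distinct(all_back$cell_id), 2L)
})

test_that("matched-initial-volume selection filters on the first volume", {
  v0 <- c(19.99, 27.3, 30.25)
  tracks <- dplyr::bind_rows(lapply(1:3, function(i) {
    make_track(i, seq(0, 20, 5), v0[i] + seq(0, 4))
  }))
  sel <- select_matched_initial_volume(tracks, target = 27, tol = 1)
  expect_equal(unique(sel$cell_id), 2L)
  expect_equal(nrow(select_matched_initial_volume(tracks, 27, tol = 0)), 0L)
  expect_equal(dplyr::n_distinct(
    select_matched_initial_volume(tracks, 27, tol = Inf)$cell_id), 3L)
})

test_that("condition summaries aggregate coefficients as mean and sample sd", {
  fits <- tibble::tibble(cell_id = 1:3, a = c(1, 1, 1) * 1e-10,
                         b = c(1, 2, 3) * 1e-3, c = c(0, 0.01, 0.02),
                         d = c(19.99, 30.25, 47.28),
                         r2 = c(0.99, 0.995, 1), n = 100L)
  s <- summarize_condition(fits, flow_rate = 150)
  expect_equal(s$d_mean, mean(c(19.99, 30.25, 47.28)), tolerance = 1e-12)
  expect_equal(round(s$d_mean, 2), 32.51)
  expect_equal(s$d_sd, sd(c(19.99, 30.25, 47.28)))
  expect_equal(s$a_sd, 0)
  one <- summarize_condition(fits[1, ], flow_rate = 30)
  expect_equal(one$d_mean, 19.99)
  expect_true(is.na(one$d_sd))
  expect_error(summarize_condition(fits[0, ]), "at least one")
})

test_that("summaries are invariant to cell order", {
  fits <- tibble::tibble(cell_id = 1:3, a = rnorm(3, 0, 1e-10),
                         b = rnorm(3, 0, 1e-3), c = rnorm(3, 0.01, 0.005),
                         d = c(20, 30, 45), r2 = c(0.99, 0.98, 0.999),
                         n = 50L)
  s1 <- summarize_condition(fits, flow_rate = 90)
  s2 <- summarize_condition(fits[c(3, 1, 2), ], flow_rate = 90)
  expect_equal(s1[, !grepl("volumes|periods", names(s1))],
               s2[, !grepl("volumes|periods", names(s2))])
})

test_that("find_optimal_flow honours both metrics, ties and errors", {
  mk <- function(flow, vmax, pmed) {
    tibble::tibble(flow_rate = flow, division_volume_max = vmax,
                   growth_period_median_min = pmed)
  }
  s <- dplyr::bind_rows(mk(150, 100, 900), mk(270, 140, 500),
                        mk(300, 120, 700))
  expect_equal(find_optimal_flow(s, "max_division_volume"), 270)
  expect_equal(find_optimal_flow(s, "min_growth_period"), 270)
  expect_equal(find_optimal_flow(s[1, ], "max_division_volume"), 150)
  tie <- dplyr::bind_rows(mk(180, 110, 600), mk(240, 110, 800))
  expect_equal(find_optimal_flow(tie, "max_division_volume"), c(180, 240))
  none <- mk(60, NA_real_, NA_real_)
  expect_error(find_optimal_flow(none, "max_division_volume"), "unavailable")
})

test_that("the flow-to-epsilon lookup interpolates between exact anchors", {
  expect_identical(flow_to_epsilon(270), 5.62e-5)
  expect_identical(flow_to_epsilon(30), 6.2e-6)
  expect_identical(flow_to_epsilon(420), 7.5e-5)
  mid <- flow_to_epsilon(150)
  expect_equal(mid, 6.2e-6 + (150 - 30) / (270 - 30) * (5.62e-5 - 6.2e-6))
  expect_error(flow_to_epsilon(500), "unknown")
  expect_error(flow_to_epsilon(0), "unknown")
  custom <- epsilon_map(tibble::tibble(flow = c(0, 100),
                                       epsilon = c(1e-6, 2e-6)))
  expect_equal(flow_to_epsilon(50, custom), 1.5e-6)
  expect_error(epsilon_map(tibble::tibble(flow = c(1, 1),
                                          epsilon = c(1e-6, 2e-6))),
               "distinct")
})
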