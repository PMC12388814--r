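#' Specify one synthetic cell
#'
#' A cell is drawn as a filled ellipse (the projection of a prolate spheroid,
#' matching the elongated shape of *Scenedesmus* cells) whose true volume
#' follows the cubic growth law `V(t) = a t^3 + b t^2 + c t + d` (t in
#' minutes, V in um^3; `d` is the initial volume). A cell may either divide
#' (it is replaced by two daughters) or be lost (flushed away by flow), never
#' both.
#'
#' @param centroid Numeric `(row, col)` centre in pixels.
#' @param growth_coeffs Numeric `(a, b, c, d)` of the cubic volume law, in
#'   um^3 min^-3, um^3 min^-2, um^3 min^-1 and um^3. `d` must be > 0.
#' @param orientation Major-axis orientation in radians (0 = along columns).
#' @param division_time,loss_time Event times in minutes, or `NULL`. Mutually
#'   exclusive.
#' @param area_noise_sd Relative (fractional) standard deviation of the
#'   apparent projected area, emulating measurement noise; 0 disables it.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(centroid, growth_coeffs, orientation = 0,
                      division_time = NULL, loss_time = NULL,
                      area_noise_sd = 0) {
  stopifnot(is.numeric(centroid), length(centroid) == 2L,
            is.numeric(growth_coeffs), length(growth_coeffs) == 4L,
            is.numeric(orientation), length(orientation) == 1L,
            is.numeric(area_noise_sd), area_noise_sd >= 0)
  if (growth_coeffs[4] <= 0) {
    abort("Initial volume `d` (growth_coeffs[4]) must be > 0.")
  }
  if (!is.null(division_time) && !is.null(loss_time)) {
    abort("`division_time` and `loss_time` are mutually exclusive.")
  }
  structure(
    list(centroid = as.numeric(centroid),
         growth_coeffs = as.numeric(growth_coeffs),
         orientation = orientation,
         division_time = division_time,
         loss_time = loss_time,
         area_noise_sd = area_noise_sd,
         birth_time = 0),
    class = "cell_spec"
  )
}

#' Specify a synthetic imaging scene
#'
#' Describes everything needed to render a micrograph time-lapse with known
#' ground truth: image geometry, pixel calibration, the cells, and the
#' foreground/background intensity model (per-channel Gaussian noise on 8-bit
#' values). Foreground and background must be separable in at least one
#' channel (|mean difference| >= 4 x the larger sd), cells must lie inside
#' the frame and must not overlap at their initial volumes.
#'
#' @param image_shape Integer `(rows, cols)` in pixels.
#' @param pixel_ratio Calibration ratio, um per pixel.
#' @param cells List of [cell_spec()] objects.
#' @param background_mean,foreground_mean Per-channel 8-bit means (length 1
#'   or 3). Defaults give dark background and bright greenish cells.
#' @param background_sd,foreground_sd Gaussian noise sd on 8-bit values.
#' @param rng_seed Master seed; each frame derives a child seed from
#'   `(rng_seed, t)` so any frame is reproducible in isolation.
#' @param aspect Minor/major semi-axis ratio of rendered ellipses.
#' @param volume_model 2D-to-3D rule the renderer inverts, so that measuring
#'   a noise-free render returns the generating volume (see
#'   [axes_from_volume()]).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(160L, 160L), pixel_ratio = 0.30,
                       cells = list(),
                       background_mean = 40, background_sd = 5,
                       foreground_mean = c(90, 190, 110), foreground_sd = 5,
                       rng_seed = 1L, aspect = 0.6,
                       volume_model = c("spheroid", "equivalent_sphere")) {
  volume_model <- arg_match(volume_model)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8),
            pixel_ratio > 0, is.list(cells))
  bg <- rep_len(background_mean, 3L)
  fg <- rep_len(foreground_mean, 3L)
  max_sd <- max(background_sd, foreground_sd)
  if (max_sd > 0 && all(abs(fg - bg) < 4 * max_sd)) {
    abort("Foreground/background means must differ by >= 4 sd in one channel.")
  }
  for (i in seq_along(cells)) {
    if (!inherits(cells[[i]], "cell_spec")) abort("`cells` must be cell_spec.")
    ctr <- cells[[i]]$centroid
    if (ctr[1] < 1 || ctr[1] > image_shape[1] ||
        ctr[2] < 1 || ctr[2] > image_shape[2]) {
      abort(sprintf("Cell %d centroid lies outside the image.", i))
    }
  }
  scene <- structure(
    list(image_shape = as.integer(image_shape), pixel_ratio = pixel_ratio,
         cells = cells, background_mean = bg, background_sd = background_sd,
         foreground_mean = fg, foreground_sd = foreground_sd,
         rng_seed = as.integer(rng_seed), aspect = aspect,
         volume_model = volume_model),
    class = "scene_spec"
  )
  check_no_overlap(scene)
  scene
}

# Initial-volume bounding-circle overlap check.
check_no_overlap <- function(scene) {
  n <- length(scene$cells)
  if (n < 2) return(invisible(TRUE))
  cal <- calibration(scene$pixel_ratio)
  a <- map_dbl(scene$cells, function(cl) {
    axes_from_volume(cl$growth_coeffs[4], scene$aspect, cal,
                     scene$volume_model)$a_px
  })
  ctr <- do.call(rbind, map(scene$cells, "centroid"))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (sqrt(sum((ctr[i, ] - ctr[j, ])^2)) < a[i] + a[j]) {
        abort(sprintf("Cells %d and %d overlap at their initial volumes.",
                      i, j))
      }
    }
  }
  invisible(TRUE)
}

# Deterministic per-frame child seed from (master seed, frame time).
frame_seed <- function(seed, t) {
  as.integer((abs(as.double(seed)) * 48271 + round(abs(t)) * 7919 + 1) %%
               2147483647)
}

# Cubic volume law at time t (minutes since the cell's birth).
cell_volume_at <- function(cell, t) {
  tt <- t - cell$birth_time
  cf <- cell$growth_coeffs
  cf[1] * tt^3 + cf[2] * tt^2 + cf[3] * tt + cf[4]
}

cell_is_live <- function(cell, t) {
  if (t < cell$birth_time) return(FALSE)
  if (!is.null(cell$division_time) && t >= cell$division_time) return(FALSE)
  if (!is.null(cell$loss_time) && t >= cell$loss_time) return(FALSE)
  TRUE
}

#' Render one synthetic micrograph
#'
#' Draws every live cell as a filled ellipse sized by inverting the scene's
#' volume model, applies the per-cell apparent-area noise, then adds
#' per-channel Gaussian pixel noise clipped to \[0, 255\]. Rasterisation is
#' coverage-based: a pixel belongs to the cell when at least half of its
#' footprint lies inside the ellipse (judged on a 4x4 subsample grid), which
#' keeps the discretised area close to the analytic ellipse area even for
#' cells only 15-20 pixels long. All randomness is governed by a child seed
#' derived from `(rng_seed, t)`, so identical scene and time give a
#' bit-identical frame.
#'
#' @param scene A [scene_spec()].
#' @param t Frame time in minutes (>= 0).
#' @return A list with `frame` (rows x cols x 3 numeric array, 0-255),
#'   `mask` (integer label matrix, 0 = background, k = cell id) and `truth`
#'   (tibble: `cell_id`, `t_min`, `true_volume_um3`, `centroid_row`,
#'   `centroid_col`).
#' @export
render_frame <- function(scene, t) {
  stopifnot(inherits(scene, "scene_spec"), is.numeric(t), t >= 0)
  set.seed(frame_seed(scene$rng_seed, t))
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  mask <- matrix(0L, nr, nc)
  cal <- calibration(scene$pixel_ratio)
  live_ids <- integer(0)
  truth <- list()
  cells <- scene$cells
  ids <- cell_ids(cells)
  for (k in seq_along(cells)) {
    cl <- cells[[k]]
    if (!cell_is_live(cl, t)) next
    v_true <- cell_volume_at(cl, t)
    if (!is.finite(v_true) || v_true <= 0) {
      abort(sprintf("Cell %d has non-positive volume at t = %g.", ids[k], t))
    }
    ax <- axes_from_volume(v_true, scene$aspect, cal, scene$volume_model)
    a <- ax$a_px; b <- ax$b_px
    if (cl$area_noise_sd > 0) {
      nf <- max(0.5, 1 + rnorm(1, 0, cl$area_noise_sd))
      a <- a * sqrt(nf); b <- b * sqrt(nf)
    }
    ctr <- cl$centroid
    if (ctr[1] - a < 0.5 || ctr[1] + a > nr + 0.5 ||
        ctr[2] - a < 0.5 || ctr[2] + a > nc + 0.5) {
      abort(sprintf("Cell %d ellipse exceeds the frame at t = %g.", ids[k], t))
    }
    rows <- seq(max(1L, floor(ctr[1] - a)), min(nr, ceiling(ctr[1] + a)))
    cols <- seq(max(1L, floor(ctr[2] - a)), min(nc, ceiling(ctr[2] + a)))
    th <- cl$orientation
    nsub <- 4L
    offs <- (seq_len(nsub) - 0.5) / nsub - 0.5
    coverage <- matrix(0L, length(rows), length(cols))
    for (or in offs) {
      for (oc in offs) {
        dr <- outer(rows + or - ctr[1], rep(1, length(cols)))
        dc <- outer(rep(1, length(rows)), cols + oc - ctr[2])
        u <- (dc * cos(th) + dr * sin(th)) / a
        v <- (-dc * sin(th) + dr * cos(th)) / b
        coverage <- coverage + ((u^2 + v^2) <= 1)
      }
    }
    inside <- coverage >= nsub * nsub / 2
    sub <- mask[rows, cols, drop = FALSE]
    sub[inside] <- ids[k]
    mask[rows, cols] <- sub
    live_ids <- c(live_ids, ids[k])
    truth[[length(truth) + 1L]] <- tibble(
      cell_id = ids[k], t_min = t, true_volume_um3 = v_true,
      centroid_row = ctr[1], centroid_col = ctr[2]
    )
  }
  fg <- mask > 0
  frame <- array(0, dim = c(nr, nc, 3L))
  sd_px <- ifelse(fg, scene$foreground_sd, scene$background_sd)
  for (ch in 1:3) {
    base <- ifelse(fg, scene$foreground_mean[ch], scene$background_mean[ch])
    if (max(scene$background_sd, scene$foreground_sd) > 0) {
      base <- base + rnorm(nr * nc) * sd_px
    }
    frame[, , ch] <- pmin(255, pmax(0, round(base)))
  }
  truth <- if (length(truth)) bind_rows(truth) else
    tibble(cell_id = integer(), t_min = numeric(),
           true_volume_um3 = numeric(),
           centroid_row = numeric(), centroid_col = numeric())
  list(frame = frame, mask = mask, truth = truth)
}

cell_ids <- function(cells) {
  map_int(seq_along(cells), function(k) {
    id <- cells[[k]]$id
    if (is.null(id)) k else as.integer(id)
  })
}

#' Generate a synthetic time-lapse with ground truth
#'
#' Renders frames at a fixed cadence (default 5 min, the camera interval the
#' platform uses). At a cell's `division_time` the cell is replaced by two
#' daughters, each holding 45% of the parent volume, placed just apart along
#' the parent's major axis (so a tracker sees the parent vanish and two
#' nearby smaller objects appear). Daughters are only weakly attached and
#' are flushed away after `daughter_residence` minutes. At `loss_time` a
#' cell simply disappears (flushed away by flow). All events are logged.
#'
#' @param scene A [scene_spec()].
#' @param t_start,t_end Simulation window in minutes (`t_end > t_start`).
#' @param interval Frame interval in minutes. If it does not divide the
#'   window, the last frame falls at the largest multiple and a warning is
#'   issued.
#' @param daughter_residence How long (minutes) daughter cells remain
#'   visible after a division before being flushed away.
#' @return An object of class `timelapse`: list with `times`, `frames`
#'   (list of arrays), `masks` (list of label matrices), `truth` (long
#'   tibble), `events` (tibble: `cell_id`, `t_min`, `event`), `interval`,
#'   and the final `scene` (including daughter cells).
#' @export
generate_timelapse <- function(scene, t_start = 0, t_end, interval = 5,
                               daughter_residence = 60) {
  stopifnot(inherits(scene, "scene_spec"), t_end > t_start, interval > 0)
  if (abs((t_end - t_start) %% interval) > 1e-9 &&
      abs((t_end - t_start) %% interval - interval) > 1e-9) {
    warn("`interval` does not divide the window; last frame at the largest multiple.")
  }
  times <- seq(t_start, t_end, by = interval)
  cells <- scene$cells
  for (k in seq_along(cells)) cells[[k]]$id <- k
  next_id <- length(cells) + 1L
  cal <- calibration(scene$pixel_ratio)
  events <- list()
  frames <- vector("list", length(times))
  masks <- vector("list", length(times))
  truth <- vector("list", length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    # process divisions whose time has arrived (parent -> two daughters)
    for (k in seq_along(cells)) {
      cl <- cells[[k]]
      if (!is.null(cl$division_time) && t >= cl$division_time &&
          !isTRUE(cl$divided)) {
        v_par <- cell_volume_at(cl, cl$division_time)
        v_dau <- 0.45 * v_par
        a_d <- axes_from_volume(v_dau, scene$aspect, cal,
                                scene$volume_model)$a_px
        off <- a_d + 2
        dir <- c(sin(cl$orientation), cos(cl$orientation))
        for (s in c(-1, 1)) {
          dau <- cell_spec(centroid = cl$centroid + s * off * dir,
                           growth_coeffs = c(0, 0, 0, v_dau),
                           orientation = cl$orientation,
                           loss_time = t + daughter_residence,
                           area_noise_sd = cl$area_noise_sd)
          dau$birth_time <- t
          dau$id <- next_id
          next_id <- next_id + 1L
          cells[[length(cells) + 1L]] <- dau
        }
        cells[[k]]$divided <- TRUE
        events[[length(events) + 1L]] <- tibble(
          cell_id = cl$id, t_min = t, event = "division")
      }
      if (!is.null(cl$loss_time) && t >= cl$loss_time &&
          !isTRUE(cl$lost)) {
        cells[[k]]$lost <- TRUE
        events[[length(events) + 1L]] <- tibble(
          cell_id = cl$id, t_min = t, event = "lost")
      }
    }
    scene_t <- scene
    scene_t$cells <- cells
    fr <- render_frame(scene_t, t)
    frames[[i]] <- fr$frame
    masks[[i]] <- fr$mask
    truth[[i]] <- fr$truth
  }
  structure(
    list(times = times, frames = frames, masks = masks,
         truth = bind_rows(truth),
         events = if (length(events)) bind_rows(events) else
           tibble(cell_id = integer(), t_min = numeric(), event = character()),
         interval = interval,
         scene = { scene$cells <- cells; scene }),
    class = "timelapse"
  )
}

#' @export
print.timelapse <- function(x, ...) {
  cat(sprintf("<timelapse> %d frames (%g-%g min, every %g min), %d cells, %d events\n",
              length(x$times), min(x$times), max(x$times), x$interval,
              length(unique(x$truth$cell_id)), nrow(x$events)))
  invisible(x)
}

#' Sample labelled pixels for classifier training
#'
#' Emulates the manual pixel labelling step used to train the cell/background
#' classifier: it draws a balanced, seeded sample of per-pixel channel values
#' from one or more frames, labelled from the ground-truth masks.
#'
#' @param frames A frame array or list of frame arrays.
#' @param masks Matching label mask or list of masks.
#' @param n_per_class Number of pixels to draw from each class (> 0).
#' @param rng_seed Seed controlling the draw.
#' @return A tibble with columns `r`, `g`, `b` (0-255) and `label`
#'   (factor, `"background"`/`"cell"`), `2 * n_per_class` rows.
#' @export
sample_training_pixels <- function(frames, masks, n_per_class = 1000,
                                   rng_seed = 1L) {
  if (!is.list(frames)) frames <- list(frames)
  if (!is.list(masks)) masks <- list(masks)
  stopifnot(length(frames) == length(masks))
  if (n_per_class <= 0) abort("`n_per_class` must be > 0.")
  px <- map2(frames, masks, function(fr, mk) {
    tibble(r = as.vector(fr[, , 1]), g = as.vector(fr[, , 2]),
           b = as.vector(fr[, , 3]),
           label = ifelse(as.vector(mk) > 0, "cell", "background"))
  }) |> bind_rows()
  n_cell <- sum(px$label == "cell")
  n_bg <- sum(px$label == "background")
  if (n_cell == 0 || n_bg == 0) abort("Both classes must be present.")
  if (n_per_class > min(n_cell, n_bg)) {
    abort(sprintf("Requested %d per class; only %d cell / %d background available.",
                  n_per_class, n_cell, n_bg))
  }
  set.seed(rng_seed)
  idx_cell <- sample(which(px$label == "cell"), n_per_class)
  idx_bg <- sample(which(px$label == "background"), n_per_class)
  out <- px[c(idx_bg, idx_cell), ]
  out$label <- factor(out$label, levels = c("background", "cell"))
  out
}
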