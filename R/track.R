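#' Link per-frame detections into per-cell tracks
#'
#' Cells in the flow chamber are attached and essentially stationary, so
#' linking is greedy nearest-centroid matching between consecutive frames,
#' gated at `max_displacement`. A division ends a track in either of two
#' ways: at least two detections fall within the track's gate and every one
#' of them is markedly smaller than the track's last area (below
#' `division_area_ratio` of it — two daughters carrying 45% of the parent
#' volume each project to about 59% of its area, so the default 0.8
#' separates daughters from ordinary growth fluctuation); or the track is
#' left unmatched while at least two unmatched detections appear within its
#' gate. A track left unmatched otherwise ends as `"lost"` (the loss is
#' stamped one interval after the last sighting). A new detection matching no
#' existing track starts a new track, attached at its first frame. Tracks
#' alive at the final frame end as `"censored"`.
#'
#' @param detections A detections tibble over frames on a uniform time grid
#'   (e.g. from [segment_timelapse()], optionally after [measure_cells()]).
#' @param max_displacement Matching gate in pixels.
#' @param interval Frame interval in minutes; inferred from the grid if
#'   omitted. A non-uniform grid is an error.
#' @param division_area_ratio Area ratio below which gate candidates count
#'   as daughters (see above).
#' @return A tibble: all detection columns plus `cell_id`,
#'   `attachment_t_min`, `end_t_min` and `end_event`
#'   (`"division"`/`"lost"`/`"censored"`), ordered by cell and time.
#' @export
track_cells <- function(detections, max_displacement = 15, interval = NULL,
                        division_area_ratio = 0.8) {
  stopifnot(is.data.frame(detections), nrow(detections) > 0)
  times <- sort(unique(detections$frame_t_min))
  if (length(times) > 1) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9 * max(1, dt[1])) {
      abort("Detections must lie on a uniform time grid.")
    }
    grid_interval <- dt[1]
  } else {
    grid_interval <- NA_real_
  }
  if (is.null(interval)) interval <- grid_interval
  if (is.na(interval)) interval <- 0

  detections <- as_tibble(detections)
  detections$.row <- seq_len(nrow(detections))
  by_frame <- map(times, function(t) detections[detections$frame_t_min == t, ])

  assign_id <- integer(nrow(detections))
  # active tracks: id -> last centroid/row
  active <- list()
  next_id <- 1L
  meta <- list()  # id -> list(attachment, end_t, end_event)
  for (i in seq_along(times)) {
    cur <- by_frame[[i]]
    ncur <- nrow(cur)
    matched_cur <- rep(FALSE, ncur)
    # explicit split check: >= 2 gate candidates, all clearly smaller
    if (length(active) && ncur) {
      for (ai in rev(seq_along(active))) {
        ctr <- active[[ai]]$centroid
        d_cand <- sqrt((cur$centroid_row - ctr[1])^2 +
                       (cur$centroid_col - ctr[2])^2)
        cand <- which(d_cand <= max_displacement)
        if (length(cand) >= 2L &&
            all(cur$area_px2[cand] <
                division_area_ratio * active[[ai]]$area)) {
          id <- active[[ai]]$id
          meta[[id]]$end_event <- "division"
          meta[[id]]$end_t <- times[i]
          active[[ai]] <- NULL
        }
      }
    }
    matched_act <- rep(FALSE, length(active))
    if (length(active) && ncur) {
      prev_xy <- do.call(rbind, map(active, "centroid"))
      cur_xy <- cbind(cur$centroid_row, cur$centroid_col)
      D <- sqrt(outer(prev_xy[, 1], cur_xy[, 1], "-")^2 +
                outer(prev_xy[, 2], cur_xy[, 2], "-")^2)
      repeat {
        D_ok <- D
        D_ok[matched_act, ] <- Inf
        D_ok[, matched_cur] <- Inf
        m <- which.min(D_ok)
        if (!length(m) || !is.finite(D_ok[m]) ||
            D_ok[m] > max_displacement) break
        ai <- ((m - 1L) %% nrow(D)) + 1L
        ci <- ((m - 1L) %/% nrow(D)) + 1L
        matched_act[ai] <- TRUE
        matched_cur[ci] <- TRUE
        id <- active[[ai]]$id
        assign_id[cur$.row[ci]] <- id
        active[[ai]]$centroid <- c(cur$centroid_row[ci], cur$centroid_col[ci])
        active[[ai]]$area <- cur$area_px2[ci]
      }
    }
    # close unmatched active tracks
    if (length(active)) {
      for (ai in rev(seq_along(active))) {
        if (matched_act[ai]) next
        id <- active[[ai]]$id
        ctr <- active[[ai]]$centroid
        n_new <- 0L
        if (ncur) {
          d_new <- sqrt((cur$centroid_row - ctr[1])^2 +
                        (cur$centroid_col - ctr[2])^2)
          n_new <- sum(!matched_cur & d_new <= max_displacement)
        }
        if (n_new >= 2L) {
          meta[[id]]$end_event <- "division"
          meta[[id]]$end_t <- times[i]
        } else {
          meta[[id]]$end_event <- "lost"
          meta[[id]]$end_t <- times[i - 1L] + interval
        }
        active[[ai]] <- NULL
      }
    }
    # open new tracks for unmatched detections
    if (ncur) {
      for (ci in which(!matched_cur)) {
        id <- next_id; next_id <- next_id + 1L
        assign_id[cur$.row[ci]] <- id
        active[[length(active) + 1L]] <-
          list(id = id, centroid = c(cur$centroid_row[ci],
                                     cur$centroid_col[ci]),
               area = cur$area_px2[ci])
        meta[[id]] <- list(attachment = times[i], end_t = times[i],
                           end_event = "censored")
      }
    }
  }
  for (a in active) {
    meta[[a$id]]$end_t <- times[length(times)]
    meta[[a$id]]$end_event <- "censored"
  }
  meta_tbl <- tibble(
    cell_id = seq_along(meta),
    attachment_t_min = map_dbl(meta, "attachment"),
    end_t_min = map_dbl(meta, "end_t"),
    end_event = map_chr(meta, "end_event")
  )
  detections$cell_id <- assign_id
  detections$.row <- NULL
  detections |>
    left_join(meta_tbl, by = "cell_id") |>
    arrange(.data$cell_id, .data$frame_t_min)
}
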