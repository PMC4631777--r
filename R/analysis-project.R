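#' Assign spots to poles/centromeres and project onto the spindle axis
#'
#' Per-frame geometry step of the tracking pipeline: among the four tracked
#' spots of a frame (two spindle-pole markers, two sister-centromere markers)
#' the pair with the largest pairwise distance is taken to be the poles; the
#' remaining two are the centromeres.  All four are orthogonally projected
#' onto the pole-pole axis and reported relative to the spindle centre (the
#' pole midpoint).  Frames with a spot count other than 4 are flagged invalid
#' and dropped (with a message), never interpolated.
#'
#' @param spots A data frame with columns `t`, `x`, `y` (image-plane
#'   coordinates, um), one row per spot.
#' @return A `kt_trajectory` tibble with columns `t`, `pole1`, `pole2`
#'   (`pole1 < pole2`), `cenA`, `cenB` (sorted along the axis); one row per
#'   valid frame.
#' @examples
#' spots <- data.frame(t = 0, x = c(0, 3, 1.4, 1.6), y = 0)
#' assign_and_project(spots)
#' @export
assign_and_project <- function(spots) {
  need <- c("t", "x", "y")
  miss <- setdiff(need, names(spots))
  if (length(miss) > 0) {
    abort(paste0("`spots` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  frames <- split(spots, spots$t)
  bad <- 0L
  rows <- lapply(frames, function(fr) {
    if (nrow(fr) != 4) {
      bad <<- bad + 1L
      return(NULL)
    }
    xy <- as.matrix(fr[, c("x", "y")])
    dm <- as.matrix(stats::dist(xy))
    ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    poles <- sort(ij)
    cens <- setdiff(1:4, poles)
    u <- xy[poles[2], ] - xy[poles[1], ]
    u <- u / sqrt(sum(u^2))
    # orient the axis deterministically so orientation is stable over frames
    if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
    ctr <- (xy[poles[1], ] + xy[poles[2], ]) / 2
    proj <- as.numeric((xy - matrix(ctr, 4, 2, byrow = TRUE)) %*% u)
    pp <- sort(proj[poles])
    cc <- sort(proj[cens])
    tibble(t = fr$t[1], pole1 = pp[1], pole2 = pp[2],
           cenA = cc[1], cenB = cc[2])
  })
  if (bad > 0) {
    inform(sprintf("assign_and_project: dropped %d frame(s) with spot count != 4", bad))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out <- dplyr::arrange(out, .data$t)
  class(out) <- c("kt_trajectory", class(out))
  out
}

#' Normalized distance to the spindle centre
#'
#' Distance of a sister-pair midpoint to the spindle centre divided by the
#' spindle length: 0 at the centre, 0.5 at a pole.  Values above 0.5 (a
#' kinetochore outside the pole span) are allowed but flagged with a warning.
#'
#' @param mid Midpoint position(s) along the spindle axis, um.
#' @param pole1,pole2 Pole positions, um (`pole1 != pole2`).
#' @return Numeric vector of normalized distances.
#' @examples
#' normalized_distance(0.33, -1.5, 1.5)  # 0.11
#' @export
normalized_distance <- function(mid, pole1, pole2) {
  L <- abs(pole2 - pole1)
  if (any(L == 0)) abort("zero spindle length: `pole1` must differ from `pole2`")
  nd <- abs(mid - (pole1 + pole2) / 2) / L
  if (any(nd > 0.5, na.rm = TRUE)) {
    warn(sprintf("%d normalized distance(s) exceed 0.5 (midpoint outside the pole span)",
                 sum(nd > 0.5, na.rm = TRUE)))
  }
  nd
}

#' Ensemble time-course of centromere and pole distances to the centre
#'
#' Aligns a collection of trajectories on their anaphase-onset times and
#' averages, per time point, the absolute distance between the sister-pair
#' midpoint and the spindle centre, and between the poles and the centre
#' (half the spindle length).  Distances are in um, deliberately not
#' normalized by spindle size.
#'
#' @param trajs A list of `kt_trajectory` tibbles (or a single one).
#' @param onsets Anaphase-onset times (s), one per trajectory; defaults to
#'   each trajectory's `"anaphase_onset"` attribute.
#' @param dt Output sampling interval; defaults to the median frame interval
#'   of the first trajectory.
#' @return A tibble with `time` (relative to anaphase onset), `cen_mean`,
#'   `cen_sd`, `pole_mean`, `pole_sd` and `n` (trajectories contributing).
#' @export
center_distance_timecourse <- function(trajs, onsets = NULL, dt = NULL) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  if (length(trajs) == 0) abort("`trajs` is empty")
  if (is.null(onsets)) {
    onsets <- vapply(trajs, function(tr) {
      on <- attr(tr, "anaphase_onset")
      if (is.null(on)) abort("trajectory lacks an anaphase-onset annotation")
      on
    }, numeric(1))
  }
  if (length(onsets) != length(trajs)) {
    abort("`onsets` must have one value per trajectory")
  }
  if (is.null(dt)) dt <- median(diff(trajs[[1]]$t))
  per <- purrr::map2(trajs, onsets, function(tr, on) {
    rel <- tr$t - on
    ctr <- (tr$pole1 + tr$pole2) / 2
    d_cen <- abs((tr$cenA + tr$cenB) / 2 - ctr)
    d_pole <- (tr$pole2 - tr$pole1) / 2
    grid <- seq(ceiling(min(rel) / dt) * dt, floor(max(rel) / dt) * dt, by = dt)
    tibble(time = grid,
           d_cen = approx(rel, d_cen, xout = grid)$y,
           d_pole = approx(rel, d_pole, xout = grid)$y)
  })
  dplyr::bind_rows(per) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(cen_mean = mean(.data$d_cen),
                     cen_sd = if (dplyr::n() > 1) sd(.data$d_cen) else 0,
                     pole_mean = mean(.data$d_pole),
                     pole_sd = if (dplyr::n() > 1) sd(.data$d_pole) else 0,
                     n = dplyr::n(), .groups = "drop")
}
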