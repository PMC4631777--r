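#' Length-binned statistics of fluorescence intensity profiles
#'
#' Summarises a collection of 1-D fluorescence profiles recorded along
#' microtubules of different lengths (e.g. a plus-end-accumulating kinesin-8
#' marker on intra-nuclear microtubules).  Each profile is normalized by its
#' own median intensity (profiles with zero median are excluded and
#' reported), mapped to fractional position 0 (minus end) to 1 (plus end),
#' and resampled to a common grid; profiles are then grouped into
#' microtubule-length bins and averaged per position.  The "tip intensity"
#' of a profile is the mean normalized intensity over the distal `tip_frac`
#' of the position axis, and the per-bin tip table shows how plus-end
#' accumulation changes with microtubule length (any monotonic trend is
#' reported, never assumed).
#'
#' @param profiles A data frame with columns `profile_id`, `position`
#'   (sample order or physical position along the microtubule), `intensity`
#'   (arbitrary units) and `mt_length` (um, constant within a profile).
#'   Profiles need at least 3 samples.
#' @param bins Increasing vector of length-bin edges, um; profiles outside
#'   the range are dropped.
#' @param tip_frac Fraction of the position axis counted as the plus-end
#'   window.
#' @param grid_n Number of points of the common fractional-position grid.
#' @return A `profile_stats` object: list with `profile` (per-bin mean +/- sd
#'   normalized profile over fractional position), `tips` (per-bin tip
#'   intensity mean +/- sem, with bin mid-lengths) and `excluded`
#'   (profile ids dropped for zero median).  `tidy()` returns the tip table.
#' @export
klp5_profile_stats <- function(profiles, bins = seq(0.5, 3.5, by = 0.5),
                               tip_frac = 0.1, grid_n = 50) {
  need <- c("profile_id", "position", "intensity", "mt_length")
  miss <- setdiff(need, names(profiles))
  if (length(miss) > 0) {
    abort(paste0("`profiles` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (is.unsorted(bins, strictly = TRUE)) abort("`bins` must be increasing")
  grid <- seq(0, 1, length.out = grid_n)
  excluded <- character(0)
  per <- profiles |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::group_map(function(pr, key) {
      if (nrow(pr) < 3) abort("each profile needs at least 3 samples")
      med <- median(pr$intensity)
      if (med == 0) {
        excluded <<- c(excluded, as.character(key$profile_id))
        return(NULL)
      }
      pr <- dplyr::arrange(pr, .data$position)
      s <- (pr$position - min(pr$position)) /
           (max(pr$position) - min(pr$position))
      v <- pr$intensity / med
      tibble(profile_id = key$profile_id,
             mt_length = pr$mt_length[1],
             tip = mean(v[s >= 1 - tip_frac]),
             pos = list(grid),
             val = list(approx(s, v, xout = grid)$y))
    }) |>
    dplyr::bind_rows()
  if (length(excluded) > 0) {
    inform(sprintf("klp5_profile_stats: excluded %d profile(s) with zero median intensity",
                   length(excluded)))
  }
  if (nrow(per) == 0) abort("no usable profiles")
  per$bin <- cut(per$mt_length, bins, right = FALSE)
  n_out <- sum(is.na(per$bin))
  if (n_out > 0) {
    inform(sprintf("klp5_profile_stats: %d profile(s) outside the bin range", n_out))
  }
  per <- per[!is.na(per$bin), ]
  profile <- per |>
    tidyr::unnest(c("pos", "val")) |>
    dplyr::group_by(.data$bin, .data$pos) |>
    dplyr::summarise(mean = mean(.data$val),
                     sd = if (dplyr::n() > 1) sd(.data$val) else 0,
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::rename(position = "pos")
  tips <- per |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mid_length = mean(.data$mt_length),
                     tip_mean = mean(.data$tip),
                     tip_sem = if (dplyr::n() > 1) sd(.data$tip) / sqrt(dplyr::n()) else NA_real_,
                     n = dplyr::n(), .groups = "drop")
  structure(list(profile = profile, tips = tips, bins = bins,
                 tip_frac = tip_frac, excluded = excluded),
            class = "profile_stats")
}

#' @export
print.profile_stats <- function(x, ...) {
  cat(sprintf("<profile_stats> %d length bin(s), %d profile(s)\n",
              nrow(x$tips), sum(x$tips$n)))
  print(x$tips)
  invisible(x)
}

#' Group means, standard errors and pairwise Student's t-tests
#'
#' Summarises a measurement per experimental group (mean +/- sem) and runs an
#' unpaired two-sided Student's t-test (equal variances) for each requested
#' pair of groups.
#'
#' @param data A data frame.
#' @param value Column with the measurements (tidy-eval).
#' @param group Column with the group labels (tidy-eval).
#' @param comparisons List of length-2 character vectors naming group pairs
#'   to test; defaults to all pairs.
#' @return A `group_summary` object: `tidy()` gives the per-group table
#'   (`group`, `n`, `mean`, `sem`); `$tests` holds `group1`, `group2`,
#'   `statistic`, `p.value`.
#' @examples
#' d <- data.frame(g = rep(c("wt", "mut"), each = 4),
#'                 y = c(1, 2, 1, 2, 4, 5, 4, 5))
#' summarize_groups(d, y, g)$tests
#' @export
summarize_groups <- function(data, value, group, comparisons = NULL) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  d <- tibble(g = as.character(dplyr::pull(data, !!group)),
              y = dplyr::pull(data, !!value))
  d <- d[is.finite(d$y), ]
  summ <- d |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                     sem = sd(.data$y) / sqrt(dplyr::n()), .groups = "drop") |>
    dplyr::rename(group = "g")
  if (any(summ$n < 2)) abort("every group needs at least 2 values")
  if (is.null(comparisons)) {
    comparisons <- utils::combn(sort(unique(d$g)), 2, simplify = FALSE)
  }
  tests <- purrr::map_dfr(comparisons, function(pr) {
    tt <- t.test(d$y[d$g == pr[1]], d$y[d$g == pr[2]], var.equal = TRUE)
    tibble(group1 = pr[1], group2 = pr[2],
           statistic = unname(tt$statistic), p.value = tt$p.value)
  })
  structure(list(summary = summ, tests = tests), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$summary)
  cat("pairwise Student's t-tests:\n")
  print(x$tests)
  invisible(x)
}
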