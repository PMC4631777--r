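#' Lagging time between sister-chromatid pole arrivals
#'
#' After anaphase onset each sister chromatid moves towards a pole; its
#' target pole is the one on its side of the spindle centre at the end of the
#' trajectory.  Arrival is the first time the sister comes within `epsilon`
#' of its (tracked, possibly still moving) target pole.  The lagging time is
#' the absolute difference between the two arrival times, symmetric in the
#' sister labels; a sister that never arrives is reported as censored and the
#' lag is `NA`.
#'
#' @param traj A `kt_trajectory` tibble (`t`, `pole1`, `pole2`, `cenA`,
#'   `cenB`).
#' @param onset Anaphase-onset time (s); defaults to the trajectory's
#'   `"anaphase_onset"` attribute.  Missing both is an error.
#' @param epsilon Arrival tolerance, um.
#' @return A one-row tibble: `lagging_time` (s), `censored`, `t_arrival_A`,
#'   `t_arrival_B`.
#' @export
lagging_time <- function(traj, onset = NULL, epsilon = 0.2) {
  if (epsilon <= 0) abort("`epsilon` must be > 0")
  onset <- onset %||% attr(traj, "anaphase_onset")
  if (is.null(onset)) abort("missing anaphase-onset annotation")
  a <- traj[traj$t >= onset, ]
  if (nrow(a) == 0) abort("no frames after anaphase onset")
  ctr_end <- (a$pole1[nrow(a)] + a$pole2[nrow(a)]) / 2
  arrive <- function(x) {
    target <- if (x[length(x)] >= ctr_end) a$pole2 else a$pole1
    hit <- which(abs(x - target) <= epsilon)
    if (length(hit) == 0) NA_real_ else a$t[hit[1]]
  }
  tA <- arrive(a$cenA)
  tB <- arrive(a$cenB)
  tibble(lagging_time = abs(tA - tB),
         censored = is.na(tA) || is.na(tB),
         t_arrival_A = tA, t_arrival_B = tB)
}

#' Mis-segregation call at the end of anaphase A
#'
#' `TRUE` when both sister chromatids end on the same side of the spindle
#' centre (two centromere signals at the same pole).  A sister lying exactly
#' at the centre is counted as not mis-segregated (documented tie-break).
#'
#' @param traj A `kt_trajectory` tibble.
#' @return Logical scalar.
#' @examples
#' tr <- tibble::tibble(t = 0, pole1 = -1.5, pole2 = 1.5,
#'                      cenA = 1.2, cenB = 1.4)
#' missegregation_flag(tr)  # TRUE
#' @export
missegregation_flag <- function(traj) {
  i <- nrow(traj)
  ctr <- (traj$pole1[i] + traj$pole2[i]) / 2
  sA <- sign(traj$cenA[i] - ctr)
  sB <- sign(traj$cenB[i] - ctr)
  sA != 0 && sB != 0 && sA == sB
}
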