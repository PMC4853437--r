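#' Distance from map positions to the feeding-zone door
#'
#' Euclidean distance in metres between each position and the door centroid.
#' The default centroid (5.5, 3.5) is the centre of the 1 x 1 m door cell of
#' the feeding zone on the observation map.
#'
#' @param x,y position coordinates in metres; `NA` marks an out-of-sight
#'   record and propagates to an `NA` distance rather than a number.
#' @param door numeric length-2, door centroid `(x, y)`.
#' @return numeric vector of distances in metres.
#' @examples
#' distance_to_door(8.5, 7.5)  # 5 (3-4-5 triangle)
#' @export
distance_to_door <- function(x, y, door = c(5.5, 3.5)) {
  sqrt((x - door[1])^2 + (y - door[2])^2)
}

#' Per-individual spatial frequencies around the food patch
#'
#' Summarises each individual's use of space relative to the feeding-zone
#' door over one observation period (afternoon by default, when competition
#' for the still-closed food patch is strongest):
#'
#' * `F10M` — relative frequency of scans within `r_near` m of the door
#'   (`d <= r_near`), out of the scans in which the individual was observed
#'   anywhere in the area. Adjusts for unequal observation counts.
#' * `SRF10M` — `sqrt(F10M)`, the square-root transform used downstream to
#'   stabilise variance.
#' * `F20M` — absolute count of scans beyond `r_far` m (`d > r_far`) plus
#'   the scans in which the individual was out of sight (in the forest):
#'   unseen animals are by construction far from the patch.
#'
#' Observations at intermediate distances (`r_near < d <= r_far`) contribute
#' to neither measure; the design contrasts proximity with distance. The
#' near boundary is inclusive and the far boundary exclusive, matching
#' "within 10 m" and "over 20 m".
#'
#' @param scans validated scan tibble (see [read_scan_table()]); must cover
#'   the requested period.
#' @param door door centroid, metres.
#' @param r_near,r_far buffer radii in metres.
#' @param period `"pm"` (default), `"am"`, or `"all"`.
#' @return A tibble with one row per individual appearing in the scans:
#'   `individual`, `n_scans_observed`, `F10M`, `SRF10M`, `F20M`. Individuals
#'   never observed in the period have `NA` F10M/SRF10M (flagged, not 0) but
#'   a valid F20M.
#' @export
spatial_frequencies <- function(scans, door = c(5.5, 3.5),
                                r_near = 10, r_far = 20, period = "pm") {
  stopifnot(period %in% c("am", "pm", "all"))
  if (period != "all") scans <- dplyr::filter(scans, .data$period == !!period)
  scans |>
    dplyr::mutate(d = distance_to_door(.data$x, .data$y, door)) |>
    dplyr::group_by(individual = .data$individual) |>
    dplyr::summarise(
      n_scans_observed = sum(.data$visible),
      F10M = ifelse(.data$n_scans_observed > 0,
                    sum(.data$visible & .data$d <= r_near) / .data$n_scans_observed,
                    NA_real_),
      SRF10M = sqrt(.data$F10M),
      F20M = sum(.data$visible & .data$d > r_far) + sum(!.data$visible),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$individual)
}
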