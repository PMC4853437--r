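#' Scan-sampling schedule
#'
#' Instantaneous scan sampling runs on a fixed clock: a morning block and an
#' afternoon block, sampled every `every_min` minutes with both endpoints
#' included. The default blocks (09:00--12:00 and 15:00--18:00 at 15 min)
#' give 13 morning and 13 afternoon scans, i.e. 26 scans per observation day.
#'
#' @param am,pm character vectors of length 2, block start/end as `"HH:MM"`.
#' @param every_min sampling interval in minutes.
#' @return A tibble with one row per scheduled scan: `time` (`"HH:MM"`),
#'   `minutes` (minutes after midnight) and `period` (`"am"`/`"pm"`). The
#'   noon scan belongs to the morning block.
#' @examples
#' nrow(scan_schedule())  # 26
#' @export
scan_schedule <- function(am = c("09:00", "12:00"),
                          pm = c("15:00", "18:00"),
                          every_min = 15) {
  stopifnot(every_min > 0)
  block <- function(bounds, label) {
    mins <- seq(.hm_to_min(bounds[1]), .hm_to_min(bounds[2]), by = every_min)
    tibble::tibble(time = .min_to_hm(mins), minutes = mins, period = label)
  }
  dplyr::bind_rows(block(am, "am"), block(pm, "pm"))
}

#' Total observation time implied by a scan count
#'
#' With one scan every `every_min` minutes, `n_scans` scans represent
#' `n_scans * every_min / 60` hours of observation.
#'
#' @param n_scans number of completed scans.
#' @param every_min sampling interval in minutes.
#' @return Hours of observation (numeric scalar).
#' @examples
#' observation_hours(631)  # 157.75
#' @export
observation_hours <- function(n_scans, every_min = 15) {
  stopifnot(n_scans >= 0)
  n_scans * every_min / 60
}

#' Assign observation period from clock time
#'
#' Times up to and including 12:00 are morning (`"am"`); later times are
#' afternoon (`"pm"`).
#'
#' @param time character vector of `"HH:MM"` (optionally `"HH:MM:SS"`) times.
#' @return factor with levels `am`, `pm`.
#' @export
scan_period <- function(time) {
  mins <- vapply(time, .hm_to_min, numeric(1), USE.NAMES = FALSE)
  factor(ifelse(mins <= 12 * 60, "am", "pm"), levels = c("am", "pm"))
}

.hm_to_min <- function(hm) {
  parts <- as.numeric(strsplit(hm, ":", fixed = TRUE)[[1]])
  parts[1] * 60 + parts[2]
}

.min_to_hm <- function(mins) {
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}
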