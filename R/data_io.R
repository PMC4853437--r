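#' Read and validate a scan table
#'
#' A scan table holds one row per (scan, individual): the individual's map
#' position at that instant, or a `visible = FALSE` row when the individual
#' was out of sight (in the forest area) during that scan. Positions are
#' continuous metres on the observation grid, origin at the lower-left
#' corner; records digitised to 1-m grid cells should be stored as
#' cell-centre coordinates (cell (5, 3) becomes (5.5, 3.5)).
#'
#' @param path CSV file with columns
#'   `scan_id,date,time,individual,x,y,visible`.
#' @param individuals optional individual table (see [read_individuals()]);
#'   when given, every `individual` id must appear in it.
#' @param grid extent of the square observation area in metres.
#' @return A validated tibble of scan records with a derived `period` column
#'   (`am`/`pm`, noon counted as morning).
#' @seealso [validate_scan_table()] for the rules enforced.
#' @export
read_scan_table <- function(path, individuals = NULL, grid = 30) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      scan_id = readr::col_integer(),
      date = readr::col_date(),
      time = readr::col_character(),
      individual = readr::col_character(),
      x = readr::col_double(),
      y = readr::col_double(),
      visible = readr::col_logical()
    )
  )
  validate_scan_table(raw, individuals = individuals, grid = grid)
}

#' Validate scan records
#'
#' Enforces the recording conventions: at most one row per
#' (scan, individual); visible rows must carry in-bounds coordinates;
#' out-of-sight rows must carry no coordinates; all ids known when an
#' individual table is supplied. Violations raise an error listing the
#' offending rows.
#'
#' @param scans data frame of scan records.
#' @inheritParams read_scan_table
#' @return The scan table as a tibble with a `period` factor column.
#' @export
validate_scan_table <- function(scans, individuals = NULL, grid = 30) {
  scans <- tibble::as_tibble(scans)
  needed <- c("scan_id", "individual", "x", "y", "visible")
  missing_cols <- setdiff(needed, names(scans))
  if (length(missing_cols)) {
    stop("scan table is missing columns: ", paste(missing_cols, collapse = ", "))
  }

  dup <- scans |>
    dplyr::count(.data$scan_id, .data$individual) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop(
      "duplicate (scan, individual) records: ",
      paste(sprintf("scan %s / %s", dup$scan_id, dup$individual), collapse = "; ")
    )
  }

  vis <- dplyr::filter(scans, .data$visible)
  bad <- dplyr::filter(
    vis,
    !is.finite(.data$x) | !is.finite(.data$y) |
      .data$x < 0 | .data$x > grid | .data$y < 0 | .data$y > grid
  )
  if (nrow(bad)) {
    stop(
      "positions outside the ", grid, " x ", grid, " m grid (or missing) in rows: ",
      paste(sprintf("scan %s / %s (x=%s, y=%s)", bad$scan_id, bad$individual, bad$x, bad$y),
            collapse = "; ")
    )
  }
  ghost <- dplyr::filter(scans, !.data$visible, is.finite(.data$x) | is.finite(.data$y))
  if (nrow(ghost)) {
    stop(
      "out-of-sight rows must have empty coordinates: ",
      paste(sprintf("scan %s / %s", ghost$scan_id, ghost$individual), collapse = "; ")
    )
  }

  if (!is.null(individuals)) {
    unknown <- setdiff(unique(scans$individual), individuals$id)
    if (length(unknown)) {
      stop("unknown individual id(s): ", paste(unknown, collapse = ", "))
    }
  }

  if (!"period" %in% names(scans)) {
    if (!"time" %in% names(scans)) stop("scan table needs a 'time' or 'period' column")
    scans$period <- scan_period(scans$time)
  } else {
    scans$period <- factor(as.character(scans$period), levels = c("am", "pm"))
  }
  scans
}

#' Read an agonistic interaction log
#'
#' One row per agonistic event: actor, receiver, an opaque behaviour label
#' (when an event is a behaviour sequence, only the final, submission-causing
#' behaviour is recorded upstream), the number of participants and whether
#' the outcome was clear. Hierarchy construction later keeps only dyadic,
#' clear-outcome events.
#'
#' @param path CSV with columns
#'   `timestamp,actor,receiver,behavior,n_participants,clear_outcome`.
#' @return A validated tibble of agonistic records.
#' @export
read_agonistic_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      actor = readr::col_character(),
      receiver = readr::col_character(),
      behavior = readr::col_character(),
      n_participants = readr::col_integer(),
      clear_outcome = readr::col_logical()
    )
  )
  validate_agonistic_table(raw)
}

#' @rdname read_agonistic_table
#' @param records data frame of agonistic records to validate in place.
#' @export
validate_agonistic_table <- function(records) {
  records <- tibble::as_tibble(records)
  self <- dplyr::filter(records, .data$actor == .data$receiver)
  if (nrow(self)) {
    stop("actor equals receiver in ", nrow(self), " record(s)")
  }
  if (any(records$n_participants < 2)) {
    stop("n_participants must be >= 2")
  }
  records
}

#' Read an individual metadata table
#'
#' @param path CSV with columns `id,sex,birth_date,age,matriline`; `age` in
#'   years (may be empty), `matriline` a maternal-line label (may be empty).
#' @return A tibble with `sex` as a factor (`F`/`M`) and unique ids.
#' @export
read_individuals <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      sex = readr::col_character(),
      birth_date = readr::col_date(),
      age = readr::col_double(),
      matriline = readr::col_character()
    )
  )
  validate_individuals(raw)
}

#' @rdname read_individuals
#' @param individuals data frame of individual metadata to validate in place.
#' @export
validate_individuals <- function(individuals) {
  individuals <- tibble::as_tibble(individuals)
  if (anyDuplicated(individuals$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  }
  if (!all(individuals$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'")
  }
  if (any(individuals$age < 0, na.rm = TRUE)) stop("negative age")
  individuals$sex <- factor(individuals$sex, levels = c("F", "M"))
  individuals
}

#' Exclude juveniles from the study population
#'
#' Individuals younger than `min_age` years are dropped: their positions
#' track their mothers' and their relationships with other group members are
#' unstable, so they are not part of the analysed population. The threshold
#' is inclusive (age exactly `min_age` is retained).
#'
#' @param individuals individual tibble with complete ages (run
#'   [impute_missing_ages()] first if needed).
#' @param min_age minimum age in years, default 5.
#' @return The retained individuals, with the exclusions recorded in the
#'   `"excluded"` attribute.
#' @examples
#' ind <- tibble::tibble(id = c("a", "b", "c"), sex = c("F", "F", "M"),
#'                       age = c(4, 5, 10), matriline = "m1")
#' apply_study_filters(ind)$id  # "b" "c"
#' @export
apply_study_filters <- function(individuals, min_age = 5) {
  if (anyNA(individuals$age)) {
    stop("ages must be complete before filtering; see impute_missing_ages()")
  }
  keep <- individuals$age >= min_age
  if (!any(keep)) stop("no individuals left after the age filter")
  out <- individuals[keep, , drop = FALSE]
  attr(out, "excluded") <- individuals[!keep, , drop = FALSE]
  out
}

#' Impute missing ages by age-class mean
#'
#' Missing ages are replaced by the mean observed age of the individual's
#' age class (subadult vs adult). The class boundary is a convention: ages
#' `subadult_range` (default 5--7 y inclusive) are subadult, older animals
#' adult; individuals missing age are classified by the `age_class` column
#' when present.
#'
#' @param individuals individual tibble; optionally with an `age_class`
#'   column (`"subadult"`/`"adult"`) for individuals whose age is missing.
#' @param subadult_range numeric length-2, inclusive subadult age bounds.
#' @return The tibble with complete `age` and a logical `age_imputed` column.
#' @export
impute_missing_ages <- function(individuals, subadult_range = c(5, 7)) {
  individuals <- tibble::as_tibble(individuals)
  cls <- ifelse(
    !is.na(individuals$age),
    ifelse(individuals$age <= subadult_range[2], "subadult", "adult"),
    if ("age_class" %in% names(individuals)) as.character(individuals$age_class) else NA
  )
  if (anyNA(individuals$age) && anyNA(cls[is.na(individuals$age)])) {
    stop("individuals with missing age need an age_class for imputation")
  }
  class_means <- tapply(individuals$age, cls, mean, na.rm = TRUE)
  miss <- is.na(individuals$age)
  if (any(miss)) {
    fill <- class_means[cls[miss]]
    if (anyNA(fill)) {
      stop("age class with no observed ages: ",
           paste(unique(cls[miss][is.na(fill)]), collapse = ", "))
    }
    individuals$age[miss] <- as.numeric(fill)
  }
  individuals$age_imputed <- miss
  individuals
}

#' Write / read a labelled square matrix as CSV
#'
#' Derived matrices (win counts, association indices, attribute distances)
#' are stored as square CSVs with individual ids as both header and first
#' column, so they round-trip exactly.
#'
#' @param m square matrix with identical row and column names.
#' @param path destination CSV.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), identical(rownames(m), colnames(m)))
  df <- tibble::as_tibble(m, rownames = "id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @return `read_matrix_csv()` returns the labelled matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(id = readr::col_character(),
                                                      .default = readr::col_double()))
  m <- as.matrix(df[-1])
  rownames(m) <- df$id
  stopifnot(identical(rownames(m), colnames(m)))
  m
}

#' Write a scan table to CSV
#'
#' @param scans scan tibble as returned by [read_scan_table()].
#' @param path destination CSV.
#' @export
write_scan_table <- function(scans, path) {
  readr::write_csv(
    scans[, c("scan_id", "date", "time", "individual", "x", "y", "visible")],
    path
  )
  invisible(path)
}
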