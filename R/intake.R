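#' Read a visit-level feeding record file
#'
#' Reads a CSV of feeder visits with columns `animal_id`, `year`,
#' `test_day`, `device_id`, `intake_kg`, `duration_s` (header required)
#' and validates it.
#'
#' @param path Path to the CSV file.
#' @return A data frame of visits with columns `animal_id`, `year`,
#'   `test_day`, `device_id`, `intake`, `duration`.
#' @export
read_visits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "year", "test_day", "device_id", "intake_kg",
            "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("visit file is missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(animal_id = df$animal_id, year = df$year,
                    test_day = as.integer(df$test_day),
                    device_id = df$device_id,
                    intake = as.numeric(df$intake_kg),
                    duration = as.numeric(df$duration_s),
                    stringsAsFactors = FALSE)
  validate_visits(out)
  out
}

validate_visits <- function(visits) {
  if (nrow(visits) == 0L) stop("no visit records")
  bad <- which(!is.finite(visits$intake) | visits$intake < 0)
  if (length(bad) > 0L)
    stop("negative or non-finite intake in visit row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(visits$test_day < 1L)) stop("test_day must be >= 1")
  # an animal belongs to exactly one cohort
  tab <- unique(visits[, c("animal_id", "year")])
  dup <- tab$animal_id[duplicated(tab$animal_id)]
  if (length(dup) > 0L)
    stop("animal(s) appear in more than one year cohort: ",
         paste(utils::head(unique(dup), 5L), collapse = ", "))
  invisible(visits)
}

#' Aggregate feeder visits to daily feed intake
#'
#' Sums all visit intakes within each animal-day to obtain the daily
#' feed intake (DFI).  The device is the modal device of the
#' animal-day's visits.  Animal-days with zero total intake are flagged
#' and excluded from the returned records (a message reports the count):
#' the log-CV machinery downstream assumes positive intake.  Animal-days
#' with no visits at all simply yield no record.
#'
#' @param visits Data frame of visits as returned by [read_visits()].
#' @return Data frame with one row per retained animal-day: columns
#'   `animal_id`, `year`, `test_day`, `device_id`, `dfi` (kg/day).
#' @export
aggregate_visits <- function(visits) {
  validate_visits(visits)
  key <- interaction(visits$animal_id, visits$year, visits$test_day,
                     drop = TRUE, lex.order = TRUE)
  dfi <- tapply(visits$intake, key, sum)
  first <- !duplicated(key)
  meta <- visits[first, c("animal_id", "year", "test_day")]
  meta <- meta[order(key[first]), , drop = FALSE]
  modal_dev <- tapply(as.character(visits$device_id), key, function(d) {
    t <- table(d)
    names(t)[which.max(t)]
  })
  out <- data.frame(animal_id = meta$animal_id, year = meta$year,
                    test_day = meta$test_day,
                    device_id = as.character(modal_dev),
                    dfi = as.numeric(dfi), stringsAsFactors = FALSE)
  out <- out[order(out$year, out$test_day, out$animal_id), , drop = FALSE]
  zero <- out$dfi <= 0
  if (any(zero)) {
    message(sum(zero), " animal-day(s) with zero intake excluded")
    out <- out[!zero, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-day cross-animal variability of daily feed intake
#'
#' For every (year, test day) cell with at least `min_animals` records,
#' computes the cross-animal mean, sample standard deviation (n - 1
#' denominator), coefficient of variation CV = sd/mean and its natural
#' logarithm.  Days with fewer animals or zero variance are excluded
#' with a warning.  The log CV is the quantity on which the challenge
#' mixture model operates: analysing the CV rather than the raw daily
#' variance removes the scale effect of animals growing over the test
#' period.
#'
#' @param records Daily records as returned by [aggregate_visits()]
#'   (columns `animal_id`, `year`, `test_day`, `dfi`).
#' @param min_animals Minimum animals per day (default 10); smaller
#'   days give unstable CV estimates.
#' @return Data frame ordered by (year, test_day) with columns `year`,
#'   `test_day`, `n`, `mean`, `sd`, `cv`, `log_cv`.
#' @export
compute_day_variability <- function(records, min_animals = 10L) {
  if (is.null(records) || nrow(records) == 0L) stop("no daily records")
  if (min_animals < 2L) stop("min_animals must be >= 2")
  if (anyDuplicated(records[, c("animal_id", "year", "test_day")]))
    stop("more than one record per animal-day")
  key <- interaction(records$year, records$test_day, drop = TRUE)
  n <- as.integer(tapply(records$dfi, key, length))
  m <- as.numeric(tapply(records$dfi, key, mean))
  s <- as.numeric(tapply(records$dfi, key, stats::sd))
  first <- !duplicated(key)
  meta <- records[first, c("year", "test_day")]
  meta <- meta[order(key[first]), , drop = FALSE]
  out <- data.frame(year = meta$year, test_day = meta$test_day,
                    n = n, mean = m, sd = s, cv = s / m,
                    log_cv = log(s / m), stringsAsFactors = FALSE)
  small <- out$n < min_animals
  degen <- !small & (out$sd == 0 | !is.finite(out$log_cv))
  if (any(small))
    warning(sum(small), " day(s) excluded with fewer than ", min_animals,
            " animals")
  if (any(degen))
    warning(sum(degen), " degenerate day(s) excluded (zero variance)")
  out <- out[!small & !degen, , drop = FALSE]
  if (nrow(out) == 0L) stop("no usable days")
  out <- out[order(out$year, out$test_day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pre-aggregated daily intake file
#'
#' CSV with columns `animal_id`, `year`, `test_day`, `device_id`,
#' `dfi_kg`.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns as in [aggregate_visits()].
#' @export
read_daily <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "year", "test_day", "device_id", "dfi_kg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("daily file is missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(animal_id = df$animal_id, year = df$year,
                    test_day = as.integer(df$test_day),
                    device_id = df$device_id, dfi = as.numeric(df$dfi_kg),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$dfi) | out$dfi < 0))
    stop("negative or non-finite dfi in daily file")
  out
}

#' Write daily records / day-variability tables
#'
#' Writers for the plain-CSV interchange formats used by the pipeline.
#'
#' @param records,dayvar Data frames as produced by
#'   [aggregate_visits()] and [compute_day_variability()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_daily <- function(records, path) {
  out <- data.frame(animal_id = records$animal_id, year = records$year,
                    test_day = records$test_day,
                    device_id = records$device_id, dfi_kg = records$dfi)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily
#' @export
write_day_variability <- function(dayvar, path) {
  utils::write.csv(dayvar, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily
#' @param path Path of a day-variability CSV written by
#'   [write_day_variability()].
#' @export
read_day_variability <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "test_day", "n", "mean", "sd", "cv", "log_cv")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("day-variability file is missing columns: ",
         paste(miss, collapse = ", "))
  df
}
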