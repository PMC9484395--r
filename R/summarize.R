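#' Minute-of-day behaviour profile with non-wear imputation
#'
#' Converts smoothed 30-s epoch labels into a 1440-minute behaviour
#' profile. Within each calendar day (device-local time), a minute's
#' behaviour fractions are the mean of the one-hot labels of its wear
#' epochs; minutes with no wear epoch on a day are imputed as the mean
#' behaviour in the corresponding minute of the day on the remaining
#' days -- which is exactly the across-valid-day average this function
#' returns. A minute of day never observed on any day is an error (such
#' a participant should already have failed the hourly-coverage quality
#' rule).
#'
#' @param epochs Tibble with `start` (POSIXct epoch start), `label`
#'   (behaviour) and `wear` (logical). Typically smoothed predictions.
#' @return Tibble of class `minute_profile`: `minute` (0-1439), four
#'   behaviour fraction columns summing to 1, and `n_valid_days`.
#' @export
impute_profile <- function(epochs) {
  need <- c("start", "label", "wear")
  if (!all(need %in% names(epochs))) {
    abort("epochs needs columns start, label, wear")
  }
  df <- tibble(
    day = format(epochs$start, "%Y-%m-%d", tz = "UTC"),
    minute = as.integer(format(epochs$start, "%H", tz = "UTC")) * 60L +
      as.integer(format(epochs$start, "%M", tz = "UTC")),
    label = as_behaviour(epochs$label),
    wear = epochs$wear
  )
  wearing <- dplyr::filter(df, .data$wear)
  if (nrow(wearing) == 0) abort("no wear epochs to build a profile from")
  onehot <- as.data.frame(stats::model.matrix(~ label - 1, wearing))
  names(onehot) <- .BEHAVIOURS
  per_day_min <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_cols(wearing[c("day", "minute")], onehot),
                    .data$day, .data$minute),
    dplyr::across(dplyr::all_of(.BEHAVIOURS), mean), .groups = "drop"
  )
  prof <- dplyr::summarise(
    dplyr::group_by(per_day_min, .data$minute),
    dplyr::across(dplyr::all_of(.BEHAVIOURS), mean),
    n_valid_days = dplyr::n(), .groups = "drop"
  )
  missing_min <- setdiff(0:1439, prof$minute)
  if (length(missing_min) > 0) {
    abort(paste0("minute(s) of day never observed: ",
                 paste(head(missing_min, 5), collapse = ", "),
                 if (length(missing_min) > 5) " ..."))
  }
  prof <- dplyr::arrange(prof, .data$minute)
  class(prof) <- c("minute_profile", class(prof))
  prof
}

#' Daily 24-hour behaviour composition from a minute profile
#'
#' Sums each behaviour's minute fractions over the 1440 minutes of the
#' day and converts to hours/day; parts sum to exactly 24.
#'
#' @param profile A [impute_profile()] result.
#' @return Tibble with one row and the four behaviour columns (h/day).
#' @export
daily_composition <- function(profile) {
  if (!all(.BEHAVIOURS %in% names(profile))) {
    abort("profile must contain the four behaviour fraction columns")
  }
  as_tibble(as.list(colSums(as.matrix(profile[, .BEHAVIOURS])) / 60))
}
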