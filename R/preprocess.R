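#' Construct a raw trace object
#'
#' A `raw_trace` is a tibble with columns `time` (POSIXct, strictly
#' increasing), `x`, `y`, `z` (acceleration in g) plus attributes:
#' `sample_rate` (Hz), `dynamic_range` (g) and `interruptions` (a tibble
#' of recording-gap intervals). Gaps are never represented as NA samples;
#' they are explicit intervals.
#'
#' @param df Tibble with `time`, `x`, `y`, `z`.
#' @param sample_rate Nominal sampling rate in Hz.
#' @param dynamic_range Device range in g (default 8).
#' @param interruptions Tibble with `start`, `end` columns (may be empty).
#' @return A `raw_trace` tibble.
#' @export
new_raw_trace <- function(df, sample_rate, dynamic_range = 8,
                          interruptions = NULL) {
  stopifnot(all(c("time", "x", "y", "z") %in% names(df)))
  if (anyNA(df[c("x", "y", "z")])) abort("trace axes must not contain NA")
  out <- as_tibble(df)
  if (is.null(interruptions)) {
    interruptions <- tibble(start = as.POSIXct(character(), tz = "UTC"),
                            end = as.POSIXct(character(), tz = "UTC"))
  }
  attr(out, "sample_rate") <- sample_rate
  attr(out, "dynamic_range") <- dynamic_range
  attr(out, "interruptions") <- interruptions
  class(out) <- c("raw_trace", class(out))
  out
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d samples @ %g Hz, range +/-%g g, %d interruption(s)\n",
              nrow(x), sample_rate(x), attr(x, "dynamic_range"),
              nrow(interruptions(x))))
  NextMethod()
}

#' @export
`[.raw_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("time", "x", "y", "z") %in% names(out))) {
    for (a in c("sample_rate", "dynamic_range", "interruptions",
                "calibrated", "clip_fraction_before")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- unique(c("raw_trace", class(out)))
  }
  out
}

#' Trace metadata accessors
#' @param trace A `raw_trace`.
#' @return `sample_rate()` the sampling rate in Hz; `interruptions()` a
#'   tibble of recording-gap intervals.
#' @export
sample_rate <- function(trace) attr(trace, "sample_rate")

#' @rdname sample_rate
#' @export
interruptions <- function(trace) attr(trace, "interruptions")

#' Read a raw trace from delimited text
#'
#' Expects a CSV with header `time,x,y,z`, ISO-8601 times and axes in g.
#' Timestamps must be strictly increasing. Gaps larger than 1.5 sample
#' intervals are recorded as interruption intervals. If the empirical
#' sampling rate of contiguous samples deviates from the nominal rate by
#' more than 1%, each contiguous segment is linearly interpolated onto a
#' uniform grid at the nominal rate (frequency-domain features assume
#' uniform sampling).
#'
#' @param path CSV file path.
#' @param sample_rate Nominal rate in Hz; inferred from the median sample
#'   interval when `NULL`.
#' @param dynamic_range Device range in g.
#' @return A `raw_trace`.
#' @export
read_trace <- function(path, sample_rate = NULL, dynamic_range = 8) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time = readr::col_datetime(), x = readr::col_double(),
    y = readr::col_double(), z = readr::col_double()
  ), progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("unparseable rows at line(s): ",
                 paste(unique(prob$row), collapse = ", ")))
  }
  if (nrow(df) < 2) abort("trace must contain at least 2 samples")
  dt <- diff(as.numeric(df$time))
  if (any(dt <= 0)) {
    abort(paste0("timestamps not strictly increasing at row(s): ",
                 paste(head(which(dt <= 0) + 1, 10), collapse = ", ")))
  }
  dt_med <- median(dt)
  if (is.null(sample_rate)) sample_rate <- 1 / dt_med
  gap <- which(dt > 1.5 * dt_med)
  inter <- tibble(start = df$time[gap], end = df$time[gap + 1])
  # resample contiguous segments if the empirical rate is off by > 1%
  if (abs(1 / dt_med - sample_rate) / sample_rate > 0.01) {
    seg_id <- cumsum(c(1, as.integer(dt > 1.5 * dt_med)))
    df <- dplyr::group_by(dplyr::mutate(df, .seg = seg_id), .data$.seg)
    df <- dplyr::group_modify(df, function(d, ...) {
      tt <- as.numeric(d$time)
      grid <- seq(tt[1], tt[length(tt)], by = 1 / sample_rate)
      tibble(time = as.POSIXct(grid, tz = "UTC",
                               origin = as.POSIXct("1970-01-01", tz = "UTC")),
             x = approx(tt, d$x, grid)$y,
             y = approx(tt, d$y, grid)$y,
             z = approx(tt, d$z, grid)$y)
    })
    df <- dplyr::select(dplyr::ungroup(df), -".seg")
  }
  new_raw_trace(df, sample_rate = sample_rate, dynamic_range = dynamic_range,
                interruptions = inter)
}

#' Quality-control configuration
#'
#' Thresholds for trace-level quality control: maximum tolerated clipped
#' fraction, the non-wear rule (per-axis SD below `nonwear_sd_mg` for at
#' least `nonwear_min_duration` minutes), the minimum number of wear days,
#' the requirement that every 1-hour bin of the 24-hour cycle contains
#' wear data, and the maximum plausible average acceleration.
#'
#' @param clip_fraction_max Maximum clipped-sample fraction (default 0.01).
#' @param nonwear_sd_mg Non-wear SD threshold in milli-g (default 13).
#' @param nonwear_min_duration Minimum non-wear episode length in minutes
#'   (default 60).
#' @param min_wear_days Minimum wear days (default 3).
#' @param require_all_24_hourly_bins Require wear data in every hour of
#'   day (default TRUE).
#' @param max_mean_acceleration_mg Maximum plausible mean acceleration
#'   (ENMO, milli-g; default 100).
#' @return Object of class `quality_config`.
#' @export
quality_config <- function(clip_fraction_max = 0.01,
                           nonwear_sd_mg = 13,
                           nonwear_min_duration = 60,
                           min_wear_days = 3,
                           require_all_24_hourly_bins = TRUE,
                           max_mean_acceleration_mg = 100) {
  vals <- c(clip_fraction_max, nonwear_sd_mg, nonwear_min_duration,
            min_wear_days, max_mean_acceleration_mg)
  if (any(vals <= 0)) abort("all quality thresholds must be positive")
  structure(list(
    clip_fraction_max = clip_fraction_max,
    nonwear_sd_mg = nonwear_sd_mg,
    nonwear_min_duration = nonwear_min_duration,
    min_wear_days = min_wear_days,
    require_all_24_hourly_bins = require_all_24_hourly_bins,
    max_mean_acceleration_mg = max_mean_acceleration_mg
  ), class = "quality_config")
}

# fraction of samples with any axis at the device limit (0.5 mg tolerance
# for float storage jitter)
clip_fraction <- function(trace) {
  lim <- attr(trace, "dynamic_range") - 5e-4
  mean(abs(trace$x) >= lim | abs(trace$y) >= lim | abs(trace$z) >= lim)
}

# stationary anchor points: means of 10-s blocks whose per-axis SD is
# below sd_mg on every axis
stationary_points <- function(trace, sd_mg = 13) {
  rate <- sample_rate(trace)
  bs <- max(2L, round(10 * rate))
  nb <- floor(nrow(trace) / bs)
  if (nb < 1) return(matrix(numeric(0), 0, 3))
  idx <- rep(seq_len(nb), each = bs)
  m <- as.matrix(trace[seq_len(nb * bs), c("x", "y", "z")])
  mu <- rowsum(m, idx) / bs
  mu2 <- rowsum(m^2, idx) / bs
  sds <- sqrt(pmax((mu2 - mu^2) * bs / (bs - 1), 0))
  keep <- rowSums(sds < sd_mg / 1000) == 3
  mu[keep, , drop = FALSE]
}

#' Autocalibrate a trace to the unit gravity sphere
#'
#' Selects stationary 10-s blocks (per-axis SD < 13 mg), then iteratively
#' fits a per-axis linear gain and offset that moves the stationary
#' points onto the unit sphere (each iteration regresses the points'
#' projections onto the sphere against the current points). Calibration
#' is declared failed when the stationary points do not include both
#' positive and negative values on every axis (insufficient sphere
#' coverage) or when the fitted points do not end up within 3 mg of 1 g
#' on average; the trace is then returned unchanged with
#' `calibrated = FALSE`.
#'
#' @param trace A `raw_trace`.
#' @param sd_mg Stationarity SD threshold in milli-g.
#' @param max_iter Maximum number of refinement iterations.
#' @return List of class `calibration_result`: `trace` (calibrated,
#'   carrying `calibrated` and `clip_fraction_before` attributes), `gain`
#'   and `offset` 3-vectors, and the logical `calibrated`.
#' @export
calibrate_trace <- function(trace, sd_mg = 13, max_iter = 100) {
  stopifnot(inherits(trace, "raw_trace"))
  if (nrow(trace) == 0) abort("trace is empty")
  clip_before <- clip_fraction(trace)
  pts <- stationary_points(trace, sd_mg)
  gain <- c(1, 1, 1)
  offset <- c(0, 0, 0)
  ok <- nrow(pts) >= 10 &&
    all(apply(pts, 2, function(v) min(v) < 0 && max(v) > 0))
  if (ok) {
    cur <- pts
    for (it in seq_len(max_iter)) {
      mag <- sqrt(rowSums(cur^2))
      target <- cur / mag
      g <- numeric(3); o <- numeric(3)
      for (a in 1:3) {
        fitln <- stats::lm.fit(cbind(1, cur[, a]), target[, a])
        o[a] <- fitln$coefficients[1]
        g[a] <- fitln$coefficients[2]
      }
      cur <- sweep(sweep(cur, 2, g, "*"), 2, o, "+")
      gain <- gain * g
      offset <- offset * g + o
      if (max(abs(g - 1)) < 1e-9 && max(abs(o)) < 1e-9) break
    }
    ok <- abs(mean(sqrt(rowSums(cur^2))) - 1) < 0.003
  }
  out <- trace
  if (ok) {
    out$x <- offset[1] + gain[1] * trace$x
    out$y <- offset[2] + gain[2] * trace$y
    out$z <- offset[3] + gain[3] * trace$z
  } else {
    gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  }
  attr(out, "calibrated") <- ok
  attr(out, "clip_fraction_before") <- clip_before
  structure(list(trace = out, gain = gain, offset = offset, calibrated = ok),
            class = "calibration_result")
}

# membership of times in a set of [start, end) intervals
in_intervals <- function(times, intervals) {
  out <- rep(FALSE, length(times))
  if (is.null(intervals) || nrow(intervals) == 0) return(out)
  tn <- as.numeric(times)
  for (i in seq_len(nrow(intervals))) {
    out <- out | (tn >= as.numeric(intervals$start[i]) &
                    tn < as.numeric(intervals$end[i]))
  }
  out
}

#' Detect non-wear episodes
#'
#' Scans rolling 60-minute windows stepping by 1 minute; a window
#' qualifies when the SD of every axis over the window is below the
#' threshold (13 mg by default) and the window is fully covered by
#' samples. A non-wear episode is the union of overlapping qualifying
#' windows, so every episode is at least `nonwear_min_duration` long and
#' maximal.
#'
#' @param trace A `raw_trace` (calibrated).
#' @param config A [quality_config()].
#' @return Tibble with `start`, `end` (POSIXct) and `duration_min`.
#' @export
detect_nonwear <- function(trace, config = quality_config()) {
  stopifnot(inherits(trace, "raw_trace"))
  t0 <- as.numeric(trace$time[1])
  minute <- floor((as.numeric(trace$time) - t0) / 60)
  n_min <- max(minute) + 1
  m <- as.matrix(trace[, c("x", "y", "z")])
  cnt <- tabulate(minute + 1, nbins = n_min)
  # per-minute sums with explicit zero rows for minutes inside gaps
  fill <- function(g) {
    out <- matrix(0, n_min, 3)
    out[as.integer(rownames(g)) + 1, ] <- g
    out
  }
  s1 <- fill(rowsum(m, minute))
  s2 <- fill(rowsum(m^2, minute))
  w <- config$nonwear_min_duration
  if (n_min < w) {
    return(tibble(start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  duration_min = numeric()))
  }
  # windowed sums over w consecutive minutes via cumulative sums
  csum <- function(v) {
    cs <- c(0, cumsum(v))
    cs[(w + 1):(n_min + 1)] - cs[1:(n_min - w + 1)]
  }
  Wn <- csum(cnt)
  full <- Wn >= w * max(1, floor(sample_rate(trace) * 60 * 0.9))  # near-full coverage
  qual <- full
  for (a in 1:3) {
    S <- csum(s1[, a]); SS <- csum(s2[, a])
    v <- pmax(0, (SS - S^2 / Wn) / pmax(Wn - 1, 1))
    qual <- qual & sqrt(v) < config$nonwear_sd_mg / 1000
  }
  if (!any(qual)) {
    return(tibble(start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  duration_min = numeric()))
  }
  # union of qualifying windows [i, i + w)
  starts <- which(qual) - 1
  cover <- rep(FALSE, n_min)
  for (s in starts) cover[(s + 1):(s + w)] <- TRUE
  r <- rle(cover)
  ends_idx <- cumsum(r$lengths)
  begins_idx <- ends_idx - r$lengths + 1
  keep <- which(r$values)
  origin <- trace$time[1]
  tibble(
    start = origin + (begins_idx[keep] - 1) * 60,
    end = origin + ends_idx[keep] * 60,
    duration_min = r$lengths[keep]
  )
}

#' Trace-level quality report
#'
#' Applies the inclusion rules: clipped fraction at most 1% before and
#' after calibration, at least 3 days of wear, wear data in every 1-hour
#' bin of the 24-hour cycle, mean acceleration no more than 100 mg, and
#' successful calibration. All violated rules are reported, regardless of
#' order.
#'
#' @param trace A calibrated `raw_trace` (from [calibrate_trace()]).
#' @param nonwear Non-wear intervals from [detect_nonwear()].
#' @param config A [quality_config()].
#' @return Object of class `quality_report`: flags, measured quantities,
#'   `included` and `exclusion_reasons`.
#' @export
quality_check <- function(trace, nonwear = NULL, config = quality_config()) {
  stopifnot(inherits(trace, "raw_trace"))
  if (is.null(nonwear)) nonwear <- detect_nonwear(trace, config)
  calibrated <- isTRUE(attr(trace, "calibrated"))
  clip_before <- attr(trace, "clip_fraction_before")
  if (is.null(clip_before)) clip_before <- clip_fraction(trace)
  clip_after <- clip_fraction(trace)
  nw <- in_intervals(trace$time, nonwear)
  wear <- !nw
  rate <- sample_rate(trace)
  wear_days <- sum(wear) / rate / 86400
  hour <- as.integer(format(trace$time, "%H", tz = "UTC"))
  hourly <- vapply(0:23, function(h) any(wear & hour == h), logical(1))
  mag <- sqrt(trace$x^2 + trace$y^2 + trace$z^2)
  mean_acc_mg <- mean(pmax(mag[wear] - 1, 0)) * 1000
  reasons <- character()
  if (clip_before > config$clip_fraction_max ||
      clip_after > config$clip_fraction_max) reasons <- c(reasons, "clipping")
  if (wear_days < config$min_wear_days) reasons <- c(reasons, "insufficient wear days")
  if (config$require_all_24_hourly_bins && !all(hourly)) {
    reasons <- c(reasons, "missing hourly coverage")
  }
  if (is.finite(mean_acc_mg) && mean_acc_mg > config$max_mean_acceleration_mg) {
    reasons <- c(reasons, "implausible mean acceleration")
  }
  if (!calibrated) reasons <- c(reasons, "calibration failure")
  structure(list(
    calibrated = calibrated,
    clip_fraction_before = clip_before,
    clip_fraction_after = clip_after,
    wear_days = wear_days,
    hourly_coverage = setNames(hourly, sprintf("%02d", 0:23)),
    mean_acceleration_mg = mean_acc_mg,
    included = length(reasons) == 0,
    exclusion_reasons = reasons
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> included: %s\n", x$included))
  cat(sprintf("  wear days %.2f | mean acc %.1f mg | clip %.3f%%/%.3f%% | calibrated %s\n",
              x$wear_days, x$mean_acceleration_mg,
              100 * x$clip_fraction_before, 100 * x$clip_fraction_after,
              x$calibrated))
  if (length(x$exclusion_reasons)) {
    cat("  reasons:", paste(x$exclusion_reasons, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Serialise a quality report to JSON
#'
#' @param report A [quality_check()] result.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @export
quality_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "quality_report"))
  x <- unclass(report)
  x$hourly_coverage <- as.list(x$hourly_coverage)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
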