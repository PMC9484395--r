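#' Per-behaviour signal model
#'
#' Parameters of the tri-axial signal generator for each behaviour. The
#' model for an epoch of behaviour b is, per axis,
#' gravity + movement + noise: a slowly re-orienting unit gravity vector,
#' a sinusoid of amplitude `amplitude_g` at `frequency_hz` along a
#' per-bout movement direction (aperiodic jitter when `frequency_hz = 0`),
#' and white noise with `noise_sd_g`.
#'
#' @param params Data frame with one row per behaviour (canonical order)
#'   and columns `amplitude_g`, `frequency_hz`, `noise_sd_g`,
#'   `drift_rad_min` (orientation random-walk rate) and `orient_x/y/z`
#'   (baseline gravity orientation, normalised internally).
#' @param randomize_orientation Draw a fresh uniform orientation at each
#'   bout start (default) rather than starting every bout at the baseline
#'   orientation; wearers re-position their wrist between bouts, and the
#'   resulting sphere coverage is what makes autocalibration feasible.
#' @param bout_sdlog Lognormal SD of a per-bout intensity factor applied
#'   to the amplitude and noise SD (0 disables). Free-living bouts of the
#'   same behaviour differ in vigour; without this heterogeneity the
#'   classes separate unrealistically cleanly.
#' @param freq_jitter Relative half-width of the uniform per-bout jitter
#'   on the dominant frequency (0 disables).
#' @return Object of class `signal_model`.
#' @export
signal_model <- function(params, randomize_orientation = TRUE,
                         bout_sdlog = 0, freq_jitter = 0) {
  need <- c("amplitude_g", "frequency_hz", "noise_sd_g", "drift_rad_min",
            "orient_x", "orient_y", "orient_z")
  if (!all(need %in% names(params)) || nrow(params) != 4) {
    abort("params must have 4 rows (canonical behaviour order) and columns: ",
          paste(need, collapse = ", "))
  }
  if (any(params$amplitude_g < 0) || any(params$noise_sd_g < 0)) {
    abort("amplitudes and noise SDs must be non-negative")
  }
  o <- as.matrix(params[, c("orient_x", "orient_y", "orient_z")])
  o <- o / sqrt(rowSums(o^2))
  params[, c("orient_x", "orient_y", "orient_z")] <- o
  structure(list(params = as_tibble(params),
                 behaviours = .BEHAVIOURS,
                 randomize_orientation = randomize_orientation,
                 bout_sdlog = bout_sdlog,
                 freq_jitter = freq_jitter),
            class = "signal_model")
}

#' Default signal model preset
#'
#' Amplitudes are ordered MVPA > LIPA > SB > sleep so that magnitude
#' statistics separate the classes; LIPA and MVPA carry dominant
#' frequencies near typical walking/running cadence so frequency-domain
#' features are informative too.
#'
#' @inheritParams signal_model
#' @return A [signal_model()].
#' @export
default_signal_model <- function(randomize_orientation = TRUE,
                                 bout_sdlog = 0.35, freq_jitter = 0.2) {
  signal_model(tibble(
    behaviour    = .BEHAVIOURS,
    amplitude_g  = c(0.000, 0.030, 0.150, 0.600),
    frequency_hz = c(0.0,   0.0,   1.0,   2.0),
    noise_sd_g   = c(0.005, 0.012, 0.040, 0.090),
    drift_rad_min = c(0.050, 0.060, 0.300, 0.600),
    orient_x = c(0, 1, 0.5, 0.5),
    orient_y = c(0, 0, 0.5, -0.5),
    orient_z = c(1, 0, 0.7071, 0.7071)
  ), randomize_orientation = randomize_orientation,
  bout_sdlog = bout_sdlog, freq_jitter = freq_jitter)
}

# rotate vector v about unit axis u by angle a (Rodrigues)
rotate_about <- function(v, u, a) {
  v * cos(a) + pracma_cross(u, v) * sin(a) + u * sum(u * v) * (1 - cos(a))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate a raw tri-axial trace from a behaviour label sequence
#'
#' Generates acceleration in gravity units (g) for each 30-s epoch of the
#' label sequence under the per-behaviour [signal_model()]. The gravity
#' component is a unit vector that performs a small random walk on the
#' sphere (rate `drift_rad_min`) and is re-drawn at bout boundaries when
#' `randomize_orientation` is set; with zero noise and zero amplitude the
#' vector magnitude of every sample is exactly 1 g.
#'
#' @param labels Tibble from [simulate_behaviour_sequence()] or a factor /
#'   character vector of per-epoch behaviours.
#' @param model A [signal_model()].
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @param seed Integer seed.
#' @param start_time Timestamp of the first sample.
#' @param dynamic_range Device range in g (values are clipped to this).
#' @return A `raw_trace` tibble with columns `time`, `x`, `y`, `z` and
#'   attributes `sample_rate` and `dynamic_range`.
#' @export
simulate_trace <- function(labels, model = default_signal_model(),
                           sample_rate = 20, seed = 1,
                           start_time = NULL, dynamic_range = 8) {
  stopifnot(inherits(model, "signal_model"))
  if (sample_rate <= 0) abort("sample_rate must be positive")
  if (is.data.frame(labels)) {
    if (is.null(start_time)) start_time <- labels$time[1]
    labels <- labels$behaviour
  }
  labels <- as_behaviour(labels)
  if (length(labels) == 0) abort("label sequence is empty")
  if (is.null(start_time)) start_time <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

  n_ep <- length(labels)
  spe <- round(30 * sample_rate)        # samples per epoch
  if (spe < 1) abort("sample_rate too low for 30-s epochs")
  n <- n_ep * spe
  acc <- matrix(0, n, 3)
  pars <- model$params
  withr::with_seed(seed, {
    grav <- random_unit_vector()
    mdir <- random_unit_vector()
    phase <- runif(1, 0, 2 * pi)
    prev <- NA
    tt <- seq(0, by = 1 / sample_rate, length.out = spe)
    for (e in seq_len(n_ep)) {
      b <- as.integer(labels[e])
      p <- pars[b, ]
      if (!identical(b, prev)) {
        # bout boundary: new orientation, movement direction, phase and
        # per-bout intensity / cadence
        grav <- if (model$randomize_orientation) random_unit_vector() else
          as.numeric(p[, c("orient_x", "orient_y", "orient_z")])
        # movement direction biased toward gravity: rhythmic movement
        # modulates the vector magnitude at its fundamental frequency
        mdir <- grav + 0.5 * random_unit_vector()
        mdir <- mdir / sqrt(sum(mdir^2))
        phase <- runif(1, 0, 2 * pi)
        intensity <- if (model$bout_sdlog > 0) exp(rnorm(1, 0, model$bout_sdlog)) else 1
        fj <- if (model$freq_jitter > 0) runif(1, 1 - model$freq_jitter,
                                               1 + model$freq_jitter) else 1
        prev <- b
      } else {
        # orientation drift: one small random rotation per epoch
        a <- rnorm(1, 0, p$drift_rad_min * 0.5)
        grav <- rotate_about(grav, random_unit_vector(), a)
        grav <- grav / sqrt(sum(grav^2))
      }
      amp <- p$amplitude_g * intensity
      nsd <- p$noise_sd_g * intensity
      move <- if (amp == 0) {
        numeric(spe)
      } else if (p$frequency_hz > 0) {
        amp * sin(2 * pi * p$frequency_hz * fj * tt + phase)
      } else {
        amp * rnorm(spe)   # aperiodic movement
      }
      blk <- matrix(grav, spe, 3, byrow = TRUE) +
        outer(move, mdir) +
        if (nsd > 0) matrix(rnorm(spe * 3, 0, nsd), spe, 3) else 0
      acc[(e - 1) * spe + seq_len(spe), ] <- blk
    }
  })
  acc[acc > dynamic_range] <- dynamic_range
  acc[acc < -dynamic_range] <- -dynamic_range
  out <- tibble(
    time = start_time + (seq_len(n) - 1) / sample_rate,
    x = acc[, 1], y = acc[, 2], z = acc[, 3]
  )
  new_raw_trace(out, sample_rate = sample_rate, dynamic_range = dynamic_range)
}

#' Write / read a trace as delimited text
#'
#' The on-disk format is a CSV with header `time,x,y,z`; `time` is
#' ISO-8601 UTC and the axes are in g.
#'
#' @param trace A `raw_trace` tibble.
#' @param path Output file.
#' @return `write_trace` returns `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- dplyr::mutate(as_tibble(trace),
                      time = format(.data$time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"))
  readr::write_csv(df, path)
  invisible(path)
}

#' Write per-epoch behaviour labels as delimited text
#'
#' @param labels Tibble from [simulate_behaviour_sequence()].
#' @param path Output file.
#' @export
write_labels <- function(labels, path) {
  df <- dplyr::mutate(labels,
                      time = format(.data$time, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  readr::write_csv(df, path)
  invisible(path)
}
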