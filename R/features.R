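#' Feature catalogue
#'
#' The package computes a fixed, versioned set of 50 rotation-invariant
#' features per 30-s epoch. All features are functions of the vector
#' magnitude series, of the angles between consecutive sample vectors, or
#' of neighbouring-epoch magnitude summaries -- quantities unchanged by
#' any fixed 3-D rotation of the axes, so rotation invariance holds by
#' construction. The `ordering_sensitive` tag marks features that depend
#' on the time ordering of samples within the epoch (differences,
#' autocorrelation, zero crossings, spectral and angle features); moment
#' and percentile features are invariant to within-epoch permutation.
#'
#' @return Tibble with columns `feature`, `domain` (`time`, `frequency`,
#'   `orientation`, `context`) and `ordering_sensitive`.
#' @export
feature_info <- function() {
  tibble(
    feature = c(
      "mag_mean", "mag_sd", "mag_skew", "mag_kurt", "mag_min", "mag_max",
      "mag_range", "mag_mad", "enmo_mean", "enmo_sd",
      paste0("mag_p", c("01", "05", "10", "25", "50", "75", "90", "95", "99")),
      "mag_iqr", "mean_abs_diff", "max_abs_diff", "sd_diff",
      "autocorr_1s", "autocorr_2s", "autocorr_5s",
      "zero_cross_rate", "mag_power", "mag_rms",
      "dom_freq", "dom_power", "dom_power_rel", "dom2_freq", "dom2_power",
      "band_0.3_1", "band_1_3", "band_3_5", "band_5_8",
      "band_0.3_1_rel", "band_1_3_rel", "band_3_5_rel", "band_5_8_rel",
      "spectral_entropy", "spectral_centroid", "spectral_spread",
      "angle_mean", "angle_sd",
      "prev_mag_mean", "next_mag_mean", "neighbour_contrast"
    ),
    domain = c(
      rep("time", 10), rep("time", 9), rep("time", 10),
      rep("frequency", 16),
      rep("orientation", 2),
      rep("context", 3)
    ),
    ordering_sensitive = c(
      rep(FALSE, 10), rep(FALSE, 9),
      # iqr, diffs, autocorrs, zcr, power, rms
      FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
      rep(TRUE, 16),
      TRUE, TRUE,
      rep(FALSE, 3)
    )
  )
}

#' Names of the 50 epoch features
#' @return Character vector of length 50.
#' @export
feature_names <- function() feature_info()$feature

#' Extract the 50 rotation-invariant features from one epoch
#'
#' @param samples Numeric matrix (n x 3) of acceleration samples in g.
#' @param sample_rate Sampling rate in Hz.
#' @param prev_mag_mean,next_mag_mean Magnitude means of the neighbouring
#'   epochs; defaults to this epoch's own mean at sequence boundaries.
#' @return Named numeric vector of length 50. Degenerate inputs take
#'   documented sentinels: autocorrelation and spectral entropy of a
#'   constant signal are 0 and its dominant frequency is 0 Hz.
#' @export
extract_features <- function(samples, sample_rate,
                             prev_mag_mean = NULL, next_mag_mean = NULL) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2 * sample_rate) abort("an epoch needs at least 2 s of samples")
  v <- sqrt(rowSums(samples^2))
  mu <- mean(v); s <- sd(v)
  ctr <- v - mu
  skew <- if (s > 0) mean(ctr^3) / s^3 else 0
  kurt <- if (s > 0) mean(ctr^4) / s^4 - 3 else 0
  enmo <- pmax(v - 1, 0)
  qs <- quantile(v, c(.01, .05, .10, .25, .50, .75, .90, .95, .99),
                 names = FALSE, type = 7)
  d <- diff(v)
  ac <- function(lag_s) {
    l <- round(lag_s * sample_rate)
    if (l < 1 || l >= n - 1 || s == 0) return(0)
    r <- suppressWarnings(cor(v[1:(n - l)], v[(l + 1):n]))
    if (is.na(r)) 0 else r
  }
  zc <- if (n > 1) sum(ctr[-n] * ctr[-1] < 0) / (n / sample_rate) else 0

  # frequency domain: Hann-windowed FFT of the demeaned magnitude
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  sp <- Mod(fft(ctr * w))^2
  nf <- floor(n / 2)
  freqs <- (1:nf) * sample_rate / n
  p <- sp[2:(nf + 1)]
  ptot <- sum(p)
  if (ptot > 0) {
    prel <- p / ptot
    i1 <- which.max(p)
    dom_freq <- freqs[i1]; dom_power <- p[i1]; dom_rel <- prel[i1]
    p2 <- p; p2[i1] <- -Inf
    i2 <- if (nf > 1) which.max(p2) else i1
    dom2_freq <- freqs[i2]; dom2_power <- max(p[i2], 0)
    ent <- -sum(prel[prel > 0] * log(prel[prel > 0]))
    cen <- sum(freqs * prel)
    spr <- sqrt(sum(prel * (freqs - cen)^2))
    band <- function(lo, hi) sum(p[freqs >= lo & freqs < hi])
    b <- c(band(0.3, 1), band(1, 3), band(3, 5), band(5, 8))
    brel <- b / ptot
  } else {
    dom_freq <- 0; dom_power <- 0; dom_rel <- 0
    dom2_freq <- 0; dom2_power <- 0
    ent <- 0; cen <- 0; spr <- 0
    b <- c(0, 0, 0, 0); brel <- b
  }

  # orientation dispersion: angle between consecutive sample vectors
  nrm <- v[-n] * v[-1]
  dots <- rowSums(samples[-n, , drop = FALSE] * samples[-1, , drop = FALSE])
  cosang <- ifelse(nrm > 0, pmin(1, pmax(-1, dots / nrm)), 1)
  ang <- acos(cosang)

  pm <- if (is.null(prev_mag_mean) || is.na(prev_mag_mean)) mu else prev_mag_mean
  nm <- if (is.null(next_mag_mean) || is.na(next_mag_mean)) mu else next_mag_mean

  setNames(c(
    mu, s, skew, kurt, min(v), max(v), max(v) - min(v),
    median(abs(v - median(v))), mean(enmo), sd(enmo),
    qs, qs[6] - qs[4],
    mean(abs(d)), max(abs(d)), if (length(d) > 1) sd(d) else 0,
    ac(1), ac(2), ac(5),
    zc, mean(v^2), sqrt(mean(v^2)),
    dom_freq, dom_power, dom_rel, dom2_freq, dom2_power,
    b, brel, ent, cen, spr,
    mean(ang), if (length(ang) > 1) sd(ang) else 0,
    pm, nm, mu - (pm + nm) / 2
  ), feature_names())
}

#' Segment a trace into non-overlapping 30-s epochs
#'
#' Epochs are aligned to the trace start; a trailing partial epoch is
#' dropped. Epochs overlapping a non-wear interval or a recording
#' interruption are flagged `wear = FALSE`.
#'
#' @param trace A `raw_trace`.
#' @param epoch_length Epoch length in seconds (default 30); must be a
#'   positive multiple of the sample interval.
#' @param nonwear Optional non-wear intervals from [detect_nonwear()].
#' @return Tibble with `epoch`, `start`, `wear` and list-column `rows`
#'   giving each epoch's sample row range (start, length).
#' @export
make_epochs <- function(trace, epoch_length = 30, nonwear = NULL) {
  stopifnot(inherits(trace, "raw_trace"))
  rate <- sample_rate(trace)
  spe <- epoch_length * rate
  if (epoch_length <= 0 || abs(spe - round(spe)) > 1e-8) {
    abort("epoch_length must be a positive multiple of the sample interval")
  }
  spe <- as.integer(round(spe))
  t0 <- as.numeric(trace$time[1])
  rel <- as.numeric(trace$time) - t0
  ep <- floor(rel / epoch_length)
  n_ep <- floor((max(rel) + 1 / rate) / epoch_length)
  if (n_ep < 1) abort("trace shorter than one epoch")
  ints <- interruptions(trace)
  starts <- trace$time[1] + epoch_length * (0:(n_ep - 1))
  cnt <- tabulate(ep + 1, nbins = n_ep)
  wear <- cnt == spe
  bad_iv <- dplyr::bind_rows(ints, if (!is.null(nonwear)) nonwear[c("start", "end")])
  if (nrow(bad_iv) > 0) {
    es <- as.numeric(starts); ee <- es + epoch_length
    for (i in seq_len(nrow(bad_iv))) {
      wear <- wear & !(es < as.numeric(bad_iv$end[i]) &
                         ee > as.numeric(bad_iv$start[i]))
    }
  }
  first_row <- match(0:(n_ep - 1), ep)
  tibble(
    epoch = seq_len(n_ep),
    start = starts,
    wear = wear,
    rows = purrr::map2(first_row, cnt, function(f, k) c(f, k))
  )
}

#' Per-epoch feature frame for a whole trace
#'
#' Segments the trace with [make_epochs()] and computes the 50 features
#' for every wear epoch (features of non-wear epochs are NA). Optionally
#' attaches true behaviour labels.
#'
#' @inheritParams make_epochs
#' @param labels Optional per-epoch behaviour labels (vector or tibble
#'   from [simulate_behaviour_sequence()]); recycled checks apply.
#' @return Tibble: `epoch`, `start`, `wear`, optional `truth`, and the 50
#'   feature columns.
#' @export
epoch_features <- function(trace, epoch_length = 30, nonwear = NULL,
                           labels = NULL) {
  eps <- make_epochs(trace, epoch_length, nonwear)
  rate <- sample_rate(trace)
  m <- as.matrix(trace[, c("x", "y", "z")])
  n_ep <- nrow(eps)
  # first pass: epoch magnitude means for the neighbour-context features
  mag_means <- vapply(seq_len(n_ep), function(i) {
    r <- eps$rows[[i]]
    if (!eps$wear[i] || r[2] < 2) return(NA_real_)
    blk <- m[r[1]:(r[1] + r[2] - 1), , drop = FALSE]
    mean(sqrt(rowSums(blk^2)))
  }, numeric(1))
  feat <- matrix(NA_real_, n_ep, 50, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n_ep)) {
    if (!eps$wear[i]) next
    r <- eps$rows[[i]]
    blk <- m[r[1]:(r[1] + r[2] - 1), , drop = FALSE]
    feat[i, ] <- extract_features(
      blk, rate,
      prev_mag_mean = if (i > 1) mag_means[i - 1] else NA,
      next_mag_mean = if (i < n_ep) mag_means[i + 1] else NA
    )
  }
  out <- dplyr::bind_cols(eps[c("epoch", "start", "wear")],
                          as_tibble(as.data.frame(feat)))
  if (!is.null(labels)) {
    if (is.data.frame(labels)) labels <- labels$behaviour
    labels <- as_behaviour(labels)
    if (length(labels) < n_ep) {
      abort("fewer labels than epochs")
    }
    out$truth <- labels[seq_len(n_ep)]
  }
  out
}
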