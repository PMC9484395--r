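# Shared fixtures, generated once per test run and cached.
# Problem sizes are scaled so the whole suite stays fast: multi-participant
# classification data use 8-hour days at 10 Hz; quality-control fixtures use
# a 7-day trace at 5 Hz.

.wc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .wc_cache)) {
    assign(key, force(expr), envir = .wc_cache)
  }
  get(key, envir = .wc_cache)
}

# one labelled participant-day: trace -> features, with truth attached
make_participant_epochs <- function(i, hours = 8, rate = 10) {
  labs <- simulate_behaviour_sequence(default_bout_model(), hours * 60,
                                      seed = 100 + i)
  tr <- simulate_trace(labs, sample_rate = rate, seed = 200 + i)
  ef <- epoch_features(tr, labels = labs)
  ef$participant <- paste0("p", i)
  ef[ef$wear, ]
}

# 10 labelled participants for forest / LOOCV tests
loocv_dataset <- function() {
  cached("loocv_dataset", dplyr::bind_rows(lapply(1:10, make_participant_epochs)))
}

loocv_result_cached <- function() {
  cached("loocv_result", loocv(loocv_dataset(), seed = 3))
}

# clean 7-day trace passing every quality rule
clean_week_trace <- function() {
  cached("clean_week_trace", {
    labs <- simulate_behaviour_sequence(default_bout_model(), 7 * 24 * 60,
                                        seed = 11)
    simulate_trace(labs, sample_rate = 5, seed = 12)
  })
}

# overwrite [start_min, start_min + dur_min) with a constant orientation
inject_still_block <- function(tr, start_min, dur_min) {
  rel <- as.numeric(tr$time - tr$time[1], units = "mins")
  i <- rel >= start_min & rel < start_min + dur_min
  tr$x[i] <- 0.57; tr$y[i] <- -0.31; tr$z[i] <- 0.76
  tr
}

# quick labelled feature frame with a single informative feature, for
# forest unit tests that do not need the signal pipeline
toy_feature_frame <- function(n_per_class, classes = c("sleep", "MVPA"),
                              separation = 5, seed = 42) {
  withr::with_seed(seed, {
    n <- n_per_class * length(classes)
    m <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, feature_names()))
    truth <- rep(classes, each = n_per_class)
    m[, "mag_mean"] <- rnorm(n) + separation * (as.integer(factor(truth, levels = classes)) - 1)
    out <- tibble::as_tibble(as.data.frame(m))
    out$truth <- truth
    out
  })
}

# hand-rolled HMM parameters for decoder tests
toy_hmm <- function(A, B, prior = rep(0.25, 4)) {
  k <- behaviour_levels()
  dimnames(A) <- list(k, k); dimnames(B) <- list(k, k)
  structure(list(prior = stats::setNames(prior, k), A = A, B = B,
                 epsilon = 0, classes = k),
            class = "hmm_params")
}

random_hmm <- function() {
  norm <- function(m) m / rowSums(m)
  toy_hmm(A = norm(matrix(runif(16, 0.05, 1), 4)),
          B = norm(matrix(runif(16, 0.05, 1), 4)),
          prior = {p <- runif(4, 0.05, 1); p / sum(p)})
}
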