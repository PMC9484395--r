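test_that("perfectly separable classes give perfect OOB accuracy", {
  dat <- toy_feature_frame(60, c("sleep", "MVPA"), separation = 8)
  m <- train_balanced_forest(dat, seed = 1)
  expect_equal(mean(m$oob == dat$truth), 1)
  expect_equal(m$n_trees, 100)
  expect_equal(m$bootstrap_per_class, 60)
})

test_that("shuffled labels give chance-level OOB accuracy", {
  dat <- toy_feature_frame(100, behaviour_levels(), separation = 6)
  dat$truth <- withr::with_seed(7, sample(dat$truth))
  m <- train_balanced_forest(dat, seed = 2)
  acc <- mean(m$oob == dat$truth)
  se <- sqrt(0.25 * 0.75 / nrow(dat))
  expect_lt(abs(acc - 0.25), 3 * se)
})

test_that("the forest separates the synthetic behaviour presets", {
  dat <- loocv_dataset()
  m <- train_balanced_forest(dat, seed = 1, classes = behaviour_levels())
  expect_gt(mean(m$oob == dat$truth), 0.85)
})

test_that("training rejects empty classes and too few classes", {
  dat <- toy_feature_frame(30, c("sleep", "SB"))
  expect_error(train_balanced_forest(dat, classes = behaviour_levels()),
               "MVPA")
  one <- dat[dat$truth == "sleep", ]
  expect_error(train_balanced_forest(one), "2 classes")
})

test_that("prediction is deterministic, normalised and manifest-checked", {
  dat <- toy_feature_frame(60, c("sleep", "MVPA"), separation = 8)
  m <- train_balanced_forest(dat, seed = 1)
  # training accuracy is at least OOB accuracy (optimism inequality)
  pr <- predict(m, dat)
  expect_gte(mean(pr$pred == dat$truth), mean(m$oob == dat$truth))
  # duplicated epoch -> identical predictions
  dup <- dat[rep(1, 10), ]
  prd <- predict(m, dup)
  expect_equal(length(unique(prd$pred)), 1)
  # vote fractions sum to one
  votes <- as.matrix(pr[, grep("^vote_", names(pr))])
  expect_true(all(abs(rowSums(votes) - 1) < 1e-9))
  # manifest mismatch is an informative error
  broken <- dat[, setdiff(names(dat), "mag_mean")]
  expect_error(predict(m, broken), "mag_mean")
})

test_that("HMM counts match hand enumeration on a toy sequence", {
  truth <- c("sleep", "sleep", "SB", "SB", "LIPA", "LIPA", "MVPA", "SB", "sleep", "sleep")
  oob   <- c("sleep", "SB",    "SB", "SB", "LIPA", "MVPA", "MVPA", "SB", "sleep", "sleep")
  h <- estimate_hmm(truth, oob, epsilon = 1e-4)
  # hand-counted transitions: sleep->sleep 2, sleep->SB 1, SB->SB 1,
  # SB->LIPA 1, SB->sleep 1, LIPA->LIPA 1, LIPA->MVPA 1, MVPA->SB 1
  A_hand <- matrix(c(2, 1, 0, 0,
                     1, 1, 1, 0,
                     0, 0, 1, 1,
                     0, 1, 0, 0), 4, 4, byrow = TRUE)
  expect_equal(unclass(h$A_counts), A_hand, ignore_attr = TRUE)
  B_hand <- matrix(c(3, 1, 0, 0,
                     0, 3, 0, 0,
                     0, 0, 1, 1,
                     0, 0, 0, 1), 4, 4, byrow = TRUE)
  expect_equal(unclass(h$B_counts), B_hand, ignore_attr = TRUE)
  expect_equal(as.numeric(h$prior), c(4, 3, 2, 1) / 10)
  # floored rows still sum to one
  expect_true(all(abs(rowSums(h$A) - 1) < 1e-12))
  expect_true(all(abs(rowSums(h$B) - 1) < 1e-12))
  expect_true(all(h$A >= 1e-4 / 2))
})

test_that("absorbing truth and perfect predictions give degenerate counts", {
  truth <- rep("sleep", 5)
  h <- estimate_hmm(c(truth, "SB", "LIPA", "MVPA"),
                    c(truth, "SB", "LIPA", "MVPA"))
  expect_equal(unname(h$A_counts["sleep", ]), c(4, 1, 0, 0))
  expect_equal(unname(diag(h$B_counts)), c(5, 1, 1, 1))
  expect_error(estimate_hmm(rep("sleep", 4), rep("sleep", 4)), "absent")
})

test_that("identity emissions make Viterbi a pass-through", {
  A <- matrix(0.05, 4, 4); diag(A) <- 0.85
  B <- matrix(1e-4, 4, 4); diag(B) <- 1 - 3e-4
  h <- toy_hmm(A, B)
  obs <- c("sleep", "SB", "SB", "MVPA", "LIPA", "sleep")
  expect_equal(as.character(viterbi_smooth(obs, h)), obs)
})

test_that("Viterbi matches exhaustive enumeration on short sequences", {
  withr::with_seed(123, {
    for (i in 1:40) {
      n <- sample(2:8, 1)
      h <- random_hmm()
      obs <- sample(behaviour_levels(), n, replace = TRUE)
      opt <- brute_force_viterbi(obs, h)
      v <- as.character(viterbi_smooth(obs, h))
      if (nrow(opt) == 1) {
        expect_equal(v, unname(opt[1, ]))
      } else {
        expect_true(is_optimal_path(v, obs, h))
      }
    }
  })
})

test_that("smoothing removes an isolated spike under sticky transitions", {
  A <- matrix(0.01, 4, 4); diag(A) <- 0.97
  B <- matrix(0.05, 4, 4); diag(B) <- 0.85
  h <- toy_hmm(A, B)
  obs <- c(rep("sleep", 10), "MVPA", rep("sleep", 10))
  sm <- viterbi_smooth(obs, h)
  expect_true(all(sm == "sleep"))
})

test_that("smoothed paths never lose log-likelihood against the raw path", {
  withr::with_seed(31, {
    for (i in 1:20) {
      h <- random_hmm()
      obs <- sample(behaviour_levels(), 30, replace = TRUE)
      sm <- viterbi_smooth(obs, h)
      expect_gte(path_loglik(sm, obs, h), path_loglik(obs, obs, h) - 1e-12)
    }
  })
})

test_that("emission noise is repaired by smoothing across seeds", {
  # true sequences from the bout model; forest errors emulated by an
  # emission matrix; smoothing should beat the raw noisy labels in
  # essentially every replicate
  B <- matrix(0.06, 4, 4); diag(B) <- 0.82
  B <- B / rowSums(B)
  wins <- sapply(1:10, function(s) {
    truth <- lapply(1:10, function(p) {
      simulate_behaviour_sequence(default_bout_model(), 12 * 60,
                                  seed = s * 100 + p)$behaviour
    })
    noisy <- withr::with_seed(s, lapply(truth, function(tt) {
      factor(apply(B[as.integer(tt), ], 1, function(p) {
        sample(behaviour_levels(), 1, prob = p)
      }), levels = behaviour_levels())
    }))
    h <- estimate_hmm(truth, noisy)
    acc <- sapply(seq_along(truth), function(p) {
      sm <- viterbi_smooth(noisy[[p]], h)
      c(raw = mean(noisy[[p]] == truth[[p]]), smooth = mean(sm == truth[[p]]))
    })
    mean(acc["smooth", ]) >= mean(acc["raw", ])
  })
  expect_gte(sum(wins), 9)
})

test_that("HMM estimation is invariant to participant order", {
  withr::with_seed(17, {
    truth <- lapply(1:5, function(p) sample(behaviour_levels(), 50, replace = TRUE))
    obs <- lapply(truth, function(tt) {
      ifelse(runif(50) < 0.8, as.character(tt),
             sample(behaviour_levels(), 50, replace = TRUE))
    })
  })
  h1 <- estimate_hmm(truth, obs)
  h2 <- estimate_hmm(rev(truth), rev(obs))
  expect_equal(h1$A, h2$A)
  expect_equal(h1$B, h2$B)
  expect_equal(h1$prior, h2$prior)
  seq0 <- obs[[1]]
  expect_identical(viterbi_smooth(seq0, h1), viterbi_smooth(seq0, h2))
})

test_that("HMM parameters survive a JSON round trip", {
  truth <- c("sleep", "SB", "LIPA", "MVPA", "sleep", "SB")
  obs <- c("sleep", "SB", "LIPA", "MVPA", "SB", "SB")
  h <- estimate_hmm(truth, obs)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_hmm_params(h, tmp)
  h2 <- read_hmm_params(tmp)
  expect_equal(h2$A, h$A, tolerance = 1e-12)
  expect_equal(h2$B, h$B, tolerance = 1e-12)
  expect_equal(as.numeric(h2$prior), as.numeric(h$prior))
})
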