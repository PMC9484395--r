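#' Train a balanced random forest on labelled epochs
#'
#' Trains a 100-tree random forest in which each tree's bootstrap draws
#' an equal number of epochs per class -- the minority-class count, with
#' replacement -- so that rare behaviours (MVPA in particular) are not
#' swamped by the majority classes. Out-of-bag (OOB) predictions are kept
#' for every epoch; they feed the HMM emission estimates.
#'
#' @param epochs Tibble of labelled wear epochs: the 50 feature columns
#'   plus a `truth` column of behaviour labels. Rows with non-wear or NA
#'   features are rejected.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; training is deterministic given the seed.
#' @param classes Classes the model must cover (default: the classes
#'   observed). A class listed here with zero epochs is an error.
#' @param mtry Features tried per split; default `sqrt(50)` rounded.
#' @return Object of class `balanced_rf`: the forest, the feature-name
#'   manifest, class levels, per-class training counts, the seed, and
#'   `oob` (factor of OOB predictions, one per training epoch).
#' @export
train_balanced_forest <- function(epochs, n_trees = 100, seed = 1,
                                  classes = NULL, mtry = NULL) {
  if (!"truth" %in% names(epochs)) abort("epochs must carry a `truth` label column")
  feats <- intersect(feature_names(), names(epochs))
  if (length(feats) != 50) abort("epochs must contain the 50 feature columns")
  x <- as.matrix(epochs[, feats])
  if (anyNA(x)) abort("features contain NA; drop non-wear epochs before training")
  y <- as.character(epochs$truth)
  if (is.null(classes)) classes <- .BEHAVIOURS[.BEHAVIOURS %in% unique(y)]
  missing_cls <- classes[!classes %in% y]
  if (length(missing_cls) > 0) {
    abort(paste0("class(es) with zero epochs: ", paste(missing_cls, collapse = ", ")))
  }
  if (length(classes) < 2) abort("need at least 2 classes to train")
  y <- factor(y, levels = classes)
  n_min <- min(table(y))
  if (is.null(mtry)) mtry <- max(1, round(sqrt(length(feats))))
  forest <- withr::with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = mtry,
    strata = y, sampsize = rep(n_min, nlevels(y)), replace = TRUE,
    nodesize = 1
  ))
  structure(list(
    forest = forest,
    feature_names = feats,
    classes = classes,
    n_per_class = as.integer(table(y)),
    bootstrap_per_class = n_min,
    n_trees = n_trees,
    seed = seed,
    oob = forest$predicted
  ), class = "balanced_rf")
}

#' @export
print.balanced_rf <- function(x, ...) {
  cat(sprintf("<balanced_rf> %d trees, %d features, classes: %s\n",
              x$n_trees, length(x$feature_names),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  balanced bootstrap: %d per class (training n: %s)\n",
              x$bootstrap_per_class, paste(x$n_per_class, collapse = "/")))
  invisible(x)
}

#' Predict behaviours for epochs with a trained forest
#'
#' Returns the majority-vote class per epoch together with per-class vote
#' fractions. Ties are broken toward the lower class index in canonical
#' behaviour order.
#'
#' @param object A [train_balanced_forest()] model.
#' @param epochs Tibble containing the model's feature columns.
#' @param ... Unused.
#' @return Tibble with `pred` (factor) and one `vote_<class>` column per
#'   class; vote fractions sum to 1 per epoch.
#' @export
predict.balanced_rf <- function(object, epochs, ...) {
  miss <- setdiff(object$feature_names, names(epochs))
  if (length(miss) > 0) {
    abort(paste0("feature manifest mismatch; missing: ", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(epochs[, object$feature_names])
  votes <- stats::predict(object$forest, x, type = "vote", norm.votes = TRUE)
  votes <- votes[, object$classes, drop = FALSE]
  pick <- max.col(votes, ties.method = "first")
  out <- tibble(pred = factor(object$classes[pick], levels = object$classes))
  votes_tb <- as_tibble(as.data.frame(votes))
  names(votes_tb) <- paste0("vote_", object$classes)
  dplyr::bind_cols(out, votes_tb)
}

#' Estimate HMM parameters from true sequences and OOB predictions
#'
#' The smoothing HMM treats the forest's predicted labels as emissions
#' from the underlying true behaviour sequence. Transition probabilities
#' are row-normalised counts of consecutive-epoch true-label transitions
#' pooled over participants; emission probabilities are row-normalised
#' counts of (true label, OOB-predicted label) pairs; the prior is the
#' empirical true-label frequency. All entries are floored at `epsilon`
#' and re-normalised so no transition has zero probability.
#'
#' @param truth_seqs List of true label sequences (factors/characters),
#'   one per participant, or a single sequence.
#' @param oob_seqs Matching list of OOB-predicted label sequences.
#' @param epsilon Probability floor (default 1e-4).
#' @return Object of class `hmm_params` with `prior` (4-vector), `A`
#'   (4 x 4 transition), `B` (4 x 4 emission), all row-stochastic in
#'   canonical behaviour order, plus the pre-regularisation count
#'   matrices.
#' @export
estimate_hmm <- function(truth_seqs, oob_seqs, epsilon = 1e-4) {
  if (!is.list(truth_seqs)) truth_seqs <- list(truth_seqs)
  if (!is.list(oob_seqs)) oob_seqs <- list(oob_seqs)
  if (length(truth_seqs) != length(oob_seqs)) {
    abort("truth and OOB sequence lists must have the same length")
  }
  k <- length(.BEHAVIOURS)
  A_cnt <- matrix(0, k, k, dimnames = list(.BEHAVIOURS, .BEHAVIOURS))
  B_cnt <- A_cnt
  pi_cnt <- setNames(numeric(k), .BEHAVIOURS)
  for (i in seq_along(truth_seqs)) {
    tr <- as_behaviour(truth_seqs[[i]])
    ob <- as_behaviour(oob_seqs[[i]])
    if (length(tr) != length(ob)) abort("sequences and OOB predictions are not aligned")
    pi_cnt <- pi_cnt + tabulate(tr, k)
    B_cnt <- B_cnt + table(tr, ob)
    if (length(tr) > 1) {
      A_cnt <- A_cnt + table(tr[-length(tr)], tr[-1])
    }
  }
  absent <- .BEHAVIOURS[pi_cnt == 0]
  if (length(absent) > 0) {
    abort(paste0("behaviour(s) absent from training labels: ",
                 paste(absent, collapse = ", ")))
  }
  norm_floor <- function(m) {
    p <- m / pmax(rowSums(m), 1)
    p[p < epsilon] <- epsilon
    p / rowSums(p)
  }
  structure(list(
    prior = pi_cnt / sum(pi_cnt),
    A = norm_floor(A_cnt),
    B = norm_floor(B_cnt),
    A_counts = unclass(A_cnt),
    B_counts = unclass(B_cnt),
    epsilon = epsilon,
    classes = .BEHAVIOURS
  ), class = "hmm_params")
}

#' Serialise / restore HMM parameters as JSON
#'
#' Matrices are written row-major with the canonical class order recorded
#' in the file.
#'
#' @param params An [estimate_hmm()] object.
#' @param path Output (input) file.
#' @export
write_hmm_params <- function(params, path) {
  stopifnot(inherits(params, "hmm_params"))
  jsonlite::write_json(list(
    classes = params$classes,
    prior = as.numeric(params$prior),
    A = as.numeric(t(params$A)),  # row-major
    B = as.numeric(t(params$B)),
    epsilon = params$epsilon
  ), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(x$classes)
  structure(list(
    prior = setNames(x$prior, x$classes),
    A = matrix(x$A, k, k, byrow = TRUE, dimnames = list(x$classes, x$classes)),
    B = matrix(x$B, k, k, byrow = TRUE, dimnames = list(x$classes, x$classes)),
    epsilon = x$epsilon,
    classes = x$classes
  ), class = "hmm_params")
}

#' Viterbi smoothing of a predicted label sequence
#'
#' Finds the hidden true-behaviour sequence maximising
#' `prior(s1) B[s1,o1] prod_t A[s(t-1),s(t)] B[s(t),o(t)]` by dynamic
#' programming in the log domain. Ties are broken toward the lower class
#' index in canonical behaviour order.
#'
#' @param predicted Factor/character vector of forest-predicted labels
#'   (the observation sequence).
#' @param params An [estimate_hmm()] object.
#' @return Factor of smoothed labels, same length as the input.
#' @export
viterbi_smooth <- function(predicted, params) {
  stopifnot(inherits(params, "hmm_params"))
  check_stochastic(params$A, "A"); check_stochastic(params$B, "B")
  obs <- as.integer(as_behaviour(predicted))
  n <- length(obs)
  if (n == 0) return(factor(character(), levels = .BEHAVIOURS))
  k <- length(params$classes)
  logA <- log(params$A); logB <- log(params$B)
  logpi <- log(pmax(params$prior, 1e-300))
  if (any(!is.finite(logB[, obs]))) {
    abort("zero-probability emission encountered; params must be epsilon-floored")
  }
  delta <- matrix(-Inf, k, n)
  psi <- matrix(0L, k, n)
  delta[, 1] <- logpi + logB[, obs[1]]
  for (t in 2:max(n, 2)) {
    if (t > n) break
    for (j in seq_len(k)) {
      cand <- delta[, t - 1] + logA[, j]
      i <- which.max(cand)  # first max = lowest class index
      psi[j, t] <- i
      delta[j, t] <- cand[i] + logB[j, obs[t]]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[, n])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[path[t + 1], t + 1]
  factor(params$classes[path], levels = .BEHAVIOURS)
}

#' Log-likelihood of a state path under the smoothing HMM
#'
#' Scores a candidate true-label sequence against an observed predicted
#' sequence; [viterbi_smooth()] maximises this quantity.
#'
#' @param states Candidate hidden label sequence.
#' @param predicted Observed (forest-predicted) label sequence.
#' @param params An [estimate_hmm()] object.
#' @return Scalar log-likelihood.
#' @export
path_loglik <- function(states, predicted, params) {
  s <- as.integer(as_behaviour(states))
  o <- as.integer(as_behaviour(predicted))
  stopifnot(length(s) == length(o))
  n <- length(s)
  ll <- log(params$prior[s[1]]) + log(params$B[s[1], o[1]])
  if (n > 1) {
    ll <- ll + sum(log(params$A[cbind(s[-n], s[-1])])) +
      sum(log(params$B[cbind(s[-1], o[-1])]))
  }
  as.numeric(ll)
}
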