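#' Cohen's kappa
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with the expected
#' agreement `pe` from the product of the two label marginals. Returns 1
#' when both observed and expected agreement are 1.
#'
#' @param truth,pred Equal-length label vectors.
#' @return Scalar kappa in \[-1, 1\].
#' @export
#' @examples
#' kappa_score(c("a", "b", "a"), c("a", "b", "a"))  # 1
kappa_score <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("label vectors must have equal length")
  lev <- union(unique(as.character(truth)), unique(as.character(pred)))
  t1 <- factor(as.character(truth), levels = lev)
  t2 <- factor(as.character(pred), levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Minute-wise confusion matrix from 30-s epoch labels
#'
#' Each 30-s epoch contributes 0.5 minutes to the (true, predicted) cell,
#' so a calendar minute splits its two epochs at half weight each and
#' total time is conserved exactly: the matrix total equals
#' `n_epochs / 2` minutes.
#'
#' @param truth,pred Equal-length per-epoch behaviour labels.
#' @return 4 x 4 matrix of minutes; rows are ground truth, columns are
#'   model-assigned, in canonical behaviour order.
#' @export
confusion_minutes <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("label vectors must have equal length")
  tab <- table(as_behaviour(truth), as_behaviour(pred))
  m <- unclass(tab) * 0.5
  dimnames(m) <- list(truth = .BEHAVIOURS, predicted = .BEHAVIOURS)
  m
}

#' Precision and recall per class from a confusion matrix
#'
#' Precision is the diagonal over the column (model-assigned) sum, recall
#' the diagonal over the row (ground-truth) sum. Classes with a zero
#' denominator are flagged undefined (NA) rather than forced to a value.
#'
#' @param confusion Square matrix, rows = ground truth, columns =
#'   model-assigned (any consistent unit: counts or minutes).
#' @return Tibble with `class`, `precision`, `recall`, `true_minutes`
#'   (row sum) and `predicted_minutes` (column sum).
#' @export
precision_recall <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) abort("confusion matrix must be square")
  if (any(m < 0)) abort("confusion matrix entries must be non-negative")
  cls <- rownames(m)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(m)))
  rs <- rowSums(m); cs <- colSums(m)
  tibble(
    class = cls,
    precision = unname(ifelse(cs > 0, diag(m) / cs, NA_real_)),
    recall = unname(ifelse(rs > 0, diag(m) / rs, NA_real_)),
    true_minutes = unname(rs),
    predicted_minutes = unname(cs)
  )
}

#' Mean and normal-approximation 95% CI across participants
#'
#' Arithmetic mean of per-participant metric values with
#' `mean +/- 1.96 * SD / sqrt(n)`. Undefined (NA) values are excluded and
#' their count reported.
#'
#' @param values Numeric vector (per-participant metric values).
#' @return Tibble with `mean`, `conf_low`, `conf_high`, `n`,
#'   `n_undefined`.
#' @export
mean_with_ci <- function(values) {
  n_undef <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) < 2) abort("need at least 2 defined values")
  se <- sd(v) / sqrt(length(v))
  tibble(mean = mean(v), conf_low = mean(v) - 1.96 * se,
         conf_high = mean(v) + 1.96 * se, n = length(v), n_undefined = n_undef)
}

#' Published minute-wise benchmark confusion matrix
#'
#' Minute-wise confusion matrix reported for a four-behaviour wrist
#' accelerometer classifier evaluated by leave-one-participant-out
#' cross-validation on 152 adults in a free-living validation study
#' (2501 hours of annotated data). Used as a fixture for metric
#' computations; rows are ground truth, columns model-assigned, unit
#' minutes.
#'
#' @return 4 x 4 matrix of minutes in canonical behaviour order.
#' @export
benchmark_confusion_matrix <- function() {
  matrix(c(
    51347,   980,   215,    0,
     2322, 53052,  5717,   87,
       54,  4986, 22217, 1533,
        6,   158,  2434, 4978
  ), 4, 4, byrow = TRUE,
  dimnames = list(truth = .BEHAVIOURS, predicted = .BEHAVIOURS))
}

#' Leave-one-participant-out cross-validation of the full classifier
#'
#' For each participant, trains the balanced random forest on all other
#' participants' labelled epochs, estimates HMM parameters from those
#' participants' true sequences and OOB predictions, then predicts and
#' Viterbi-smooths the held-out participant's sequence. Reports
#' per-participant accuracy (raw and smoothed), Cohen's kappa, per-class
#' precision/recall and true minutes, plus the pooled minute-wise
#' confusion matrix across folds.
#'
#' @param data Tibble of labelled wear epochs for several participants:
#'   columns `participant`, `truth`, and the 50 features. Epochs must be
#'   in temporal order within participant. Subgroup evaluation (e.g. an
#'   age band) is a row filter on `data` before the call, not a special
#'   mode.
#' @param seed Integer seed used for every fold's forest.
#' @param n_trees Trees per forest.
#' @param min_class_minutes Optional sensitivity rule: per-class metrics
#'   of a participant with at most this many true minutes of the class
#'   are flagged undefined (use 20 to reproduce the low-minutes re-mean;
#'   default 0 disables).
#' @return List of class `loocv_result`: `metrics` (per-participant
#'   tibble), `class_metrics` (participant x class tibble), `confusion`
#'   (pooled minutes matrix), `summary` (means with CIs).
#' @export
loocv <- function(data, seed = 1, n_trees = 100, min_class_minutes = 0) {
  need <- c("participant", "truth")
  if (!all(need %in% names(data))) abort("data needs `participant` and `truth` columns")
  ids <- unique(data$participant)
  if (length(ids) < 2) abort("leave-one-participant-out needs at least 2 participants")
  feats <- feature_names()
  pooled <- matrix(0, 4, 4, dimnames = list(truth = .BEHAVIOURS,
                                            predicted = .BEHAVIOURS))
  met <- list(); clm <- list()
  for (p in ids) {
    test <- dplyr::filter(data, .data$participant == p)
    train <- dplyr::filter(data, .data$participant != p)
    if (nrow(test) == 0) {
      warn(sprintf("participant %s has no wear epochs; skipped", p))
      next
    }
    model <- train_balanced_forest(train, n_trees = n_trees, seed = seed,
                                   classes = .BEHAVIOURS)
    truth_seqs <- split(as_behaviour(train$truth), train$participant)
    oob_seqs <- split(model$oob, train$participant)
    hmm <- estimate_hmm(truth_seqs, oob_seqs)
    raw <- predict(model, test)$pred
    smoothed <- viterbi_smooth(raw, hmm)
    truth <- as_behaviour(test$truth)
    cm <- confusion_minutes(truth, smoothed)
    pooled <- pooled + cm
    pr <- precision_recall(cm)
    if (min_class_minutes > 0) {
      low <- pr$true_minutes <= min_class_minutes
      pr$precision[low] <- NA; pr$recall[low] <- NA
    }
    met[[as.character(p)]] <- tibble(
      participant = p,
      n_epochs = nrow(test),
      accuracy_raw = mean(raw == truth),
      accuracy = mean(smoothed == truth),
      kappa = kappa_score(truth, smoothed)
    )
    clm[[as.character(p)]] <- dplyr::mutate(pr, participant = p, .before = 1)
  }
  metrics <- dplyr::bind_rows(met)
  class_metrics <- dplyr::bind_rows(clm)
  summ <- dplyr::bind_rows(
    dplyr::mutate(mean_with_ci(metrics$accuracy), metric = "accuracy"),
    dplyr::mutate(mean_with_ci(metrics$kappa), metric = "kappa")
  )
  structure(list(metrics = metrics, class_metrics = class_metrics,
                 confusion = pooled, summary = summ, seed = seed),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d participants, %.0f scored minutes\n",
              nrow(x$metrics), sum(x$confusion)))
  print(x$summary)
  invisible(x)
}
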