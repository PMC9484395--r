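#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a compositional Cox fit
#'
#' @param x A [fit_behaviour_cox()] object.
#' @param exponentiate Report hazard ratios instead of log-hazards.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @method tidy coda_cox
#' @export
tidy.coda_cox <- function(x, exponentiate = FALSE, ...) {
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  lo <- b - 1.96 * se
  hi <- b + 1.96 * se
  est <- b
  if (exponentiate) {
    est <- exp(b); lo <- exp(lo); hi <- exp(hi)
  }
  tibble(
    term = names(b),
    estimate = unname(est),
    std_error = unname(se),
    statistic = unname(b / se),
    p_value = unname(2 * pnorm(-abs(b / se))),
    conf_low = unname(lo),
    conf_high = unname(hi)
  )
}

#' @rdname tidy.coda_cox
#' @return `glance()` returns a one-row tibble with `n`, `n_events`,
#'   `concordance`, `loglik` and the global PH-test p-value.
#' @method glance coda_cox
#' @export
glance.coda_cox <- function(x, ...) {
  ph <- check_proportional_hazards(x)
  tibble(
    n = x$n,
    n_events = x$n_events,
    concordance = unname(summary(x$fit)$concordance[1]),
    loglik = as.numeric(stats::logLik(x$fit)),
    ph_global_p = ph$p[ph$term == "GLOBAL"]
  )
}

#' Tidy HMM parameters into long format
#'
#' @param x An [estimate_hmm()] object.
#' @param ... Unused.
#' @return Tibble with `matrix` ("prior", "transition", "emission"),
#'   `from`, `to`, `probability`.
#' @method tidy hmm_params
#' @export
tidy.hmm_params <- function(x, ...) {
  k <- x$classes
  long <- function(m, name) {
    tibble(matrix = name,
           from = rep(k, each = length(k)),
           to = rep(k, length(k)),
           probability = as.numeric(t(m)))
  }
  dplyr::bind_rows(
    tibble(matrix = "prior", from = NA_character_, to = k,
           probability = as.numeric(x$prior)),
    long(x$A, "transition"),
    long(x$B, "emission")
  )
}

#' Tidy a LOOCV result
#'
#' @param x A [loocv()] result.
#' @param ... Unused.
#' @return The per-participant metrics tibble.
#' @method tidy loocv_result
#' @export
tidy.loocv_result <- function(x, ...) x$metrics

#' @rdname tidy.loocv_result
#' @return `glance()` returns the across-participant summary (mean
#'   accuracy and kappa with 95% CIs).
#' @method glance loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy", ]
  kap <- x$summary[x$summary$metric == "kappa", ]
  tibble(
    n_participants = nrow(x$metrics),
    mean_accuracy = acc$mean, accuracy_low = acc$conf_low,
    accuracy_high = acc$conf_high,
    mean_kappa = kap$mean, kappa_low = kap$conf_low, kappa_high = kap$conf_high,
    scored_minutes = sum(x$confusion)
  )
}
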