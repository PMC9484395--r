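#' Isometric log-ratio pivot basis
#'
#' A pivot basis for the 4-part behaviour composition. Under the pivot
#' order \eqn{(x_1, ..., x_D)} the coordinates are
#' \deqn{z_i = \sqrt{(D-i)/(D-i+1)} \; \ln\left(x_i \middle/
#'   \left(\prod_{j>i} x_j\right)^{1/(D-i)}\right), \quad i = 1..D-1,}
#' i.e. the first coordinate contrasts the first part against the
#' geometric mean of all the others. The basis is orthonormal in the
#' Aitchison metric, so Euclidean distance between coordinate vectors
#' equals Aitchison distance between compositions, and reallocation
#' hazard ratios do not depend on the pivot order.
#'
#' @param order Permutation of [behaviour_levels()]; the default puts
#'   MVPA first so the first coordinate contrasts MVPA against the rest.
#' @return Object of class `ilr_basis` with the contrast matrix `V`
#'   (4 x 3, in canonical part order) and the pivot `order`.
#' @export
ilr_basis <- function(order = c("MVPA", "SB", "LIPA", "sleep")) {
  if (!setequal(order, .BEHAVIOURS) || length(order) != 4) {
    abort("order must be a permutation of behaviour_levels()")
  }
  D <- 4L
  Vp <- matrix(0, D, D - 1)
  for (i in seq_len(D - 1)) {
    r <- D - i
    s <- sqrt(r / (r + 1))
    Vp[i, i] <- s
    Vp[(i + 1):D, i] <- -s / r
  }
  # rows of Vp follow the pivot order; re-index to canonical part order
  perm <- match(order, .BEHAVIOURS)
  V <- matrix(0, D, D - 1, dimnames = list(.BEHAVIOURS, paste0("z", 1:3)))
  V[perm, ] <- Vp
  structure(list(order = order, V = V, D = D), class = "ilr_basis")
}

# coerce composition input (vector, matrix, or data frame with behaviour
# columns) to an n x 4 matrix in canonical order
comp_matrix <- function(x) {
  if (is.data.frame(x)) {
    miss <- setdiff(.BEHAVIOURS, names(x))
    if (length(miss) > 0) abort(paste0("missing composition column(s): ",
                                       paste(miss, collapse = ", ")))
    m <- as.matrix(x[, .BEHAVIOURS])
  } else if (is.matrix(x)) {
    m <- x
    if (!is.null(colnames(m)) && all(.BEHAVIOURS %in% colnames(m))) {
      m <- m[, .BEHAVIOURS, drop = FALSE]
    }
    if (ncol(m) != 4) abort("composition matrix must have 4 columns")
  } else {
    if (length(x) != 4) abort("a composition has exactly 4 parts")
    m <- matrix(x, 1, 4)
  }
  colnames(m) <- .BEHAVIOURS
  m
}

#' Isometric log-ratio pivot coordinates of compositions
#'
#' @param x Composition input: a numeric 4-vector, an n x 4 matrix, or a
#'   data frame containing the four behaviour columns (hours/day). Parts
#'   must be strictly positive; run [replace_zeros()] first if not.
#' @param basis An [ilr_basis()].
#' @return Tibble with columns `z1`, `z2`, `z3` (one row per composition).
#' @export
#' @examples
#' ilr_pivot(c(sleep = 6, SB = 6, LIPA = 6, MVPA = 6))  # barycentre -> 0
ilr_pivot <- function(x, basis = ilr_basis()) {
  m <- comp_matrix(x)
  if (any(m <= 0)) {
    abort("compositions must be strictly positive; use replace_zeros() first")
  }
  z <- log(m) %*% basis$V
  as_tibble(as.data.frame(z))
}

#' Inverse ilr transform
#'
#' @param z Numeric 3-vector, n x 3 matrix or data frame with columns
#'   `z1`, `z2`, `z3`.
#' @param basis An [ilr_basis()].
#' @param total Closure total; defaults to 24 hours/day.
#' @return Tibble of strictly positive compositions closed to `total`.
#' @export
ilr_inverse <- function(z, basis = ilr_basis(), total = 24) {
  if (is.data.frame(z)) z <- as.matrix(z[, c("z1", "z2", "z3")])
  if (!is.matrix(z)) z <- matrix(z, 1)
  if (ncol(z) != 3 || any(!is.finite(z))) abort("z must be finite with 3 coordinates")
  clr <- z %*% t(basis$V)
  x <- exp(clr)
  x <- x / rowSums(x) * total
  colnames(x) <- .BEHAVIOURS
  as_tibble(as.data.frame(x))
}

#' Compositional (geometric) mean of behaviour compositions
#'
#' Part-wise geometric means, re-closed to the common total. This is the
#' reference ("hypothetical average individual") composition that
#' reallocation hazard ratios are anchored at.
#'
#' @inheritParams ilr_pivot
#' @param total Closure total (24 hours/day).
#' @return Tibble with one row and the four behaviour columns.
#' @export
compositional_mean <- function(x, total = 24) {
  m <- comp_matrix(x)
  if (any(m <= 0)) {
    abort("compositions must be strictly positive; use replace_zeros() first")
  }
  g <- exp(colMeans(log(m)))
  g <- g / sum(g) * total
  as_tibble(as.data.frame(matrix(g, 1, dimnames = list(NULL, .BEHAVIOURS))))
}

#' Replace zero parts by a small floor
#'
#' Parts below `floor_min` minutes/day are raised to the floor and the
#' remaining parts are multiplicatively rescaled so each composition still
#' sums to `total`; ratios among unmodified parts are preserved.
#'
#' @inheritParams ilr_pivot
#' @param floor_min Floor in minutes/day (default 1).
#' @param total Closure total in hours/day.
#' @return Tibble of adjusted compositions.
#' @export
replace_zeros <- function(x, floor_min = 1, total = 24) {
  if (floor_min <= 0) abort("floor must be positive")
  fl <- floor_min / 60
  if (4 * fl >= total) abort("floor too large: four floored parts exceed the day")
  m <- comp_matrix(x)
  out <- t(apply(m, 1, function(r) {
    low <- r < fl
    if (!any(low)) return(r)
    r[low] <- fl
    r[!low] <- r[!low] * (total - sum(r[low])) / sum(r[!low])
    r
  }))
  colnames(out) <- .BEHAVIOURS
  as_tibble(as.data.frame(out))
}

#' Fit a Cox proportional-hazards model on the behaviour composition
#'
#' Fits `survival::coxph()` with age as the timescale (left truncation at
#' entry age), the three ilr pivot coordinates of the daily behaviour
#' composition as exposure terms, optional categorical covariates, and
#' stratification (sex by default, optionally further strata such as BMI
#' category).
#'
#' @param cohort Data frame with columns `entry_age`, `exit_age`, `event`
#'   (0/1), the four behaviour columns in hours/day, and any covariate or
#'   stratum columns.
#' @param basis An [ilr_basis()].
#' @param covariates Character vector of covariate column names (treated
#'   as factors, first level = reference).
#' @param strata Character vector of stratum column names (default "sex").
#' @return Object of class `coda_cox` wrapping the `coxph` fit, with the
#'   basis, covariate spec and the cohort compositional mean.
#' @export
fit_behaviour_cox <- function(cohort, basis = ilr_basis(),
                              covariates = character(), strata = "sex") {
  need <- c("entry_age", "exit_age", "event", .BEHAVIOURS, covariates, strata)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) abort(paste0("cohort is missing column(s): ",
                                     paste(miss, collapse = ", ")))
  if (any(cohort$entry_age >= cohort$exit_age)) {
    abort("entry_age must be strictly less than exit_age for every subject")
  }
  if (sum(cohort$event) < 1) abort("the cohort contains no events")
  z <- ilr_pivot(cohort, basis)
  dat <- dplyr::bind_cols(
    dplyr::select(as_tibble(cohort), dplyr::all_of(c("entry_age", "exit_age", "event",
                                                     covariates, strata))),
    z
  )
  dat <- dplyr::mutate(dat, dplyr::across(dplyr::all_of(c(covariates, strata)), as.factor))
  rhs <- c("z1", "z2", "z3", covariates,
           if (length(strata) > 0) sprintf("strata(%s)", paste(strata, collapse = ", ")))
  fml <- stats::as.formula(paste("survival::Surv(entry_age, exit_age, event) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (any(!is.finite(coef(fit)))) {
    abort("Cox fit did not converge (non-finite coefficients); check for separation")
  }
  structure(list(
    fit = fit,
    basis = basis,
    covariates = covariates,
    strata = strata,
    reference = compositional_mean(cohort),
    n = nrow(dat),
    n_events = sum(dat$event)
  ), class = "coda_cox")
}

#' @export
print.coda_cox <- function(x, ...) {
  cat("Compositional Cox model (age timescale), ", x$n, " subjects, ",
      x$n_events, " events\n", sep = "")
  cat("Pivot order:", paste(x$basis$order, collapse = " > "), "\n")
  cat("Reference composition (h/day):\n")
  print(round(as.data.frame(x$reference), 2))
  print(coef(x$fit))
  invisible(x)
}

# build the reallocated composition for a reallocation request
reallocated_composition <- function(reference, to, from, amount_min, total = 24) {
  ref <- as.numeric(comp_matrix(reference))
  names(ref) <- .BEHAVIOURS
  amt <- amount_min / 60
  newc <- ref
  if (identical(from, "all")) {
    others <- setdiff(.BEHAVIOURS, to)
    newc[to] <- ref[to] + amt
    newc[others] <- ref[others] * (1 - amt / sum(ref[others]))
  } else {
    if (!from %in% .BEHAVIOURS || !to %in% .BEHAVIOURS || from == to) {
      abort("pairwise reallocation needs two distinct behaviours")
    }
    newc[to] <- ref[to] + amt
    newc[from] <- ref[from] - amt
  }
  bad <- names(newc)[newc <= 0]
  if (length(bad) > 0) {
    abort(paste0("reallocation drives part(s) non-positive: ",
                 paste(bad, collapse = ", ")))
  }
  newc
}

#' Time-reallocation hazard ratios
#'
#' Hazard ratio associated with moving `amount_min` minutes/day into
#' behaviour `to`, relative to the reference composition (the cohort
#' compositional mean by default). With `from` a single behaviour the
#' move is pairwise; with `from = "all"` the time is drawn from the other
#' three behaviours in proportion to their share of the reference
#' composition. The HR is `exp(beta_ilr . (z_new - z_ref))` with a
#' delta-method 95% CI from the ilr block of the covariance matrix.
#' Negative amounts move time out of `to`.
#'
#' @param fit A [fit_behaviour_cox()] object.
#' @param to Recipient behaviour.
#' @param from Donor behaviour, or `"all"` for proportional reallocation.
#' @param amount_min Minutes/day to move (vectorised; may be negative).
#' @param reference Reference composition (defaults to the fit's cohort
#'   compositional mean).
#' @return Tibble with one row per amount: `to`, `from`, `amount_min`,
#'   `hr`, `conf_low`, `conf_high`, and the reallocated composition
#'   columns.
#' @export
reallocate <- function(fit, to, from = "all", amount_min, reference = fit$reference) {
  stopifnot(inherits(fit, "coda_cox"))
  beta <- coef(fit$fit)[c("z1", "z2", "z3")]
  V <- vcov(fit$fit)[c("z1", "z2", "z3"), c("z1", "z2", "z3")]
  zref <- as.numeric(ilr_pivot(reference, fit$basis))
  rows <- purrr::map_dfr(amount_min, function(a) {
    newc <- reallocated_composition(reference, to, from, a)
    znew <- as.numeric(ilr_pivot(matrix(newc, 1), fit$basis))
    dz <- znew - zref
    eta <- sum(beta * dz)
    se <- sqrt(as.numeric(t(dz) %*% V %*% dz))
    tibble(
      to = to, from = from, amount_min = a,
      hr = exp(eta),
      conf_low = exp(eta - 1.96 * se),
      conf_high = exp(eta + 1.96 * se),
      !!!setNames(as.list(newc), paste0("new_", .BEHAVIOURS))
    )
  })
  rows
}

#' Grid of pairwise reallocation estimates
#'
#' Convenience wrapper computing [reallocate()] over a grid of amounts for
#' every ordered behaviour pair (or a chosen subset), suitable for
#' pairwise time-reallocation plots.
#'
#' @param fit A [fit_behaviour_cox()] object.
#' @param amounts_min Numeric vector of amounts in minutes/day.
#' @param pairs Optional tibble/data frame with columns `from`, `to`;
#'   defaults to all 12 ordered pairs.
#' @return Tibble of reallocation estimates, class `realloc_grid`.
#' @export
reallocation_grid <- function(fit, amounts_min = seq(-60, 60, by = 10), pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(from = .BEHAVIOURS, to = .BEHAVIOURS)
    pairs <- dplyr::filter(pairs, .data$from != .data$to)
  }
  out <- purrr::pmap_dfr(pairs, function(from, to) {
    ok <- purrr::map_lgl(amounts_min, function(a) {
      !inherits(try(reallocated_composition(fit$reference, to, from, a), silent = TRUE),
                "try-error")
    })
    if (!any(ok)) return(tibble())
    reallocate(fit, to = to, from = from, amount_min = amounts_min[ok])
  })
  class(out) <- c("realloc_grid", class(out))
  out
}

#' Grambsch-Therneau proportional-hazards test
#'
#' Scaled Schoenfeld residual score tests per model term and globally,
#' using the Kaplan-Meier transformation of time.
#'
#' @param fit A [fit_behaviour_cox()] object.
#' @return Tibble with columns `term`, `chisq`, `df`, `p`; the last row is
#'   the global test.
#' @export
check_proportional_hazards <- function(fit) {
  stopifnot(inherits(fit, "coda_cox"))
  zp <- survival::cox.zph(fit$fit, transform = "km", global = TRUE)
  tb <- as.data.frame(zp$table)
  tibble(term = rownames(tb), chisq = tb$chisq, df = tb$df, p = tb$p)
}

#' E-value for unmeasured confounding
#'
#' Minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to
#' explain away an observed hazard ratio. With `HR* = max(hr, 1/hr)`,
#' `E = HR* + sqrt(HR* (HR* - 1))`. The CI E-value is computed on the
#' confidence limit nearer the null and is 1 when the CI crosses 1.
#'
#' @param hr Hazard ratio (> 0); treated as an approximate risk ratio,
#'   appropriate for rare outcomes.
#' @param conf_low,conf_high Optional 95% CI limits.
#' @return Tibble with `evalue_estimate` and (when a CI is supplied)
#'   `evalue_ci`.
#' @export
#' @examples
#' evalue(2)  # 2 + sqrt(2)
evalue <- function(hr, conf_low = NULL, conf_high = NULL) {
  if (any(hr <= 0)) abort("hazard ratios must be positive")
  ev <- function(r) {
    rstar <- pmax(r, 1 / r)
    rstar + sqrt(rstar * (rstar - 1))
  }
  out <- tibble(hr = hr, evalue_estimate = ev(hr))
  if (!is.null(conf_low) && !is.null(conf_high)) {
    if (any(conf_low <= 0) || any(conf_high <= 0)) abort("CI limits must be positive")
    if (any(conf_low > conf_high)) abort("conf_low must not exceed conf_high")
    crosses <- conf_low <= 1 & conf_high >= 1
    near <- ifelse(hr >= 1, conf_low, conf_high)
    out$evalue_ci <- ifelse(crosses, 1, ev(near))
  }
  out
}
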