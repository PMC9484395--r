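random_composition <- function(total = 24) {
  p <- stats::rgamma(4, shape = 2)
  stats::setNames(p / sum(p) * total, behaviour_levels())
}

test_that("the compositional mean is idempotent and respects symmetry", {
  x <- c(sleep = 9, SB = 9, LIPA = 5.5, MVPA = 0.5)
  same <- rbind(x, x, x)
  expect_equal(unname(unlist(compositional_mean(same))), unname(x))
  # symmetry in two exchanged parts
  a <- c(sleep = 8, SB = 10, LIPA = 5, MVPA = 1)
  b <- c(sleep = 10, SB = 8, LIPA = 5, MVPA = 1)
  m <- compositional_mean(rbind(a, b))
  expect_equal(m$sleep, m$SB)
})

test_that("the compositional mean recovers a logistic-normal location", {
  loc <- c(sleep = 8.8, SB = 9.3, LIPA = 5.6, MVPA = 0.35)
  loc <- loc / sum(loc) * 24
  basis <- ilr_basis()
  mu <- as.numeric(ilr_pivot(loc, basis))
  sds <- c(0.7, 0.25, 0.2)
  withr::with_seed(8, {
    z <- sweep(matrix(rnorm(3000), 1000, 3) %*% diag(sds), 2, mu, "+")
  })
  comp <- ilr_inverse(z, basis)
  m <- compositional_mean(comp)
  zm <- as.numeric(ilr_pivot(m, basis))
  expect_true(all(abs(zm - colMeans(z)) < 1e-9))     # geometric mean = ilr average
  expect_true(all(abs(colMeans(z) - mu) < 3 * sds / sqrt(1000)))
})

test_that("zero replacement floors parts and preserves closure and ratios", {
  x <- c(sleep = 9, SB = 10, LIPA = 5, MVPA = 0)
  r <- replace_zeros(x, floor_min = 1)
  expect_equal(r$MVPA, 1 / 60)
  expect_equal(sum(r), 24, tolerance = 1e-12)
  expect_equal(r$sleep / r$SB, 9 / 10, tolerance = 1e-9)
  ok <- c(sleep = 9, SB = 10, LIPA = 4.5, MVPA = 0.5)
  expect_equal(unname(unlist(replace_zeros(ok))), unname(ok))
  expect_error(replace_zeros(x, floor_min = 6 * 60), "floor")
})

test_that("pivot coordinates match the closed form and invert exactly", {
  expect_equal(as.numeric(ilr_pivot(c(sleep = 6, SB = 6, LIPA = 6, MVPA = 6))),
               c(0, 0, 0))
  # hand evaluation under the canonical-order basis
  b <- ilr_basis(order = behaviour_levels())
  x <- c(sleep = 12, SB = 6, LIPA = 3, MVPA = 3)
  z <- as.numeric(ilr_pivot(x, b))
  expect_equal(z[1], sqrt(3 / 4) * log(12 / (6 * 3 * 3)^(1 / 3)))
  expect_equal(z[2], sqrt(2 / 3) * log(6 / sqrt(3 * 3)))
  expect_equal(z[3], sqrt(1 / 2) * log(3 / 3))
  withr::with_seed(21, {
    for (i in 1:100) {
      x <- random_composition()
      zz <- ilr_pivot(x)
      back <- as.numeric(ilr_inverse(zz))
      expect_equal(back, unname(x), tolerance = 1e-9)
    }
  })
  expect_error(ilr_pivot(c(0, 8, 8, 8)), "strictly positive")
})

test_that("pivot coordinates are an isometry of the Aitchison metric", {
  withr::with_seed(22, {
    for (i in 1:50) {
      a <- random_composition(); b <- random_composition()
      dz <- sqrt(sum((as.numeric(ilr_pivot(a)) - as.numeric(ilr_pivot(b)))^2))
      expect_equal(dz, aitchison_distance(a, b), tolerance = 1e-9)
    }
  })
})

test_that("ilr limits behave: zero coordinates and dominance", {
  expect_equal(unname(unlist(ilr_inverse(c(0, 0, 0)))), rep(6, 4))
  big <- unlist(ilr_inverse(c(12, 0, 0)))  # first pivot part dominates
  expect_gt(big[["MVPA"]], 23.99)
})

test_that("the Cox wrapper recovers known coefficients", {
  spec <- cohort_spec(n_subjects = 5000, true_coefficients = c(0.3, 0, 0))
  coh <- simulate_cohort(spec, seed = 7)
  fit <- fit_behaviour_cox(coh, covariates = "smoking")
  td <- tidy(fit)
  z1 <- td[td$term == "z1", ]
  expect_lt(abs(z1$estimate - 0.3), 2 * z1$std_error)
  gl <- glance(fit)
  expect_equal(gl$n, 5000)
  expect_gt(gl$n_events, 0)
  # variance matrix is symmetric positive definite on the ilr block
  V <- vcov(fit$fit)[1:3, 1:3]
  expect_equal(V, t(V), tolerance = 1e-12)
  expect_true(all(eigen(V)$values > 0))
})

test_that("the Cox wrapper validates its inputs", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 100), seed = 1)
  expect_error(fit_behaviour_cox(coh[, -2]), "entry_age")
  bad <- coh; bad$entry_age <- bad$exit_age
  expect_error(fit_behaviour_cox(bad), "strictly less")
  none <- coh; none$event <- 0
  expect_error(fit_behaviour_cox(none), "no events")
})

test_that("null reallocations and reference anchoring give HR exactly 1", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 1000), seed = 3)
  fit <- fit_behaviour_cox(coh)
  r0 <- reallocate(fit, to = "MVPA", from = "SB", amount_min = 0)
  expect_equal(r0$hr, 1)
  expect_equal(r0$conf_low, 1)
  expect_equal(r0$conf_high, 1)
})

test_that("reallocation HRs match the closed form under known coefficients", {
  beta <- c(0.3, -0.2, 0.1)
  spec <- cohort_spec(n_subjects = 8000, true_coefficients = beta)
  coh <- simulate_cohort(spec, seed = 17)
  fit <- fit_behaviour_cox(coh)
  ref <- fit$reference
  for (amt in c(-10, 20, 60)) {
    est <- reallocate(fit, to = "MVPA", from = "all", amount_min = amt)
    # truth from the generator's coefficients and the same delta-z
    newc <- wristcoda:::reallocated_composition(ref, "MVPA", "all", amt)
    dz <- as.numeric(ilr_pivot(matrix(newc, 1), fit$basis)) -
      as.numeric(ilr_pivot(ref, fit$basis))
    hr_true <- exp(sum(beta * dz))
    se <- sqrt(as.numeric(t(dz) %*% vcov(fit$fit)[1:3, 1:3] %*% dz))
    expect_lt(abs(log(est$hr) - log(hr_true)), 2.6 * se)
    expect_true(est$conf_low <= est$hr && est$hr <= est$conf_high)
  }
})

test_that("pairwise reallocations are reciprocal only for negated shifts", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 2000,
                                     true_coefficients = c(0.3, -0.2, 0.1)),
                         seed = 5)
  fit <- fit_behaviour_cox(coh)
  ab <- reallocate(fit, to = "SB", from = "LIPA", amount_min = 60)
  # undoing the move from the shifted composition negates delta-z exactly,
  # so the HRs are reciprocal
  shifted <- ab[, paste0("new_", behaviour_levels())]
  names(shifted) <- behaviour_levels()
  back <- reallocate(fit, to = "LIPA", from = "SB", amount_min = 60,
                     reference = shifted)
  expect_equal(ab$hr * back$hr, 1, tolerance = 1e-9)
  # moving the same amount the other way from the *reference* is NOT the
  # reciprocal: log-ratio shifts are asymmetric around the anchor
  ba <- reallocate(fit, to = "LIPA", from = "SB", amount_min = 60)
  expect_gt(abs(ab$hr * ba$hr - 1), 1e-4)
})

test_that("reallocations that exhaust a part are rejected", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 500), seed = 9)
  fit <- fit_behaviour_cox(coh)
  expect_error(reallocate(fit, to = "SB", from = "MVPA", amount_min = 120),
               "MVPA")
})

test_that("reallocation estimates are invariant to the pivot order", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 1500,
                                     true_coefficients = c(0.25, -0.1, 0.05)),
                         seed = 13)
  orders <- list()
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  base <- NULL
  for (i in seq_len(nrow(perms))) {
    ord <- behaviour_levels()[as.integer(perms[i, ])]
    fit <- fit_behaviour_cox(coh, basis = ilr_basis(order = ord))
    est <- reallocate(fit, to = "MVPA", from = "all", amount_min = 20)
    if (is.null(base)) base <- est else {
      expect_equal(est$hr, base$hr, tolerance = 1e-9)
      expect_equal(est$conf_low, base$conf_low, tolerance = 1e-9)
      expect_equal(est$conf_high, base$conf_high, tolerance = 1e-9)
    }
  }
})

test_that("reallocation grids cover all ordered pairs within bounds", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 800), seed = 4)
  fit <- fit_behaviour_cox(coh)
  g <- reallocation_grid(fit, amounts_min = c(-10, 0, 10))
  expect_equal(nrow(unique(g[c("from", "to")])), 12)
  expect_true(all(g$hr[g$amount_min == 0] == 1))
  expect_true(all(g$conf_low <= g$hr & g$hr <= g$conf_high))
  expect_s3_class(g, "realloc_grid")
})

test_that("proportional-hazards diagnostics report one row per term", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 600), seed = 2)
  fit <- fit_behaviour_cox(coh, covariates = "smoking")
  ph <- check_proportional_hazards(fit)
  expect_true(all(c("z1", "z2", "z3", "smoking", "GLOBAL") %in% ph$term))
  expect_true(all(ph$p >= 0 & ph$p <= 1))
})

test_that("the PH test is calibrated under the null and powered otherwise", {
  ps <- sapply(1:50, function(s) {
    coh <- simulate_cohort(cohort_spec(n_subjects = 500), seed = 2000 + s)
    ph <- check_proportional_hazards(fit_behaviour_cox(coh))
    ph$p[ph$term == "GLOBAL"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # a coefficient that flips sign over follow-up must be detected
  detect <- sapply(1:5, function(s) {
    coh <- simulate_cohort(cohort_spec(n_subjects = 5000), seed = 3000 + s)
    z1 <- as.numeric(ilr_pivot(coh)$z1)
    z1c <- z1 - mean(z1)
    withr::with_seed(s, {
      lam <- 0.05
      t1 <- rexp(5000, lam * exp(0.8 * z1c))
      t2 <- 4 + rexp(5000, lam * exp(-0.8 * z1c))
      tt <- ifelse(t1 < 4, t1, t2)
      cens <- pmin(rexp(5000, 0.01), 8)
    })
    coh$exit_age <- coh$entry_age + pmin(tt, cens)
    coh$event <- as.integer(tt <= cens)
    ph <- check_proportional_hazards(fit_behaviour_cox(coh))
    ph$p[ph$term == "GLOBAL"] < 0.05
  })
  expect_gte(sum(detect), 4)
})

test_that("E-values match the closed form and known worked examples", {
  expect_equal(evalue(1)$evalue_estimate, 1)
  expect_equal(evalue(2)$evalue_estimate, 2 + sqrt(2))
  # protective and harmful HRs of equal strength give equal E-values
  expect_equal(evalue(0.5)$evalue_estimate, evalue(2)$evalue_estimate)
  ev <- evalue(0.91, 0.90, 0.93)
  expect_equal(ev$evalue_estimate, 1 / 0.91 + sqrt((1 / 0.91) * (1 / 0.91 - 1)))
  # CI crossing the null pins the CI E-value at 1
  expect_equal(evalue(0.95, 0.9, 1.01)$evalue_ci, 1)
  expect_error(evalue(-1), "positive")
})

test_that("reallocation CIs achieve nominal coverage over replicates", {
  beta <- c(0.3, 0, 0)
  basis <- ilr_basis()
  spec <- cohort_spec(n_subjects = 250, true_coefficients = beta)
  # fixed target reallocation evaluated at the *population* location
  ref <- tibble::as_tibble(as.data.frame(spec$composition_location))
  newc <- wristcoda:::reallocated_composition(ref, "MVPA", "all", 20)
  dz <- as.numeric(ilr_pivot(matrix(newc, 1), basis)) -
    as.numeric(ilr_pivot(ref, basis))
  hr_true <- exp(sum(beta * dz))
  covered <- sapply(1:500, function(s) {
    coh <- simulate_cohort(spec, seed = 5000 + s)
    fit <- fit_behaviour_cox(coh)
    est <- reallocate(fit, to = "MVPA", from = "all", amount_min = 20,
                      reference = ref)
    est$conf_low <= hr_true && hr_true <= est$conf_high
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
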