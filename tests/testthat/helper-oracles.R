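# Independent oracles used by the tests. They deliberately avoid the code
# paths they check.

# exhaustive maximisation over all 4^n hidden paths of the HMM objective;
# returns every maximising path (the optimum may be attained by several
# paths when factor products coincide), as a character matrix with one row
# per optimal path
brute_force_viterbi <- function(obs, params, tol = 1e-9) {
  obs <- as.integer(wristcoda::as_behaviour(obs))
  n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:4), n)))[, n:1, drop = FALSE]
  logA <- log(params$A); logB <- log(params$B); logpi <- log(params$prior)
  ll <- logpi[paths[, 1]] + logB[cbind(paths[, 1], obs[1])]
  if (n > 1) {
    for (t in 2:n) {
      ll <- ll + logA[cbind(paths[, t - 1], paths[, t])] +
        logB[cbind(paths[, t], obs[t])]
    }
  }
  opt <- paths[ll >= max(ll) - tol, , drop = FALSE]
  matrix(behaviour_levels()[opt], nrow(opt), n)
}

# TRUE when `path` is one of the oracle's maximising paths
is_optimal_path <- function(path, obs, params) {
  opt <- brute_force_viterbi(obs, params)
  any(apply(opt, 1, function(r) identical(unname(r), as.character(path))))
}

# explicit po/pe kappa, written from the definition
brute_force_kappa <- function(truth, pred) {
  lev <- union(unique(as.character(truth)), unique(as.character(pred)))
  n <- length(truth)
  po <- sum(as.character(truth) == as.character(pred)) / n
  pe <- 0
  for (l in lev) {
    pe <- pe + (sum(truth == l) / n) * (sum(pred == l) / n)
  }
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# Aitchison distance from the definition (clr form), independent of the
# pivot machinery
aitchison_distance <- function(a, b) {
  cl <- function(x) log(x) - mean(log(x))
  sqrt(sum((cl(a) - cl(b))^2))
}
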