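# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

# Two-subject toy cohort: A has attacks at days 10 and 30 then censored at
# 540; B is censored at 540 without an attack.
toy_cohort <- function() {
  cohort(id = c("A", "A", "A", "B"),
         treatment = c(1, 1, 1, 0),
         start = c(0, 10, 30, 0),
         stop = c(10, 30, 540, 540),
         status = c(1, 1, 0, 0))
}

# Memoised simulated cohort.
sim_fixture <- function(n = 200, theta = 0.5, beta = -0.3,
                        process = "poisson_calendar", seed = 42,
                        followup = 540, rate = 3.53 / 540) {
  key <- paste(n, theta, beta, process, seed, followup, rate, sep = "|")
  if (is.null(.fixtures[[key]])) {
    nm <- n %/% 2
    .fixtures[[key]] <- simulate_cohort(sim_params(
      n_subjects = n, n_medication = nm, n_placebo = n - nm,
      baseline_rate = rate, beta_treatment = beta,
      frailty_variance = theta, process = process,
      followup_days = followup, seed = seed))
  }
  .fixtures[[key]]
}

default_cohort <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- simulate_cohort(default_params())
  .fixtures$default
}

# Random small counting-process frame with a single binary covariate and
# no tied event times (entry 0), for baseline/prediction oracles.
random_frame <- function(n = 12, seed = 1) {
  set.seed(seed)
  exit <- round(stats::rexp(n, 0.1) + 0.5, 3)
  while (anyDuplicated(exit)) exit <- exit + stats::runif(n, 0, 1e-3)
  data.frame(entry = 0, exit = exit,
             status = stats::rbinom(n, 1, 0.7),
             x = stats::rbinom(n, 1, 0.5),
             cluster = seq_len(n))
}

# The printed reverse-cumulative attack distribution of the trial this
# package emulates: n_children with >= k attacks, k = 1..38.
printed_attack_counts <- function() {
  c(232, 145, 100, 72, 57, 45, 37, 30, 20, 19, 11, 9, 7, 4, 3, 2, 2, 2,
    2, 2, rep(1, 18))
}

# Build a cohort whose per-order attack counts equal a given reverse
# cumulative distribution; one attack per day, censored at `followup`.
cohort_from_attack_counts <- function(n_ge_k, followup = 540) {
  exact <- diff(-c(n_ge_k, 0))  # children with exactly j attacks
  id <- 0
  rows <- list()
  for (j in seq_along(exact)) {
    for (r in seq_len(exact[j])) {
      id <- id + 1
      rows[[id]] <- data.frame(
        id = id, treatment = id %% 2,
        start = c(0:(j - 1), j), stop = c(1:j, followup),
        status = c(rep(1, j), 0))
    }
  }
  as_cohort(do.call(rbind, rows))
}
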