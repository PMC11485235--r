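# shared fixture builders; everything is generated in code, no stored data

# counts array from a list of c(from, to, age, n) entries (states by name)
make_counts <- function(entries) {
  states <- mltc_states()
  arr <- array(0L, dim = c(3L, 3L, 101L),
               dimnames = list(from = states, to = states, age = 0:100))
  for (e in entries) {
    arr[e$from, e$to, as.character(e$age)] <-
      arr[e$from, e$to, as.character(e$age)] + as.integer(e$n)
  }
  transition_counts(arr)
}

# age_transition_matrices with the yearly part set directly from per-age
# yearly probabilities: p_hi (healthy->ill), q_h (healthy->dead),
# q_i (ill->dead); vectors of length 101 or scalars
yearly_matrices <- function(p_hi, q_h, q_i) {
  states <- mltc_states()
  p_hi <- rep_len(p_hi, 101L); q_h <- rep_len(q_h, 101L)
  q_i <- rep_len(q_i, 101L)
  yearly <- array(0, dim = c(3L, 3L, 101L),
                  dimnames = list(from = states, to = states, age = 0:100))
  for (a in 1:101) {
    yearly[1L, , a] <- c(1 - p_hi[a] - q_h[a], p_hi[a], q_h[a])
    yearly[2L, , a] <- c(0, 1 - q_i[a], q_i[a])
    yearly[3L, , a] <- c(0, 0, 1)
  }
  structure(list(monthly = NULL, yearly = yearly,
                 data_present = matrix(TRUE, 101L, 3L)),
            class = "age_transition_matrices")
}

# comparator with given yearly death probabilities
comparator_from_yearly <- function(q_year) {
  q_year <- rep_len(q_year, 101L)
  structure(
    data.frame(age = 0:100, monthly_death = 1 - (1 - q_year)^(1 / 12),
               yearly_death = q_year, data_present = TRUE),
    class = c("comparator_model", "data.frame"))
}

# hand-built state panel from a named list person -> data.frame(month, age,
# state)
make_panel <- function(persons) {
  do.call(rbind, lapply(names(persons), function(id) {
    p <- persons[[id]]
    data.frame(person_id = id, month_index = p$month,
               age_years = p$age, state = p$state,
               stringsAsFactors = FALSE)
  }))
}

const_hazards <- function(ill = 0, dh = 0, di = dh) {
  hazard_spec(illness = hazard_constant(ill),
              mortality_healthy = hazard_constant(dh),
              mortality_ill = hazard_constant(di))
}

# deviations/SE for empirical proportions k/n around p
binom_z <- function(k, n, p) {
  se <- sqrt(p * (1 - p) / n)
  (k / n - p) / se
}

# is the observed count outside the central exact binomial interval at the
# level equivalent to z standard errors? (the normal 3-SE rule breaks down
# when n * p is tiny, so per-age convergence checks use the exact interval)
binom_outside <- function(k, n, p, z = 3) {
  tail <- pnorm(-z)
  k < qbinom(tail, n, p) | k > qbinom(1 - tail, n, p)
}

# simultaneous per-cell consistency of observed counts with binomial truth:
# no cell may fall outside its Bonferroni-adjusted exact interval, and the
# number of cells outside the per-cell 3-SE-level interval must stay within
# the 99.9% Poisson envelope of its own null expectation. Real estimation
# bias perturbs many cells at once and trips both bounds; isolated exact-tail
# events under a correct implementation trip neither.
expect_binomial_consistency <- function(k, n, p) {
  stopifnot(length(k) == length(n), length(n) == length(p))
  m <- length(k)
  per_cell <- 2 * pnorm(-3)
  out3 <- binom_outside(k, n, p, z = 3)
  bonf_tail <- per_cell / (2 * m)
  out_bonf <- k < qbinom(bonf_tail, n, p) | k > qbinom(1 - bonf_tail, n, p)
  testthat::expect_equal(sum(out_bonf), 0)
  testthat::expect_lte(sum(out3), qpois(0.999, m * per_cell))
}
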