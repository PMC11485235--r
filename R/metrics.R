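#' Propagate a birth cohort through the yearly matrices
#'
#' Starts the whole cohort healthy at age 0 and advances the state
#' occupancy one age at a time with the yearly transition matrices. Before
#' each advance the healthy-to-ill inflow at that age is recorded:
#' `inflow(a) = P_healthy(a) * P(healthy -> ill | age a, yearly)`, the
#' proportion of the initial population that enters the illness state in
#' the transition from age a.
#'
#' @param matrices An annualized `age_transition_matrices` (see
#'   [annualize()]).
#' @return An object of class `cohort_occupancy`: data.frame with columns
#'   `age` (0--100), `p_healthy`, `p_ill`, `p_dead`, `inflow`.
#' @export
propagate_cohort <- function(matrices) {
  stopifnot(inherits(matrices, "age_transition_matrices"))
  if (is.null(matrices$yearly)) {
    stop("matrices must be annualized first (see annualize())", call. = FALSE)
  }
  occ <- matrix(NA_real_, nrow = 101L, ncol = 3L)
  inflow <- numeric(101L)
  v <- c(1, 0, 0)
  for (a in 0:100) {
    occ[a + 1L, ] <- v
    inflow[a + 1L] <- v[1L] * matrices$yearly[1L, 2L, a + 1L]
    v <- as.vector(v %*% matrices$yearly[, , a + 1L])
  }
  structure(
    data.frame(age = 0:100, p_healthy = occ[, 1L], p_ill = occ[, 2L],
               p_dead = occ[, 3L], inflow = inflow),
    class = c("cohort_occupancy", "data.frame"))
}

#' Lifetime risk of entering the illness state
#'
#' The probability that an individual at birth ever enters the illness
#' state: the sum of the healthy-to-ill inflow over ages 0--100.
#'
#' @param occupancy A `cohort_occupancy`.
#' @return A probability in \[0, 1\].
#' @export
lifetime_risk <- function(occupancy) {
  stopifnot(inherits(occupancy, "cohort_occupancy"))
  sum(occupancy$inflow)
}

# survival-weighted remaining years from age a under yearly death
# probabilities q[age+1]; the year of age a counts as lived (no half-cycle
# correction), so certain death within the year still yields 1.0
remaining_years <- function(q, a) {
  q <- as.numeric(q)
  s <- 1
  total <- 0
  for (x in a:100) {
    total <- total + s
    if (x < 100L) s <- s * (1 - q[x + 1L])
  }
  total
}

#' Expected years lived in the illness state from a given entry age
#'
#' Computed from the survival function of the ill state: the sum over ages
#' a..100 of the probability of still being alive (ill) at that age, with
#' probability 1 at the entry age itself. Sums truncate at the age cap of
#' 100 years.
#'
#' @param matrices Annualized `age_transition_matrices`.
#' @param a Entry age, integer in 0--100.
#' @return Expected years (non-negative).
#' @export
expected_remaining_years_ill <- function(matrices, a) {
  stopifnot(inherits(matrices, "age_transition_matrices"),
            !is.null(matrices$yearly), a >= 0, a <= 100)
  q <- matrices$yearly[2L, 3L, ]
  remaining_years(q, as.integer(a))
}

#' Two-state alive-dead comparator model
#'
#' The comparator against which years of life lost are measured: a Markov
#' model of the same form with the two alive states pooled. Its monthly
#' death probability at each age is the number of deaths out of either
#' alive state divided by all moves out of the alive states at that age,
#' annualized by the 12th power (equivalently `1 - (1 - q_m)^12`). Ages
#' without data fall back to staying alive.
#'
#' @param counts A `transition_counts`.
#' @return An object of class `comparator_model`: data.frame with `age`,
#'   `monthly_death`, `yearly_death`, `data_present`.
#' @export
build_comparator <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  deaths <- counts$counts[1L, 3L, ] + counts$counts[2L, 3L, ]
  total <- apply(counts$counts[1L, , ], 2L, sum) +
    apply(counts$counts[2L, , ], 2L, sum)
  monthly <- ifelse(total > 0, deaths / total, 0)
  new_comparator(monthly, total > 0)
}

new_comparator <- function(monthly, data_present) {
  structure(
    data.frame(age = 0:100,
               monthly_death = monthly,
               yearly_death = 1 - (1 - monthly)^12,
               data_present = data_present),
    class = c("comparator_model", "data.frame"))
}

#' Expected remaining years in the comparator population
#'
#' Same summation convention as [expected_remaining_years_ill()], applied
#' to the pooled alive-dead comparator.
#'
#' @param comparator A `comparator_model`.
#' @param a Age, integer in 0--100.
#' @return Expected years.
#' @export
comparator_remaining_years <- function(comparator, a) {
  stopifnot(inherits(comparator, "comparator_model"), a >= 0, a <= 100)
  remaining_years(comparator$yearly_death, as.integer(a))
}

#' Years of life lost at a given entry age
#'
#' The gap between the comparator's expected remaining years at age a and
#' the expected remaining years of a person entering the illness state at
#' a; positive when the ill state carries excess mortality, exactly zero
#' when it does not.
#'
#' @param matrices Annualized `age_transition_matrices`.
#' @param comparator A `comparator_model`.
#' @param a Entry age, integer in 0--100.
#' @return Years (can be negative if the ill state out-survives the
#'   comparator).
#' @export
years_of_life_lost_at <- function(matrices, comparator, a) {
  comparator_remaining_years(comparator, a) -
    expected_remaining_years_ill(matrices, a)
}

#' Inflow-weighted average of a per-age metric
#'
#' Averages a per-age quantity (years lived with, years lost) over entry
#' ages, weighted by the share of lifetime illness entries occurring at
#' each age, `inflow(a) / L_r`.
#'
#' @param per_age_values Numeric vector over ages 0--100.
#' @param occupancy A `cohort_occupancy`.
#' @param lr Lifetime risk; must be > 0 for the average to exist.
#' @return Weighted mean, or `NA_real_` (with a warning) when `lr` is 0.
#' @export
average_metric <- function(per_age_values, occupancy, lr) {
  stopifnot(inherits(occupancy, "cohort_occupancy"),
            length(per_age_values) == 101L)
  if (lr <= 0) {
    warning("lifetime risk is zero; inflow-weighted average is not computable")
    return(NA_real_)
  }
  w <- occupancy$inflow / lr
  sum(w * per_age_values)
}

#' Median age at onset of the illness state
#'
#' The integer age alpha minimizing the absolute deviation of the
#' upper-tail inflow share `sum_{a >= alpha} inflow(a) / L_r` from one
#' half. Ties are resolved toward the lowest age at or after the
#' half-crossing: among tied minimizers, the smallest alpha whose
#' successor tail share has already fallen to one half or below (so a
#' point mass of inflow at age a* yields a* itself, and a run of ages
#' with tail share exactly one half yields its lowest age).
#'
#' @param occupancy A `cohort_occupancy`.
#' @param lr Lifetime risk; must be > 0.
#' @return Integer age in 0--100, or `NA_integer_` (with a warning) when
#'   `lr` is 0.
#' @export
median_onset <- function(occupancy, lr) {
  stopifnot(inherits(occupancy, "cohort_occupancy"))
  if (lr <= 0) {
    warning("lifetime risk is zero; median onset is not computable")
    return(NA_integer_)
  }
  tail_share <- rev(cumsum(rev(occupancy$inflow))) / lr
  dev <- abs(tail_share - 0.5)
  next_share <- c(tail_share[-1L], 0)   # share beyond the cap is zero
  tied <- dev <= min(dev) + 1e-12
  candidates <- which(tied & next_share <= 0.5 + 1e-12)
  if (!length(candidates)) candidates <- which(tied)
  as.integer(min(candidates) - 1L)
}

#' Assemble the burden metrics for one condition combination
#'
#' Runs the full deterministic pipeline over annualized matrices: cohort
#' propagation, lifetime risk, median onset, inflow-weighted years lived
#' with the condition combination and years of life lost versus the
#' two-state comparator, age at death (median onset plus years lived
#' with), and the community-scaled totals per 1,000 population
#' (`C = 1000 * metric * L_r`).
#'
#' Unless `override = TRUE`, the counts must pass the per-transition-type
#' eligibility check; refusal carries the report in the error condition.
#'
#' @param matrices Annualized `age_transition_matrices`.
#' @param counts A `transition_counts`; used for eligibility and, when
#'   `comparator` is `NULL`, to build the pooled comparator.
#' @param comparator Optional `comparator_model` to use instead of the one
#'   pooled from `counts`.
#' @param threshold Eligibility threshold (observations per transition
#'   type); default 1000.
#' @param override If `TRUE`, compute even when ineligible (with a
#'   warning).
#' @return An object of class `burden_metrics`: one-row data.frame with
#'   columns `lifetime_risk`, `median_onset_age`, `years_lived_with`,
#'   `years_of_life_lost`, `age_at_death`, `community_years_lived`,
#'   `community_years_lost`; the eligibility report is attached as
#'   attribute `"eligibility"`.
#' @export
compute_burden <- function(matrices, counts = NULL, comparator = NULL,
                           threshold = 1000L, override = FALSE) {
  stopifnot(inherits(matrices, "age_transition_matrices"))
  if (is.null(matrices$yearly)) matrices <- annualize(matrices)
  elig <- NULL
  if (!is.null(counts)) {
    elig <- check_eligibility(counts, threshold)
    if (!elig$eligible && !override) {
      cond <- structure(
        class = c("mltc_ineligible", "error", "condition"),
        list(message = paste0(
               "condition pair ineligible: ",
               paste(elig$table$transition[!elig$table$pass],
                     collapse = ", "),
               " below threshold ", elig$threshold,
               " (use override = TRUE to force)"),
             call = sys.call(),
             eligibility = elig))
      stop(cond)
    }
    if (!elig$eligible) {
      warning("computing burden metrics despite failed eligibility check")
    }
  }
  if (is.null(comparator)) {
    if (is.null(counts)) {
      stop("either counts or a comparator must be supplied", call. = FALSE)
    }
    comparator <- build_comparator(counts)
  }
  occ <- propagate_cohort(matrices)
  lr <- lifetime_risk(occ)
  ylw_a <- vapply(0:100, function(a) expected_remaining_years_ill(matrices, a),
                  numeric(1L))
  comp_a <- vapply(0:100, function(a) comparator_remaining_years(comparator, a),
                   numeric(1L))
  yll_a <- comp_a - ylw_a
  ylw <- average_metric(ylw_a, occ, lr)
  yll <- average_metric(yll_a, occ, lr)
  amed <- median_onset(occ, lr)
  out <- data.frame(
    lifetime_risk = lr,
    median_onset_age = amed,
    years_lived_with = ylw,
    years_of_life_lost = yll,
    age_at_death = amed + ylw,
    community_years_lived = 1000 * ylw * lr,
    community_years_lost = 1000 * yll * lr
  )
  structure(out, class = c("burden_metrics", "data.frame"),
            eligibility = elig, occupancy = occ,
            per_age = data.frame(age = 0:100, years_lived_with = ylw_a,
                                 years_of_life_lost = yll_a))
}

#' @export
print.burden_metrics <- function(x, ...) {
  cat("Illness-death burden metrics\n")
  cat(sprintf("  lifetime risk          %.4f\n", x$lifetime_risk))
  cat(sprintf("  median onset age       %d\n", x$median_onset_age))
  cat(sprintf("  years lived with       %.2f\n", x$years_lived_with))
  cat(sprintf("  years of life lost     %.2f\n", x$years_of_life_lost))
  cat(sprintf("  age at death           %.1f\n", x$age_at_death))
  cat(sprintf("  per 1,000: lived %.0f, lost %.0f\n",
              x$community_years_lived, x$community_years_lost))
  invisible(x)
}

#' Path-sampling microsimulation over the yearly matrices
#'
#' An independent stochastic check on the deterministic propagation:
#' individual walkers traverse the same yearly transition matrices from age
#' 0, and lifetime risk, years lived with illness and median onset are
#' measured from the sampled paths. A healthy-to-ill draw from the age-a
#' row counts as entry at age a (the entry year is lived in the ill state
#' and same-year ill mortality applies), matching the deterministic
#' convention.
#'
#' @param matrices Annualized `age_transition_matrices`.
#' @param n_walkers Number of simulated individuals.
#' @param seed Integer seed.
#' @return A list with `lifetime_risk`, `years_lived_with`,
#'   `median_onset_age`, their Monte-Carlo standard errors
#'   (`se_lifetime_risk`, `se_years_lived_with`), and `n_onsets`.
#' @export
microsimulate_metrics <- function(matrices, n_walkers = 200000L, seed = 1L) {
  stopifnot(inherits(matrices, "age_transition_matrices"),
            !is.null(matrices$yearly))
  set.seed(seed)
  n <- as.integer(n_walkers)
  state <- rep(1L, n)                 # 1 healthy, 2 ill, 3 dead
  onset_age <- rep(NA_integer_, n)
  years_ill <- numeric(n)
  for (a in 0:100) {
    i <- a + 1L
    h_row <- matrices$yearly[1L, , i]
    q_ill <- matrices$yearly[2L, 3L, i]
    healthy <- state == 1L
    if (any(healthy)) {
      u <- runif(sum(healthy))
      # draw destination from the healthy row: ill first, then dead
      to_ill <- u < h_row[2L]
      to_dead <- !to_ill & u < h_row[2L] + h_row[3L]
      idx <- which(healthy)
      state[idx[to_ill]] <- 2L
      onset_age[idx[to_ill]] <- a
      state[idx[to_dead]] <- 3L
    }
    ill <- state == 2L
    if (any(ill)) {
      years_ill[ill] <- years_ill[ill] + 1
      dies <- runif(sum(ill)) < q_ill
      state[which(ill)[dies]] <- 3L
    }
  }
  entered <- !is.na(onset_age)
  lr <- mean(entered)
  ylw_vals <- years_ill[entered]
  ylw <- mean(ylw_vals)
  amed <- NA_integer_
  if (any(entered)) {
    inflow <- as.numeric(table(factor(onset_age[entered], levels = 0:100)))
    tail_share <- rev(cumsum(rev(inflow))) / sum(inflow)
    amed <- as.integer(which.min(abs(tail_share - 0.5)) - 1L)
  }
  list(
    lifetime_risk = lr,
    se_lifetime_risk = sqrt(lr * (1 - lr) / n),
    years_lived_with = ylw,
    se_years_lived_with = stats::sd(ylw_vals) / sqrt(length(ylw_vals)),
    median_onset_age = amed,
    n_onsets = sum(entered)
  )
}
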