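#' True per-age monthly matrices implied by a hazard specification
#'
#' Builds the exact monthly transition matrices of the generating process:
#' within a month, death is resolved first with the state-appropriate
#' mortality hazard, then illness onset among surviving healthy persons —
#' the same event ordering the panel generator uses. The result plugs into
#' the identical estimation-side machinery ([annualize()],
#' [propagate_cohort()], [compute_burden()]), which is what makes
#' parameter-recovery tests meaningful.
#'
#' @param hazards A `hazard_spec`.
#' @return An `age_transition_matrices` (monthly part filled, all ages
#'   marked data-present).
#' @export
true_monthly_matrices <- function(hazards) {
  validate_hazard_spec(hazards)
  ht <- hazard_table(hazards)
  states <- mltc_states()
  monthly <- array(0, dim = c(3L, 3L, 101L),
                   dimnames = list(from = states, to = states, age = 0:100))
  for (a in 0:100) {
    i <- a + 1L
    qdh <- ht$mortality_healthy[i]
    qdi <- ht$mortality_ill[i]
    qi <- ht$illness[i]
    monthly[1L, , i] <- c((1 - qdh) * (1 - qi), (1 - qdh) * qi, qdh)
    monthly[2L, , i] <- c(0, 1 - qdi, qdi)
    monthly[3L, , i] <- c(0, 0, 1)
  }
  structure(list(monthly = monthly, yearly = NULL,
                 data_present = matrix(TRUE, 101L, 3L,
                                       dimnames = list(age = 0:100,
                                                       from = states))),
            class = "age_transition_matrices")
}

# month-resolution occupancy of a birth cohort under the generating
# hazards; rows are months 0..1212 (through the 12 months of age 100),
# columns healthy/ill/dead
monthly_occupancy_path <- function(hazards) {
  m <- true_monthly_matrices(hazards)$monthly
  path <- matrix(NA_real_, nrow = 1213L, ncol = 3L)
  v <- c(1, 0, 0)
  path[1L, ] <- v
  for (t in 1:1212) {
    age <- min(100L, (t - 1L) %/% 12L)
    v <- as.vector(v %*% m[, , age + 1L])
    path[t + 1L, ] <- v
  }
  path
}

#' Model-implied illness prevalence among the alive, by age
#'
#' Propagates a birth cohort through the true monthly matrices and returns
#' the conditional probability of being ill given alive at the start of
#' each age year. Used to seed prevalent cases into synthetic panels so a
#' one-year observation window has the same healthy/ill mix as the model's
#' birth cohort — the condition under which the pooled comparator is
#' recoverable from the window.
#'
#' @param hazards A `hazard_spec`.
#' @return Numeric vector of length 101 indexed by age 0--100.
#' @export
model_illness_prevalence <- function(hazards) {
  path <- monthly_occupancy_path(hazards)
  at_age <- path[seq(1L, 1201L, by = 12L), , drop = FALSE]   # ages 0..100
  alive <- at_age[, 1L] + at_age[, 2L]
  ifelse(alive > 0, at_age[, 2L] / alive, 0)
}

#' True pooled alive-dead comparator implied by the hazards
#'
#' The comparator the estimation pipeline would see with infinite data: at
#' each age, the monthly death probability pooled over both alive states,
#' weighted by the model's own healthy/ill person-month mix within that
#' age year (12 monthly occupancy snapshots).
#'
#' @param hazards A `hazard_spec`.
#' @return A `comparator_model`.
#' @export
true_comparator <- function(hazards) {
  ht <- hazard_table(hazards)
  path <- monthly_occupancy_path(hazards)
  monthly <- numeric(101L)
  for (a in 0:100) {
    rows <- (a * 12L + 1L):(a * 12L + 12L)   # the 12 months of age a
    ph <- path[rows, 1L]
    pi_ <- path[rows, 2L]
    alive <- sum(ph + pi_)
    monthly[a + 1L] <- if (alive > 0) {
      (sum(ph) * ht$mortality_healthy[a + 1L] +
         sum(pi_) * ht$mortality_ill[a + 1L]) / alive
    } else 0
  }
  new_comparator(monthly, rep(TRUE, 101L))
}

#' Analytic ground-truth burden metrics for a hazard specification
#'
#' Deterministic propagation of the generating monthly hazards through the
#' very same metric definitions the estimation pipeline uses, bypassing
#' panel simulation and tallying entirely: true monthly matrices are
#' annualized, the birth cohort propagated, and lifetime risk, median
#' onset, years lived with, years of life lost (against the true pooled
#' comparator) and the community metrics assembled. Serves as the
#' independent oracle for parameter-recovery validation.
#'
#' @param hazards A `hazard_spec`.
#' @return A `burden_metrics` object.
#' @export
analytic_metrics <- function(hazards) {
  matrices <- annualize(true_monthly_matrices(hazards))
  compute_burden(matrices, counts = NULL,
                 comparator = true_comparator(hazards))
}
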