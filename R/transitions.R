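#' Apply a condition-pair illness definition to a flag panel
#'
#' Real registry extracts carry one 0/1 column per condition plus vital
#' status rather than a precomputed three-state column. This maps such a
#' panel onto the illness-death state space: a person-month is `dead` when
#' the vital column says so, `ill` when every condition of `pair` is
#' flagged (irrespective of any other conditions), and `healthy` otherwise.
#'
#' @param panel Panel with `person_id`, `month_index`, `age_years`, a vital
#'   column (`dead`, 0/1 or logical), and one 0/1 column per condition.
#' @param pair Character vector of condition column names (typically two)
#'   that must all be present for the ill state.
#' @param dead_col Name of the vital-status column; default `"dead"`.
#' @return A canonical state panel (`person_id`, `month_index`, `age_years`,
#'   `state`, plus `sex` if present).
#' @export
apply_illness_definition <- function(panel, pair, dead_col = "dead") {
  dt <- as.data.table(panel)
  miss <- setdiff(c(pair, dead_col), names(dt))
  if (length(miss)) {
    stop("panel lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  flags <- as.matrix(dt[, pair, with = FALSE]) > 0
  ill <- rowSums(flags) == length(pair)
  dead <- as.logical(dt[[dead_col]] > 0)
  keep <- intersect(c("person_id", "month_index", "age_years", "sex"),
                    names(dt))
  out <- dt[, keep, with = FALSE]
  out[, state := ifelse(dead, "dead", ifelse(ill, "ill", "healthy"))]
  out[]
}

#' Tally monthly transitions by age
#'
#' Counts, for every consecutive month pair of every person, one move from
#' the state at the first month to the state at the second, attributed to
#' the person's age in completed years at the first month. Moves out of
#' `dead` never occur in a valid panel; remission moves (ill to healthy) are
#' excluded from the counts and surfaced in the attached remission report so
#' the caller can declare the condition pair incompatible with the model.
#'
#' @param panel A validated person-month state panel.
#' @return An object of class `transition_counts`: a list with `counts`
#'   (3 x 3 x 101 integer array, dimensions from-state, to-state, age 0--100),
#'   `remission` (integer vector by age of excluded ill-to-healthy moves)
#'   and `n_pairs` (total consecutive pairs seen).
#' @export
tally_transitions <- function(panel) {
  validate_panel(panel)
  states <- mltc_states()
  counts <- array(0L, dim = c(3L, 3L, 101L),
                  dimnames = list(from = states, to = states, age = 0:100))
  dt <- as.data.table(panel)
  if (nrow(dt) == 0L) {
    return(new_transition_counts(counts, integer(101L), 0L))
  }
  setorder(dt, person_id, month_index)
  same <- dt$person_id == data.table::shift(dt$person_id)
  same[is.na(same)] <- FALSE
  from <- data.table::shift(dt$state)[same]
  to <- dt$state[same]
  age <- data.table::shift(dt$age_years)[same]
  rem <- from == "ill" & to == "healthy"
  remission <- integer(101L)
  if (any(rem)) {
    remission <- as.integer(table(factor(age[rem], levels = 0:100)))
  }
  ok <- !rem
  if (any(ok)) {
    tab <- table(factor(from[ok], levels = states),
                 factor(to[ok], levels = states),
                 factor(age[ok], levels = 0:100))
    counts[] <- as.integer(tab)
  }
  new_transition_counts(counts, remission, length(to))
}

new_transition_counts <- function(counts, remission, n_pairs) {
  structure(list(counts = counts, remission = remission,
                 n_pairs = as.integer(n_pairs)),
            class = "transition_counts")
}

#' Build a transition-count object from an array
#'
#' Convenience for constructing fixtures and for deserialized counts;
#' validates the structural zeros (no moves out of dead, no remission).
#'
#' @param counts 3 x 3 x 101 array with dimnames over states and ages.
#' @return A `transition_counts` object.
#' @export
transition_counts <- function(counts) {
  stopifnot(is.array(counts), all(dim(counts) == c(3L, 3L, 101L)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts[3L, 1:2, ] != 0)) {
    stop("counts out of the dead state must be zero", call. = FALSE)
  }
  if (any(counts[2L, 1L, ] != 0)) {
    stop("ill -> healthy counts must be zero (no remission)", call. = FALSE)
  }
  dimnames(counts) <- list(from = mltc_states(), to = mltc_states(),
                           age = 0:100)
  new_transition_counts(counts, integer(101L), sum(counts))
}

#' @export
print.transition_counts <- function(x, ...) {
  tot <- apply(x$counts, 1:2, sum)
  cat("Transition counts over ages 0-100 (", x$n_pairs, " month pairs)\n",
      sep = "")
  print(tot)
  if (sum(x$remission) > 0) {
    cat("Excluded remission moves:", sum(x$remission), "\n")
  }
  invisible(x)
}

#' Estimate per-age monthly transition matrices
#'
#' Each row of the monthly matrix at age a is the observed proportion of
#' moves out of that state at that age: P(i, j, a) = n(i, j, a) / sum_k
#' n(i, k, a). Where a state has no observed moves at an age, the row falls
#' back to the identity (individuals are assumed to remain in the same
#' state) and `data_present` records the gap. The dead row is always
#' (0, 0, 1) and the ill-to-healthy entry always 0.
#'
#' @param counts A `transition_counts` object.
#' @return An object of class `age_transition_matrices`: list with
#'   `monthly` (3 x 3 x 101), `yearly` (filled by [annualize()]) and
#'   `data_present` (101 x 3 logical, ages by origin state).
#' @export
estimate_monthly_matrices <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  states <- mltc_states()
  monthly <- array(0, dim = c(3L, 3L, 101L),
                   dimnames = list(from = states, to = states, age = 0:100))
  data_present <- matrix(FALSE, nrow = 101L, ncol = 3L,
                         dimnames = list(age = 0:100, from = states))
  for (a in 1:101) {
    m <- diag(3)
    for (i in 1:3) {
      row <- counts$counts[i, , a]
      tot <- sum(row)
      if (tot > 0) {
        m[i, ] <- row / tot
        data_present[a, i] <- TRUE
      }
    }
    # structural constraints regardless of data
    m[3L, ] <- c(0, 0, 1)
    m[2L, 1L] <- 0
    monthly[, , a] <- m
  }
  structure(list(monthly = monthly, yearly = NULL,
                 data_present = data_present),
            class = "age_transition_matrices")
}

mat_pow12 <- function(m) {
  out <- m
  for (k in 2:12) out <- out %*% m
  out
}

#' Annualize monthly transition matrices
#'
#' Raises each per-age monthly matrix to the 12th power by repeated matrix
#' multiplication, converting monthly transition probabilities to yearly
#' ones. Row-stochasticity is preserved; the dead row stays exactly
#' (0, 0, 1).
#'
#' @param matrices An `age_transition_matrices` with the monthly part
#'   filled.
#' @return The same object with `yearly` filled.
#' @export
annualize <- function(matrices) {
  stopifnot(inherits(matrices, "age_transition_matrices"))
  yearly <- matrices$monthly
  for (a in 1:101) {
    m <- matrices$monthly[, , a]
    rs <- rowSums(m)
    bad <- which(abs(rs - 1) > 1e-8 | apply(m < -1e-12, 1L, any))
    if (length(bad)) {
      stop(sprintf(
        "monthly matrix at age %d is not row-stochastic (row '%s' sums to %.12g)",
        a - 1L, mltc_states()[bad[1L]], rs[bad[1L]]), call. = FALSE)
    }
    y <- mat_pow12(m)
    y[3L, ] <- c(0, 0, 1)
    yearly[, , a] <- y
  }
  matrices$yearly <- yearly
  matrices
}

#' Eligibility of a condition pair for the illness-death model
#'
#' A pair enters the model only when enough of each transition type was
#' observed across all ages: healthy to ill, healthy to dead and ill to
#' dead must each reach the threshold (default 1,000 observations).
#'
#' @param counts A `transition_counts`.
#' @param threshold Minimum observations per transition type; default 1000.
#' @return An object of class `eligibility_report`: data.frame with one row
#'   per transition type (`transition`, `count`, `pass`) and attribute /
#'   field `eligible`.
#' @export
check_eligibility <- function(counts, threshold = 1000L) {
  stopifnot(inherits(counts, "transition_counts"),
            is.numeric(threshold), threshold >= 1)
  totals <- c(
    "healthy->ill" = sum(counts$counts[1L, 2L, ]),
    "healthy->dead" = sum(counts$counts[1L, 3L, ]),
    "ill->dead" = sum(counts$counts[2L, 3L, ])
  )
  report <- data.frame(
    transition = names(totals),
    count = as.numeric(totals),
    pass = as.vector(totals >= threshold),
    row.names = NULL
  )
  structure(list(table = report,
                 threshold = as.numeric(threshold),
                 eligible = all(report$pass)),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Transition-type eligibility (threshold ", x$threshold, "):\n", sep = "")
  print(x$table, row.names = FALSE)
  cat(if (x$eligible) "=> eligible\n" else "=> NOT eligible\n")
  invisible(x)
}

#' Long-format table of counts and transition probabilities
#'
#' One row per (age, origin state, destination state) with the tallied
#' count and, when matrices are supplied, the monthly and yearly
#' probabilities — the serialization used by the analysis drivers.
#'
#' @param counts A `transition_counts`.
#' @param matrices Optional `age_transition_matrices` (annualized or not).
#' @return A `data.frame`.
#' @export
transition_table <- function(counts, matrices = NULL) {
  states <- mltc_states()
  grid <- expand.grid(from = states, to = states, age = 0:100,
                      stringsAsFactors = FALSE)
  out <- data.frame(age = grid$age, from = grid$from, to = grid$to,
                    count = as.vector(counts$counts))
  if (!is.null(matrices)) {
    out$monthly_probability <- as.vector(matrices$monthly)
    if (!is.null(matrices$yearly)) {
      out$yearly_probability <- as.vector(matrices$yearly)
    }
  }
  out[order(out$age, match(out$from, states), match(out$to, states)), ,
      drop = FALSE]
}
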