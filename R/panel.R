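#' @importFrom data.table data.table := as.data.table setorder fwrite fread
#' @importFrom stats runif setNames
NULL

#' Ordered state labels of the illness-death model
#'
#' The three states are healthy, ill and dead; dead is absorbing and
#' remission (ill to healthy) is not permitted.
#' @export
mltc_states <- function() c("healthy", "ill", "dead")

#' Cohort configuration for the synthetic panel generator
#'
#' @param n_persons Number of persons (non-negative integer; 0 yields an
#'   empty but schema-valid panel).
#' @param start_age_distribution Discrete distribution over integer ages
#'   0--100: a named numeric vector (names are ages, values are
#'   probabilities summing to 1), or a `data.frame` with columns `age` and
#'   `prob`.
#' @param observation_months Number of monthly transition intervals; the
#'   panel carries `observation_months + 1` snapshots per person
#'   (month_index 0 .. observation_months). The default, 12, emulates one
#'   observation year.
#' @param random_seed Integer root seed; all randomness in
#'   [generate_panel()] derives from it.
#' @param initial_illness_prob Optional probability that a person is already
#'   ill at entry, as a function of age or a numeric vector indexed by age
#'   0--100. `NULL` (default) starts everyone healthy.
#' @param include_sex If `TRUE`, a `sex` column ("female"/"male", drawn
#'   50/50) is added so sex-stratified runs can be exercised.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_persons,
                          start_age_distribution,
                          observation_months = 12L,
                          random_seed = 1L,
                          initial_illness_prob = NULL,
                          include_sex = FALSE) {
  if (!is.numeric(n_persons) || length(n_persons) != 1L || n_persons < 0 ||
      n_persons != floor(n_persons)) {
    stop("n_persons must be a non-negative integer", call. = FALSE)
  }
  if (is.data.frame(start_age_distribution)) {
    stopifnot(all(c("age", "prob") %in% names(start_age_distribution)))
    ages <- as.integer(start_age_distribution$age)
    probs <- as.numeric(start_age_distribution$prob)
  } else {
    ages <- as.integer(names(start_age_distribution))
    probs <- as.numeric(start_age_distribution)
  }
  if (any(is.na(ages)) || any(ages < 0L) || any(ages > 100L)) {
    stop("start ages must be integers in [0, 100]", call. = FALSE)
  }
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("start_age_distribution probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!is.numeric(observation_months) || observation_months < 1) {
    stop("observation_months must be a positive integer", call. = FALSE)
  }
  structure(
    list(n_persons = as.integer(n_persons),
         start_ages = ages,
         start_probs = probs,
         observation_months = as.integer(observation_months),
         random_seed = as.integer(random_seed),
         initial_illness_prob = initial_illness_prob,
         include_sex = isTRUE(include_sex)),
    class = "cohort_config")
}

#' Uniform start-age distribution helper
#'
#' @param from,to Inclusive integer age bounds.
#' @return Named probability vector usable as `start_age_distribution`.
#' @export
uniform_ages <- function(from = 0L, to = 99L) {
  ages <- seq.int(from, to)
  setNames(rep(1 / length(ages), length(ages)), ages)
}

initial_ill_prob_at <- function(config, ages) {
  ip <- config$initial_illness_prob
  if (is.null(ip)) return(rep(0, length(ages)))
  p <- if (is.function(ip)) ip(ages) else as.numeric(ip)[ages + 1L]
  p[is.na(p)] <- 0
  if (any(p < 0 | p > 1)) {
    stop("initial_illness_prob must yield probabilities in [0, 1]",
         call. = FALSE)
  }
  p
}

#' Generate a synthetic person-month panel
#'
#' Simulates the discrete-time illness-death process month by month: for
#' each alive person, death is sampled first (with the state-appropriate
#' mortality hazard at the person's current age in completed years); if the
#' person survives and is healthy, illness onset is sampled. A person
#' therefore never becomes ill and dies within the same month. Death is
#' absorbing and remission never occurs. Ages increment by one year every 12
#' months from the person's start age.
#'
#' All randomness derives from `config$random_seed`; every person owns a
#' fixed row of pre-drawn uniforms, so the panel is reproducible and
#' independent of processing order. Identical configuration and hazards give
#' a byte-identical panel.
#'
#' @param config A [cohort_config()].
#' @param hazards A [hazard_spec()].
#' @return A `data.table` with columns `person_id`, `month_index`,
#'   `age_years`, `state` (and `sex` when configured), ordered by person and
#'   month.
#' @export
generate_panel <- function(config, hazards) {
  stopifnot(inherits(config, "cohort_config"))
  validate_hazard_spec(hazards)
  n <- config$n_persons
  m <- config$observation_months
  cols <- c("person_id", "month_index", "age_years", "state")
  if (config$include_sex) cols <- c(cols, "sex")
  if (n == 0L) {
    empty <- data.table(person_id = character(), month_index = integer(),
                        age_years = integer(), state = character())
    if (config$include_sex) empty[, sex := character()]
    return(empty[])
  }

  set.seed(config$random_seed)
  start_age <- sample(config$start_ages, n, replace = TRUE,
                      prob = config$start_probs)
  sex <- if (config$include_sex) {
    c("female", "male")[1L + (runif(n) < 0.5)]
  } else NULL
  p0 <- initial_ill_prob_at(config, start_age)
  init_state <- 1L + (runif(n) < p0)          # 1 healthy, 2 ill
  # per-person uniform streams: row i belongs to person i for all months
  u_death <- matrix(runif(n * m), nrow = n)
  u_ill <- matrix(runif(n * m), nrow = n)

  # hazards looked up on the completed-years grid, capped at age 100
  max_age <- min(100L, max(start_age) + (m %/% 12L) + 1L)
  grid <- 0:max_age
  q_ill <- hazard_at(hazards$illness, grid)
  q_dh <- hazard_at(hazards$mortality_healthy, grid)
  q_di <- hazard_at(hazards$mortality_ill, grid)

  states <- matrix(3L, nrow = n, ncol = m + 1L)
  states[, 1L] <- init_state
  for (t in seq_len(m)) {
    cur <- states[, t]
    age <- pmin(100L, start_age + ((t - 1L) %/% 12L))
    idx <- age + 1L
    qd <- ifelse(cur == 2L, q_di[idx], q_dh[idx])
    alive <- cur != 3L
    dies <- alive & (u_death[, t] < qd)
    onset <- (cur == 1L) & !dies & (u_ill[, t] < q_ill[idx])
    nxt <- cur
    nxt[dies] <- 3L
    nxt[onset] <- 2L
    states[, t + 1L] <- nxt
  }

  width <- nchar(as.character(n))
  ids <- sprintf(paste0("p%0", width, "d"), seq_len(n))
  panel <- data.table(
    person_id = rep(ids, each = m + 1L),
    month_index = rep(0:m, times = n),
    age_years = rep(start_age, each = m + 1L) +
      (rep(0:m, times = n) %/% 12L),
    state = mltc_states()[as.vector(t(states))]
  )
  panel[, age_years := pmin(age_years, 100L)]
  if (config$include_sex) panel[, sex := rep(sex, each = m + 1L)]
  panel[]
}

#' Validate panel invariants
#'
#' Checks the structural contract of a person-month panel: required columns,
#' ages within 0--100, consecutive month indices from 0 per person, death
#' absorbing, no remission, and ages non-decreasing.
#'
#' @param panel A person-month panel.
#' @return The panel, invisibly; errors describe the first violation found.
#' @export
validate_panel <- function(panel) {
  dt <- as.data.table(panel)
  need <- c("person_id", "month_index", "age_years", "state")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(dt) == 0L) return(invisible(panel))
  if (!all(dt$state %in% mltc_states())) {
    stop("panel states must be one of healthy|ill|dead", call. = FALSE)
  }
  if (any(dt$age_years < 0L | dt$age_years > 100L)) {
    stop("panel ages must lie in [0, 100]", call. = FALSE)
  }
  setorder(dt, person_id, month_index)
  same <- dt$person_id == data.table::shift(dt$person_id)
  same[is.na(same)] <- FALSE
  dm <- dt$month_index - data.table::shift(dt$month_index)
  if (any(dm[same] != 1L)) {
    stop("month_index must be consecutive within person", call. = FALSE)
  }
  first <- !same
  if (any(dt$month_index[first] != 0L)) {
    stop("month_index must start at 0 for every person", call. = FALSE)
  }
  prev <- data.table::shift(dt$state)
  if (any(same & prev == "dead" & dt$state != "dead", na.rm = TRUE)) {
    stop("dead must be absorbing", call. = FALSE)
  }
  da <- dt$age_years - data.table::shift(dt$age_years)
  if (any(da[same] < 0L)) {
    stop("age_years must be non-decreasing within person", call. = FALSE)
  }
  invisible(panel)
}

#' Count remission (ill to healthy) moves per age
#'
#' The illness-death model does not permit remission; panels derived from
#' real data can nevertheless contain it (the reason one of the study
#' conditions, frailty, is typically excluded). This reports where it
#' occurs so the caller can rule the condition pair out.
#'
#' @param panel A person-month panel.
#' @return Integer vector of length 101 (ages 0--100): remission moves
#'   attributed to the age at the first month of the pair.
#' @export
remission_counts <- function(panel) {
  dt <- as.data.table(panel)
  out <- integer(101L)
  if (nrow(dt) == 0L) return(out)
  setorder(dt, person_id, month_index)
  same <- dt$person_id == data.table::shift(dt$person_id)
  prev <- data.table::shift(dt$state)
  prev_age <- data.table::shift(dt$age_years)
  rem <- which(same & prev == "ill" & dt$state == "healthy")
  if (length(rem)) {
    tab <- table(factor(prev_age[rem], levels = 0:100))
    out <- as.integer(tab)
  }
  out
}

#' Write / read a person-month panel as CSV
#'
#' The on-disk format is a plain CSV with header
#' `person_id,month_index,age_years,state` (plus `sex` when present), states
#' as the literal strings `healthy|ill|dead`.
#'
#' @param panel A panel as produced by [generate_panel()].
#' @param path File path.
#' @return `read_panel` returns a validated `data.table`.
#' @export
write_panel <- function(panel, path) {
  fwrite(as.data.table(panel), path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  dt <- fread(path, colClasses = list(character = "person_id"))
  validate_panel(dt)
  dt
}
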