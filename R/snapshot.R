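#' Generate a cross-sectional prevalence snapshot
#'
#' Produces one row per person with age, sex and a 0/1 flag per condition,
#' emulating a point-prevalence extract of a registered population on a
#' fixed date. Flags are drawn independently from the per-condition
#' marginals unless a pairwise excess is specified, in which case the two
#' conditions of a pair are drawn jointly with
#' `P(both) = p_a * p_b + excess` and all other conditions stay
#' independent.
#'
#' @param n_persons Number of persons.
#' @param marginals Per-condition marginal prevalence: a named numeric
#'   vector (condition -> probability), or a `data.frame` with columns
#'   `condition`, `prob` and optional `age_lo`, `age_hi`, `sex` rows giving
#'   age/sex-specific probabilities (first matching row wins; unmatched
#'   persons get probability 0).
#' @param excess Optional list of pairwise excesses, each a
#'   `list(pair = c("a", "b"), excess = e)`. The implied joint probability
#'   must respect the Frechet bounds
#'   `[max(0, p+q-1), min(p, q)]` for every person; a condition may appear
#'   in at most one pair.
#' @param age_distribution Named probability vector over integer ages (as
#'   in [uniform_ages()]); default uniform 20--89 (an adult register).
#' @param random_seed Integer seed.
#' @return A `data.table`: `person_id`, `age_years`, `sex`, one 0/1 column
#'   per condition.
#' @export
generate_prevalence_snapshot <- function(n_persons, marginals, excess = NULL,
                                         age_distribution = uniform_ages(20L, 89L),
                                         random_seed = 1L) {
  stopifnot(is.numeric(n_persons), n_persons >= 0,
            n_persons == floor(n_persons))
  marg <- normalize_marginals(marginals)
  conditions <- unique(marg$condition)
  set.seed(as.integer(random_seed))
  n <- as.integer(n_persons)
  ages <- as.integer(names(age_distribution))
  age <- if (n > 0) sample(ages, n, replace = TRUE,
                           prob = as.numeric(age_distribution)) else integer()
  sex <- if (n > 0) c("female", "male")[1L + (runif(n) < 0.5)] else character()

  probs <- lapply(conditions, function(cn) marginal_prob(marg, cn, age, sex))
  names(probs) <- conditions
  for (cn in conditions) {
    p <- probs[[cn]]
    if (any(p < 0 | p > 1)) {
      stop("marginal probability for '", cn, "' outside [0, 1]",
           call. = FALSE)
    }
  }

  flags <- matrix(0L, nrow = n, ncol = length(conditions),
                  dimnames = list(NULL, conditions))
  paired <- character()
  if (!is.null(excess)) {
    for (ex in excess) {
      pr <- ex$pair
      if (length(pr) != 2L || !all(pr %in% conditions)) {
        stop("excess pair must name two known conditions", call. = FALSE)
      }
      if (any(pr %in% paired)) {
        stop("a condition may appear in at most one excess pair",
             call. = FALSE)
      }
      paired <- c(paired, pr)
      pa <- probs[[pr[1L]]]
      pb <- probs[[pr[2L]]]
      p11 <- pa * pb + ex$excess
      lo <- pmax(0, pa + pb - 1)
      hi <- pmin(pa, pb)
      if (any(p11 < lo - 1e-12 | p11 > hi + 1e-12)) {
        stop("excess for pair (", pr[1L], ", ", pr[2L],
             ") implies a joint probability outside [max(0, p+q-1), min(p, q)]",
             call. = FALSE)
      }
      if (n > 0) {
        a_flag <- runif(n) < pa
        # conditional draw for b given a keeps the marginal of b intact
        p_b_given <- ifelse(a_flag,
                            ifelse(pa > 0, p11 / pa, 0),
                            ifelse(pa < 1, (pb - p11) / (1 - pa), pb))
        b_flag <- runif(n) < p_b_given
        flags[, pr[1L]] <- as.integer(a_flag)
        flags[, pr[2L]] <- as.integer(b_flag)
      }
    }
  }
  for (cn in setdiff(conditions, paired)) {
    if (n > 0) flags[, cn] <- as.integer(runif(n) < probs[[cn]])
  }

  width <- max(1L, nchar(as.character(max(n, 1L))))
  out <- data.table(
    person_id = if (n > 0) sprintf(paste0("s%0", width, "d"), seq_len(n))
                else character(),
    age_years = age,
    sex = sex
  )
  for (cn in conditions) out[, (cn) := flags[, cn]]
  out[]
}

normalize_marginals <- function(marginals) {
  if (is.data.frame(marginals)) {
    stopifnot(all(c("condition", "prob") %in% names(marginals)))
    m <- as.data.frame(marginals)
    if (is.null(m$age_lo)) m$age_lo <- 0L
    if (is.null(m$age_hi)) m$age_hi <- 100L
    if (is.null(m$sex)) m$sex <- "all"
    m
  } else {
    if (is.null(names(marginals)) || any(!nzchar(names(marginals)))) {
      stop("marginals vector must be named by condition", call. = FALSE)
    }
    data.frame(condition = names(marginals), prob = as.numeric(marginals),
               age_lo = 0L, age_hi = 100L, sex = "all",
               stringsAsFactors = FALSE)
  }
}

marginal_prob <- function(marg, condition, age, sex) {
  rows <- marg[marg$condition == condition, , drop = FALSE]
  p <- rep(0, length(age))
  assigned <- rep(FALSE, length(age))
  for (r in seq_len(nrow(rows))) {
    hit <- !assigned & age >= rows$age_lo[r] & age <= rows$age_hi[r] &
      (rows$sex[r] == "all" | sex == rows$sex[r])
    p[hit] <- rows$prob[r]
    assigned <- assigned | hit
  }
  p
}

#' Write / read a prevalence snapshot as CSV
#'
#' Header `person_id,age_years,sex,<condition_1>,...`; flags as 0/1.
#'
#' @param snapshot A snapshot table.
#' @param path File path.
#' @export
write_snapshot <- function(snapshot, path) {
  fwrite(as.data.table(snapshot), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  dt <- fread(path, colClasses = list(character = "person_id"))
  if (!all(c("person_id", "age_years", "sex") %in% names(dt))) {
    stop("snapshot must have person_id, age_years, sex columns",
         call. = FALSE)
  }
  dt
}

#' Condition columns of a snapshot
#'
#' @param snapshot A snapshot table.
#' @return Character vector of flag column names.
#' @export
snapshot_conditions <- function(snapshot) {
  setdiff(names(snapshot), c("person_id", "age_years", "sex"))
}
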