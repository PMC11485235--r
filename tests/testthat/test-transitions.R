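test_that("a single illness onset is tallied at the age of the first month of the pair", {
  panel <- make_panel(list(
    p1 = list(month = 0:12, age = c(rep(40L, 12), 41L),
              state = c(rep("healthy", 12), "ill"))))
  counts <- tally_transitions(panel)
  expect_equal(counts$counts["healthy", "ill", "40"], 1L)
  expect_equal(counts$counts["healthy", "healthy", "40"], 11L)
  expect_equal(sum(counts$counts), 12L)
})

test_that("no transitions are counted out of the dead state", {
  panel <- make_panel(list(
    p1 = list(month = 0:6, age = rep(55L, 7),
              state = c("healthy", "healthy", "healthy", rep("dead", 4)))))
  counts <- tally_transitions(panel)
  expect_equal(sum(counts$counts["dead", c("healthy", "ill"), ]), 0L)
  expect_equal(counts$counts["healthy", "dead", "55"], 1L)
  expect_equal(counts$counts["dead", "dead", "55"], 3L)
})

test_that("remission moves are excluded from counts and reported by age", {
  panel <- make_panel(list(
    p1 = list(month = 0:3, age = rep(60L, 4),
              state = c("ill", "healthy", "healthy", "ill"))))
  counts <- tally_transitions(panel)
  expect_equal(counts$counts["ill", "healthy", "60"], 0L)
  expect_equal(counts$remission[61L], 1L)
  expect_equal(sum(counts$remission), 1L)
  # the two non-remission pairs are still counted
  expect_equal(sum(counts$counts), 2L)
})

test_that("per-age transition fractions converge to the generating hazards", {
  ill_m <- 0.004; dh_m <- 0.002; di_m <- 0.006
  n <- 200000L
  cc <- cohort_config(n, uniform_ages(0, 99), 12, random_seed = 13,
                      initial_illness_prob = function(a) rep(0.2, length(a)))
  panel <- generate_panel(cc, const_hazards(ill = ill_m, dh = dh_m, di = di_m))
  counts <- tally_transitions(panel)$counts
  at_risk_h <- apply(counts[1, , ], 2, sum)
  at_risk_i <- apply(counts[2, , ], 2, sum)
  # per-age deviations consistent with binomial sampling around the
  # generating hazards, multiplicity-controlled (see helper)
  ah <- which(at_risk_h >= 1000); ai <- which(at_risk_i >= 1000)
  expect_binomial_consistency(
    k = c(counts[1, 2, ah], counts[1, 3, ah], counts[2, 3, ai]),
    n = c(at_risk_h[ah], at_risk_h[ah], at_risk_i[ai]),
    p = c(rep(ill_m * (1 - dh_m), length(ah)), rep(dh_m, length(ah)),
          rep(di_m, length(ai))))
})

test_that("monthly matrix rows are the observed proportions, with identity fallback", {
  counts <- make_counts(list(
    list(from = "healthy", to = "ill", age = 50, n = 10),
    list(from = "healthy", to = "healthy", age = 50, n = 990)))
  mat <- estimate_monthly_matrices(counts)
  expect_equal(mat$monthly["healthy", , "50"],
               c(healthy = 0.99, ill = 0.01, dead = 0))
  expect_true(mat$data_present["50", "healthy"])
  # age 7 has no data at all: identity rows, data_present FALSE
  expect_equal(mat$monthly[, , "7"], diag(3),
               ignore_attr = TRUE)
  expect_false(any(mat$data_present["7", ]))
  # ill row at 50 has no data either: fallback applies per origin row
  expect_equal(mat$monthly["ill", , "50"], c(healthy = 0, ill = 1, dead = 0))
  expect_false(mat$data_present["50", "ill"])
})

test_that("estimated rows sum to one exactly and structural zeros hold", {
  set.seed(21)
  cc <- cohort_config(5000, uniform_ages(0, 99), 12, random_seed = 21)
  hz <- const_hazards(ill = 0.01, dh = 0.003, di = 0.01)
  mat <- estimate_monthly_matrices(tally_transitions(generate_panel(cc, hz)))
  rs <- apply(mat$monthly, c(1, 3), sum)
  expect_equal(max(abs(rs - 1)), 0)
  expect_true(all(mat$monthly["dead", "healthy", ] == 0))
  expect_true(all(mat$monthly["dead", "ill", ] == 0))
  expect_true(all(mat$monthly["ill", "healthy", ] == 0))
})

test_that("annualization: identity stays identity and matches the scalar closed form", {
  counts <- make_counts(list(list(from = "healthy", to = "healthy",
                                  age = 30, n = 1)))
  mat <- annualize(estimate_monthly_matrices(counts))
  expect_equal(mat$yearly[, , "7"], diag(3), ignore_attr = TRUE)
  # two-state collapse: monthly death 0.05 -> yearly 1 - 0.95^12
  counts2 <- make_counts(list(
    list(from = "healthy", to = "healthy", age = 40, n = 95),
    list(from = "healthy", to = "dead", age = 40, n = 5)))
  mat2 <- annualize(estimate_monthly_matrices(counts2))
  expect_equal(mat2$yearly["healthy", "dead", "40"], 1 - 0.95^12,
               tolerance = 1e-12)
  rs <- apply(mat2$yearly, c(1, 3), sum)
  expect_lt(max(abs(rs - 1)), 1e-10)
  expect_equal(mat2$yearly["dead", , "40"], c(healthy = 0, ill = 0, dead = 1))
})

test_that("annualization rejects a non-stochastic row naming age and row", {
  counts <- make_counts(list(list(from = "healthy", to = "healthy",
                                  age = 10, n = 1)))
  mat <- estimate_monthly_matrices(counts)
  mat$monthly["healthy", "healthy", "10"] <- 0.7   # row now sums to 0.7
  expect_error(annualize(mat), "age 10.*healthy")
})

test_that("annualization commutes with the two-state collapse when alive rows agree", {
  # healthy and ill rows identical: (0, 0.9, 0.1); collapse is alive->dead 0.1
  states <- mltc_states()
  counts <- make_counts(list(
    list(from = "healthy", to = "ill", age = 25, n = 90),
    list(from = "healthy", to = "dead", age = 25, n = 10),
    list(from = "ill", to = "ill", age = 25, n = 90),
    list(from = "ill", to = "dead", age = 25, n = 10)))
  mat <- annualize(estimate_monthly_matrices(counts))
  collapsed <- 1 - 0.9^12
  expect_equal(mat$yearly["healthy", "dead", "25"], collapsed,
               tolerance = 1e-10)
  expect_equal(mat$yearly["ill", "dead", "25"], collapsed, tolerance = 1e-10)
})

test_that("eligibility requires every transition type to reach the threshold", {
  mk <- function(hi, hd, id) make_counts(list(
    list(from = "healthy", to = "ill", age = 50, n = hi),
    list(from = "healthy", to = "dead", age = 60, n = hd),
    list(from = "ill", to = "dead", age = 70, n = id)))
  expect_true(check_eligibility(mk(1500, 1200, 1001))$eligible)
  rep2 <- check_eligibility(mk(999, 1e6, 1e6))
  expect_false(rep2$eligible)
  expect_equal(rep2$table$transition[!rep2$table$pass], "healthy->ill")
  rep3 <- check_eligibility(make_counts(list()))
  expect_false(rep3$eligible)
  expect_true(all(!rep3$table$pass))
})

test_that("illness definition maps a flag panel onto the three states", {
  panel <- data.frame(
    person_id = "p1", month_index = 0:3, age_years = 50L,
    dead = c(0, 0, 0, 1), diabetes = c(1, 1, 1, 1), htn = c(0, 1, 1, 1))
  st <- apply_illness_definition(panel, c("diabetes", "htn"))
  expect_equal(st$state, c("healthy", "ill", "ill", "dead"))
  expect_error(apply_illness_definition(panel, c("diabetes", "copd")),
               "copd")
})

test_that("transition tables serialize counts and probabilities per age and move", {
  counts <- make_counts(list(
    list(from = "healthy", to = "ill", age = 50, n = 10),
    list(from = "healthy", to = "healthy", age = 50, n = 990)))
  mat <- annualize(estimate_monthly_matrices(counts))
  tab <- transition_table(counts, mat)
  expect_equal(nrow(tab), 9L * 101L)
  row <- tab[tab$age == 50 & tab$from == "healthy" & tab$to == "ill", ]
  expect_equal(row$count, 10)
  expect_equal(row$monthly_probability, 0.01)
})
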