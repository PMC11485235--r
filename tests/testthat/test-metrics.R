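test_that("identity matrices keep the cohort healthy with zero inflow", {
  mat <- yearly_matrices(p_hi = 0, q_h = 0, q_i = 0)
  occ <- propagate_cohort(mat)
  expect_true(all(occ$p_healthy == 1))
  expect_true(all(occ$inflow == 0))
  expect_equal(lifetime_risk(occ), 0)
})

test_that("a certain healthy-to-ill transition at age 0 moves everyone at once", {
  p_hi <- c(1, rep(0, 100))
  mat <- yearly_matrices(p_hi = p_hi, q_h = 0, q_i = 0)
  occ <- propagate_cohort(mat)
  expect_equal(occ$inflow[1], 1)
  expect_equal(occ$p_ill[2], 1)
  expect_equal(lifetime_risk(occ), 1)
})

test_that("yearly propagation equals monthly brute-force propagation collapsed to years", {
  hz <- const_hazards(ill = 0.002, dh = 0.001, di = 0.001)
  mat <- annualize(true_monthly_matrices(hz))
  occ <- propagate_cohort(mat)
  # independent oracle: 1,200 monthly steps with plain scalar updates
  M <- mat$monthly[, , 1]
  v <- c(1, 0, 0)
  ref <- matrix(NA_real_, 101, 3)
  for (t in 0:1199) {
    if (t %% 12 == 0) ref[t / 12 + 1, ] <- v
    v <- as.vector(v %*% M)
  }
  ref[101, ] <- v
  expect_lt(max(abs(as.matrix(occ[, c("p_healthy", "p_ill", "p_dead")]) - ref)),
            1e-8)
  expect_lt(max(abs(occ$p_healthy + occ$p_ill + occ$p_dead - 1)), 1e-10)
})

test_that("remaining years in the ill state follow the stated convention", {
  # certain yearly death: the entry year still counts as lived
  expect_equal(expected_remaining_years_ill(
    yearly_matrices(0, 0, q_i = 1), 40), 1.0)
  # no mortality: capped at 100, ages 90..100 inclusive
  expect_equal(expected_remaining_years_ill(
    yearly_matrices(0, 0, q_i = 0), 90), 11.0)
  # constant hazard far from the cap: truncated geometric series
  q <- 0.2
  mat <- yearly_matrices(0, 0, q_i = q)
  expect_equal(expected_remaining_years_ill(mat, 20),
               sum((1 - q)^(0:80)), tolerance = 1e-12)
})

test_that("the pooled comparator reproduces direct ratio arithmetic", {
  counts <- make_counts(list(
    list(from = "healthy", to = "healthy", age = 50, n = 900),
    list(from = "healthy", to = "dead", age = 50, n = 100),
    list(from = "ill", to = "ill", age = 50, n = 50),
    list(from = "ill", to = "dead", age = 50, n = 50)))
  comp <- build_comparator(counts)
  expect_equal(comp$monthly_death[51], 150 / 1100)
  expect_equal(comp$yearly_death[51], 1 - (1 - 150 / 1100)^12)
  # ages without data fall back to staying alive
  expect_equal(comp$monthly_death[1], 0)
  expect_false(comp$data_present[1])
})

test_that("comparator with no ill person-months equals the healthy-row mortality", {
  counts <- make_counts(list(
    list(from = "healthy", to = "healthy", age = 40, n = 990),
    list(from = "healthy", to = "dead", age = 40, n = 10)))
  comp <- build_comparator(counts)
  expect_equal(comp$monthly_death[41], 0.01)
})

test_that("years of life lost vanish exactly under equal mortality and are positive under excess", {
  q <- 0.02 + 0.001 * (0:100)
  mat <- yearly_matrices(p_hi = 0.01, q_h = q, q_i = q)
  comp <- comparator_from_yearly(q)
  for (a in c(0, 30, 60, 90, 100)) {
    expect_identical(years_of_life_lost_at(mat, comp, a), 0)
  }
  mat_hi <- yearly_matrices(p_hi = 0.01, q_h = q, q_i = pmin(1, 2 * q))
  for (a in c(0, 30, 60, 90)) {
    expect_gt(years_of_life_lost_at(mat_hi, comp, a), 0)
  }
  # certain ill death: comparator remaining years minus 1
  mat1 <- yearly_matrices(p_hi = 0.01, q_h = q, q_i = 1)
  expect_equal(years_of_life_lost_at(mat1, comp, 50),
               comparator_remaining_years(comp, 50) - 1)
})

test_that("inflow-weighted averages reduce to the expected closed forms", {
  occ <- propagate_cohort(yearly_matrices(0, 0, 0))
  # degenerate weights: all inflow at one age
  occ$inflow[] <- 0; occ$inflow[51] <- 0.4
  vals <- seq(0, 100)
  expect_equal(average_metric(vals, occ, 0.4), 50)
  # constant values are invariant to the inflow shape
  occ$inflow[] <- 0; occ$inflow[c(31, 71)] <- c(0.1, 0.3)
  expect_equal(average_metric(rep(7.5, 101), occ, 0.4), 7.5)
  # two-age hand-computed weighted mean: (0.3*10 + 0.1*2) / 0.4
  occ$inflow[] <- 0; occ$inflow[c(51, 71)] <- c(0.3, 0.1)
  vals <- numeric(101); vals[51] <- 10; vals[71] <- 2
  expect_equal(average_metric(vals, occ, 0.4), 8.0)
  expect_warning(out <- average_metric(vals, occ, 0), "not computable")
  expect_true(is.na(out))
})

test_that("median onset follows the integer argmin rule with lower-age tie-break", {
  occ <- propagate_cohort(yearly_matrices(0, 0, 0))
  # point mass at 63
  occ$inflow[] <- 0; occ$inflow[64] <- 0.25
  expect_equal(median_onset(occ, 0.25), 63L)
  # uniform over 40..59: upper-tail share from 50 is exactly 0.5
  occ$inflow[] <- 0; occ$inflow[41:60] <- 0.01
  expect_equal(median_onset(occ, 0.2), 50L)
  # two point masses: every alpha in 41..80 ties at 0.5; rule returns 41
  occ$inflow[] <- 0; occ$inflow[c(41, 81)] <- 0.2
  expect_equal(median_onset(occ, 0.4), 41L)
  expect_warning(out <- median_onset(occ, 0), "not computable")
  expect_true(is.na(out))
})

test_that("compute_burden assembles the community identities exactly", {
  q <- 0.01 + 0.0005 * (0:100)
  mat <- yearly_matrices(p_hi = 0.015, q_h = q, q_i = pmin(1, 2.5 * q))
  comp <- comparator_from_yearly(q * 1.2)
  bm <- compute_burden(mat, counts = NULL, comparator = comp)
  expect_identical(bm$community_years_lived,
                   1000 * bm$years_lived_with * bm$lifetime_risk)
  expect_identical(bm$community_years_lost,
                   1000 * bm$years_of_life_lost * bm$lifetime_risk)
  expect_equal(bm$age_at_death,
               bm$median_onset_age + bm$years_lived_with)
})

test_that("compute_burden refuses ineligible counts unless overridden", {
  counts <- make_counts(list(
    list(from = "healthy", to = "ill", age = 50, n = 5),
    list(from = "healthy", to = "dead", age = 50, n = 5),
    list(from = "ill", to = "dead", age = 50, n = 5),
    list(from = "ill", to = "ill", age = 50, n = 500),
    list(from = "healthy", to = "healthy", age = 50, n = 500)))
  mat <- annualize(estimate_monthly_matrices(counts))
  err <- tryCatch(compute_burden(mat, counts), mltc_ineligible = identity)
  expect_s3_class(err, "mltc_ineligible")
  expect_false(err$eligibility$eligible)
  expect_warning(bm <- compute_burden(mat, counts, override = TRUE),
                 "despite failed eligibility")
  expect_s3_class(bm, "burden_metrics")
})

test_that("increasing ill mortality never decreases years lost nor increases years lived", {
  set.seed(31)
  for (rep in 1:20) {
    p_hi <- runif(101, 0, 0.05)
    q_h <- runif(101, 0, 0.1)
    q_i <- pmin(1, q_h * runif(1, 1, 3))
    comp <- comparator_from_yearly(q_h)
    m1 <- yearly_matrices(p_hi, q_h, q_i)
    m2 <- yearly_matrices(p_hi, q_h, pmin(1, q_i + runif(1, 0.01, 0.2)))
    b1 <- compute_burden(m1, comparator = comp)
    b2 <- compute_burden(m2, comparator = comp)
    expect_gte(b2$years_of_life_lost, b1$years_of_life_lost)
    expect_lte(b2$years_lived_with, b1$years_lived_with)
  }
})

test_that("lifetime risk equals one minus surviving-healthy-or-dying-healthy mass", {
  hz <- default_study_hazards()
  mat <- annualize(true_monthly_matrices(hz))
  occ <- propagate_cohort(mat)
  lr <- lifetime_risk(occ)
  # independent accumulation: healthy mass either becomes ill (counted in
  # inflow), dies healthy, or is still healthy after the age-100 advance
  died_healthy <- sum(occ$p_healthy * mat$yearly[1, 3, ])
  final_healthy <- occ$p_healthy[101] * mat$yearly[1, 1, 101]
  expect_equal(lr + died_healthy + final_healthy, 1, tolerance = 1e-10)
})
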