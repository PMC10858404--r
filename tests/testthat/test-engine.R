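test_that("excess mortality, effective incidence and background mortality follow their closed forms", {
  expect_equal(annual_excess_mortality(1), 0)
  expect_equal(annual_excess_mortality(0.35), 1 - 0.35^(1 / 10))
  expect_equal(annual_excess_mortality(0.81), 1 - 0.81^(1 / 10))
  expect_error(annual_excess_mortality(0), "survival")
  expect_error(annual_excess_mortality(-0.1), "survival")

  expect_equal(effective_incidence(0.01), 0.01)
  expect_equal(effective_incidence(0.01, 0.04), 4e-4)
  # partial uptake contributes its expectation u*m + (1-u)
  expect_equal(effective_incidence(0.01, 0.70, 0.163),
               0.01 * (0.163 * 0.70 + 0.837))
  expect_equal(effective_incidence(0.01, 0.70, 0.163), 0.009511)
  expect_error(effective_incidence(0.5, 3), "outside")
  expect_error(effective_incidence(0.01, -1), "multipliers")

  expect_equal(background_mortality(0.01), 0.01)
  expect_equal(
    background_mortality(0.01, premenopausal_rrso = TRUE, ht_uptake = 0.8,
                         chd_multiplier = 1.03),
    0.01 * (0.8 + 0.2 * 1.03))
  expect_equal(
    background_mortality(0.01, premenopausal_rrso = TRUE, ht_uptake = 1),
    0.01)
  expect_equal(background_mortality(1, rrso_acm_multiplier = 1.5), 1)
})

test_that("transition matrices implement sequential conditioning and normalise", {
  ps <- override_ps(qx = 0.005, oc_p = 0.01, bc_p = 0.02, gene = "BRCA2")
  M <- build_transition_matrix("BRCA2", null_strategy("BRCA2"), ps, 50)
  expect_equal(M["healthy", "death_other"], 0.005)
  expect_equal(M["healthy", "oc_y1"], 0.995 * 0.01)
  expect_equal(M["healthy", "bc_y1"], 0.995 * 0.99 * 0.02, tolerance = 1e-12)
  expect_equal(M["healthy", "healthy"], 0.995 * 0.99 * 0.98, tolerance = 1e-12)
  expect_equal(unname(rowSums(M)), rep(1, length(state_names())))

  # tunnel mechanics: year k advances to k+1, year 10 to survivor; breast
  # tunnel admits ovarian entry, ovarian tunnel admits no breast entry
  expect_gt(M["bc_y3", "bc_y4"], 0)
  expect_gt(M["bc_y10", "bc_survivor"], 0)
  expect_gt(M["bc_y5", "oc_after_bc_y1"], 0)
  expect_gt(M["bc_survivor", "oc_after_bc_y1"], 0)
  expect_equal(sum(M[paste0("oc_y", 1:10), c(paste0("bc_y", 1:10), "bc_survivor")]), 0)
  expect_equal(M["oc_y10", "oc_survivor"], (1 - 0.005) * (1 - annual_excess_mortality(
    param_value(ps, "oc_survival_10yr"))))
  # death states absorbing
  for (d in c("death_oc", "death_bc", "death_other"))
    expect_equal(unname(M[d, d]), 1)

  # zero-hazard world: healthy persists
  ps0 <- override_ps(qx = 0, oc_p = 0, bc_p = 0, gene = "BRCA2")
  M0 <- build_transition_matrix("BRCA2", null_strategy("BRCA2"), ps0, 40)
  expect_equal(unname(M0["healthy", "healthy"]), 1)

  # every generated matrix row sums to 1 across genes, strategies, ages
  ps_def <- default_ps()
  for (g in c("BRCA1", "RAD51D", "BRIP1"))
    for (s in base_strategies(g))
      for (a in c(30, 35, 45, 51, 70, 99)) {
        M <- build_transition_matrix(g, s, ps_def, a)
        expect_equal(unname(rowSums(M)), rep(1, 36), tolerance = 1e-12)
      }
})

test_that("cycle rewards combine state costs, utilities and event disutilities", {
  ps <- override_ps(qx = 0.005, oc_p = 0.001, bc_p = 0.001, gene = "BRCA2")
  none <- null_strategy("BRCA2")
  u45 <- healthy_utility(ps, 45)

  rw <- cycle_reward("healthy", 45, none, ps)
  expect_equal(rw$utility, u45)
  expect_equal(rw$cost, 0)

  expect_equal(cycle_reward("bc_y1", 45, none, ps)$cost,
               param_value(ps, "cost_bc_year1"))
  expect_equal(cycle_reward("bc_y2", 45, none, ps)$cost,
               param_value(ps, "cost_bc_subseq"))
  expect_equal(cycle_reward("oc_y7", 45, none, ps)$cost,
               param_value(ps, "cost_oc_subseq"))
  expect_equal(cycle_reward("bc_y4", 45, none, ps)$utility,
               u45 * param_value(ps, "util_mult_bc"))
  expect_equal(cycle_reward("oc_survivor", 45, none, ps)$utility,
               u45 * param_value(ps, "util_mult_oc_survivor"))
  expect_equal(cycle_reward("death_oc", 45, none, ps)$utility, 0)

  # screening year: attendance disutility plus the false-positive expectation,
  # checked against explicit two-branch enumeration
  surv <- strategy("surv", "BRCA2", tier = "high", chemo_start = NA)
  f <- param_value(ps, "fp_prob_mammo")
  d_att <- param_value(ps, "disutil_screen")
  d_fp <- param_value(ps, "disutil_fp")
  rw55 <- cycle_reward("healthy", 55, surv, ps)  # mammography-only age
  u55 <- healthy_utility(ps, 55)
  two_branch <- f * (u55 - d_att - d_fp) + (1 - f) * (u55 - d_att)
  expect_equal(rw55$utility, two_branch)
  expect_equal(rw55$cost,
               param_value(ps, "cost_mammo") + f * param_value(ps, "cost_fp_workup"))

  # surgery year cost and disutility
  rrso <- strategy("rrso", "BRCA2", rrso_age = 40, tier = "none")
  rw40 <- cycle_reward("healthy", 40, rrso, ps)
  ht_u <- param_value(ps, "ht_uptake")
  expect_equal(rw40$cost,
               param_value(ps, "cost_rrso") + ht_u * param_value(ps, "cost_ht_year") +
                 (1 - ht_u) * param_value(ps, "cost_chd_year"))
  expect_equal(rw40$utility,
               healthy_utility(ps, 40) - param_value(ps, "disutil_rrso") -
                 (1 - ht_u) * param_value(ps, "disutil_chd"))
})

test_that("cohort propagation matches closed-form toys and path enumeration", {
  for (nm in c("geometric-survival", "pure-discount", "zero-world")) {
    fx <- toy_fixture(nm)
    got <- csgprev:::markov_run(fx$matrices, fx$cost, fx$utility, fx$init,
                                fx$rate, alive = fx$alive)
    expect_equal(got$ly, fx$expected$ly, tolerance = 1e-12)
    expect_equal(got$qaly, fx$expected$qaly, tolerance = 1e-12)
    expect_equal(got$cost, fx$expected$cost, tolerance = 1e-12)
  }

  # random chains up to 6 states x 6 cycles vs exhaustive path enumeration
  for (seed in 1:4) {
    S <- sample(2:6, 1)
    n <- sample(2:6, 1)
    ch <- random_chain(S, n, seed = 100 + seed)
    got <- csgprev:::markov_run(ch$matrices, ch$cost, ch$utility, ch$init,
                                rate = 0.035)
    want <- enumerate_expected(ch$matrices, ch$cost, ch$utility, ch$init,
                               rate = 0.035)
    expect_equal(got$cost, unname(want["cost"]), tolerance = 1e-9)
    expect_equal(got$qaly, unname(want["qaly"]), tolerance = 1e-9)
    expect_equal(got$ly, unname(want["ly"]), tolerance = 1e-9)
  }
})

test_that("cohort occupancy is conserved and events accumulate", {
  ps <- default_ps()
  res <- run_cohort("BRCA1", base_strategies("BRCA1")[[3]], ps)
  expect_equal(unname(rowSums(res$trace)), rep(1, nrow(res$trace)),
               tolerance = 1e-10)
  expect_true(all(res$trace >= -1e-14))
  # cumulative event tallies never decrease
  for (cc in c("oc_cases", "bc_cases", "oc_deaths", "bc_deaths"))
    expect_true(all(diff(cumsum(res$event_series[[cc]])) >= -1e-14))
  expect_lte(res$qalys, res$life_years)
  expect_gt(res$cost, 0)
})

test_that("with no cancer and no effects, life expectancy equals the life-table sum", {
  ps <- override_ps(default_ps(), oc_p = 0, bc_p = 0, gene = "BRCA2")
  r <- param_value(ps, "discount_rate")
  res <- run_cohort("BRCA2", null_strategy("BRCA2"), ps)
  expect_equal(unname(res$events), rep(0, 4))
  # closed-form discounted life expectancy from the life table
  qx <- ps$life_table$qx[ps$life_table$age <= 99]
  surv <- c(1, cumprod(1 - qx))[seq_along(qx)]
  le <- sum(surv * (1 + r)^(-(seq_along(qx) - 1)))
  expect_equal(res$life_years, le, tolerance = 1e-9)

  # discounting convention: first cycle undiscounted
  ps0 <- override_ps(qx = 0, oc_p = 0, bc_p = 0, gene = "BRCA2",
                     set = list(discount_rate = 0.035))
  res2 <- run_cohort("BRCA2", null_strategy("BRCA2"), ps0,
                     start_age = 30, end_age = 32)
  expect_equal(res2$life_years, 1 + 1 / 1.035, tolerance = 1e-12)
})

test_that("outcomes respond monotonically to hazards, costs and discounting", {
  base <- override_ps(qx = 0.005, oc_p = 0.005, bc_p = 0.01, gene = "BRCA2")
  s <- strategy("surv", "BRCA2", tier = "high", chemo_start = 30)
  r0 <- run_cohort("BRCA2", s, base)

  up_oc <- override_ps(qx = 0.005, oc_p = 0.010, bc_p = 0.01, gene = "BRCA2")
  expect_gt(run_cohort("BRCA2", s, up_oc)$events["oc_cases"],
            r0$events["oc_cases"])

  up_cost <- base
  up_cost$params$base[up_cost$params$name == "cost_mri"] <-
    param_value(base, "cost_mri") * 2
  expect_gt(run_cohort("BRCA2", s, up_cost)$cost, r0$cost)

  up_r <- base
  up_r$params$base[up_r$params$name == "discount_rate"] <- 0.06
  expect_lt(run_cohort("BRCA2", s, up_r)$qalys, r0$qalys)

  # RRSO strictly reduces ovarian cancer cases
  with_rrso <- strategy("rrso", "BRCA2", rrso_age = 40, tier = "high",
                        chemo_start = 30)
  expect_lt(run_cohort("BRCA2", with_rrso, base)$events["oc_cases"],
            r0$events["oc_cases"])
})

test_that("half-cycle correction reduces rewards of a shrinking cohort", {
  ps <- default_ps()
  s <- base_strategies("BRCA1")[[1]]
  full <- run_cohort("BRCA1", s, ps)
  half <- run_cohort("BRCA1", s, ps, half_cycle = TRUE)
  expect_lt(half$life_years, full$life_years)
  expect_lt(abs(half$life_years - full$life_years), 1)
})
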