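test_that("method-of-moments fits match hand-derived shapes and round-trip", {
  # gamma with mean 100, sd 30 (range read as a 95% CI)
  g <- fit_distribution(100, 100 - 1.96 * 30, 100 + 1.96 * 30, "gamma")
  expect_equal(g$pars$shape, (100 / 30)^2)
  expect_equal(g$pars$rate, 100 / 900)
  expect_equal(g$pars$shape, 11.1111, tolerance = 1e-4)

  # beta with mean 0.5, sd 0.1: nu = 0.25/0.01 - 1 = 24 -> alpha = beta = 12
  b <- fit_distribution(0.5, 0.5 - 0.196, 0.5 + 0.196, "beta")
  expect_equal(b$pars$alpha, 12)
  expect_equal(b$pars$beta, 12)

  expect_equal(fit_distribution(7, 7, 7, "gamma")$family, "fixed")
  expect_error(fit_distribution(1.2, 1.1, 1.3, "beta"), "mean in")

  # analytic moments of the fit reproduce (m, s^2)
  for (fam in c("gamma", "beta", "lognormal")) {
    m <- 0.4; s <- 0.05
    sp <- fit_distribution(m, m - 1.96 * s, m + 1.96 * s, fam)
    mo <- csgprev:::dist_moments(sp)
    expect_equal(unname(mo["mean"]), m, tolerance = 1e-9)
    expect_equal(unname(mo["var"]), s^2, tolerance = 1e-9)
  }

  # sampled mean converges to the target (3 standard errors)
  set.seed(1)
  x <- sample_distribution(fit_distribution(100, 41.2, 158.8, "gamma"), 10000)
  expect_lt(abs(mean(x) - 100), 3 * 30 / sqrt(10000))
})

test_that("parameter-set sampling is seed-reproducible and respects fixed entries", {
  ps <- default_ps()
  set.seed(7); d1 <- sample_parameter_set(ps)
  set.seed(7); d2 <- sample_parameter_set(ps)
  expect_identical(d1, d2)
  set.seed(8); d3 <- sample_parameter_set(ps)
  expect_false(identical(d1$params$base, d3$params$base))

  fixed <- ps$params$dist == "fixed"
  expect_identical(d1$params$base[fixed], ps$params$base[fixed])
  expect_false(any(d1$params$base[!fixed] == ps$params$base[!fixed]))

  allfix <- ps
  allfix$params$dist <- "fixed"
  set.seed(7)
  expect_identical(sample_parameter_set(allfix)$params$base, ps$params$base)

  # family support respected
  beta_rows <- d1$params$dist == "beta"
  expect_true(all(d1$params$base[beta_rows] >= 0 & d1$params$base[beta_rows] <= 1))
  gam_rows <- d1$params$dist == "gamma"
  expect_true(all(d1$params$base[gam_rows] >= 0))
})

test_that("PSA reproduces the deterministic base case in the degenerate limit", {
  ps <- default_ps()
  cfg <- model_config(ps, "BRIP1")

  allfix <- ps
  allfix$params$dist <- "fixed"
  cfg_fix <- model_config(allfix, "BRIP1")
  psa1 <- run_psa(cfg_fix, n = 1, seed = 3, progress_every = 0)
  det <- evaluate_strategies(cfg_fix)
  expect_equal(psa1$draws$cost, det$cost, tolerance = 1e-12)
  expect_equal(psa1$draws$qaly, det$qalys, tolerance = 1e-12)
  expect_equal(psa1$rejections, 0)

  # shrink all ranges 100-fold about the base: PSA means approach the
  # deterministic values
  tight <- ps
  tight$params$low <- tight$params$base - (tight$params$base - tight$params$low) / 100
  tight$params$high <- tight$params$base + (tight$params$high - tight$params$base) / 100
  psa_t <- run_psa(model_config(tight, "BRIP1"), n = 30, seed = 5,
                   progress_every = 0)
  det_t <- evaluate_strategies(model_config(tight, "BRIP1"))
  for (lab in det_t$strategy) {
    d <- psa_t$draws[psa_t$draws$strategy == lab, ]
    i <- match(lab, det_t$strategy)
    expect_lt(abs(mean(d$cost) - det_t$cost[i]),
              max(3 * sd(d$cost) / sqrt(nrow(d)), 1e-6))
    expect_lt(abs(mean(d$qaly) - det_t$qalys[i]),
              max(3 * sd(d$qaly) / sqrt(nrow(d)), 1e-6))
  }

  # seed reproducibility of the full PSA
  p1 <- run_psa(cfg, n = 5, seed = 11, progress_every = 0)
  p2 <- run_psa(cfg, n = 5, seed = 11, progress_every = 0)
  expect_identical(p1$draws, p2$draws)
})

test_that("acceptability curves are proper probabilities with correct winners", {
  mk_psa <- function(draws, labels) {
    structure(list(draws = draws, n = max(draws$draw), seed = 0,
                   rejections = 0L, gene = "BRCA1", labels = labels),
              class = "psa_result")
  }
  # one strategy: probability 1 everywhere
  d1 <- data.frame(draw = 1:3, strategy = "only",
                   cost = c(10, 20, 30), qaly = c(1, 2, 3))
  c1 <- ceac(mk_psa(d1, "only"), wtp_grid = c(0, 10000))
  expect_true(all(c1$probability == 1))

  # hand-built 4-draw, 2-strategy PSA vs exhaustive counting at 20k:
  # NMB_A = 20000q - c
  dA <- data.frame(draw = rep(1:4, each = 2),
                   strategy = rep(c("A", "B"), 4),
                   cost = c(0, 100, 0, 100, 0, 100, 500, 0),
                   qaly = c(1, 1.1, 1, 0.9, 1, 1, 1, 1))
  cc <- ceac(mk_psa(dA, c("A", "B")), wtp_grid = 20000)
  # draw 1: B wins (+2000-100); draw 2: A; draw 3: A (B costs more);
  # draw 4: B (A costs 500). Ties: none.
  expect_equal(cc$probability[cc$strategy == "A"], 2 / 4)
  expect_equal(cc$probability[cc$strategy == "B"], 2 / 4)

  # all draws identical -> indicator of the max-NMB strategy; sums to 1
  dI <- data.frame(draw = rep(1:3, each = 2), strategy = rep(c("A", "B"), 3),
                   cost = rep(c(50, 60), 3), qaly = rep(c(1, 1.2), 3))
  ci <- ceac(mk_psa(dI, c("A", "B")), wtp_grid = c(0, 1000, 50000))
  sums <- tapply(ci$probability, ci$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
  expect_equal(ci$probability[ci$wtp == 0 & ci$strategy == "A"], 1)      # cheaper
  expect_equal(ci$probability[ci$wtp == 50000 & ci$strategy == "B"], 1)  # more QALYs

  # exact ties split equally
  dT <- data.frame(draw = c(1, 1), strategy = c("A", "B"),
                   cost = c(10, 10), qaly = c(1, 1))
  ct <- ceac(mk_psa(dT, c("A", "B")), wtp_grid = 20000)
  expect_equal(ct$probability, c(0.5, 0.5))
})

test_that("one-way sensitivity analysis brackets the base case and sorts by spread", {
  ps <- default_ps()
  cfg <- model_config(ps, "BRIP1")
  pars <- c("cost_rrso", "rrso_acm_multiplier_BRIP1", "oc_survival_10yr",
            "cost_bc_year1")
  tr <- owsa(cfg, strategy_label = "rrso45", parameters = pars, wtp = 20000)
  expect_s3_class(tr, "owsa_result")
  expect_equal(sort(tr$nmb_spread, decreasing = TRUE), tr$nmb_spread)

  # a parameter unused by either BRIP1 strategy is inert
  row_inert <- tr[tr$parameter == "cost_bc_year1", ]
  expect_equal(row_inert$nmb_spread, 0, tolerance = 1e-9)
  expect_equal(row_inert$icer_low, row_inert$icer_high, tolerance = 1e-9)

  # base-case outcome lies inside the low/high bracket for active parameters
  det <- evaluate_strategies(cfg)
  base_nmb <- det$nmb[det$strategy == "rrso45"]
  act <- tr[tr$parameter == "cost_rrso", ]
  expect_gte(base_nmb, min(act$nmb_low, act$nmb_high) - 1e-9)
  expect_lte(base_nmb, max(act$nmb_low, act$nmb_high) + 1e-9)

  # perturbing a cost charged only in the comparator arm moves NMB by the
  # discounted, occupancy-weighted cost change at the surgery cycle
  run <- run_cohort("BRIP1", cfg$strategies[[2]], ps)
  occ_h <- run$trace[45 - 30 + 1, "healthy"]
  disc <- (1 + param_value(ps, "discount_rate"))^-(45 - 30)
  delta <- unname((act$high - act$low) * disc * occ_h)
  expect_equal(act$nmb_low - act$nmb_high, delta, tolerance = 1e-6)
})
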