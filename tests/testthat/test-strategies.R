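test_that("base-case strategy catalogue matches the gene-specific options", {
  b1 <- base_strategies("BRCA1")
  expect_length(b1, 4)
  expect_true(b1[[1]]$reference)
  expect_equal(b1[[1]]$label, "surveillance")
  expect_equal(b1[[1]]$surveillance$tier, "high")
  expect_equal(b1[[1]]$chemo_start, 30L)
  rrm_rrso <- b1[[4]]
  expect_equal(rrm_rrso$rrm_age, 30L)
  expect_equal(rrm_rrso$rrso_age, 35L)

  b2 <- base_strategies("BRCA2")
  expect_equal(b2[[4]]$rrm_age, 35L)
  expect_equal(b2[[4]]$rrso_age, 40L)
  p2 <- base_strategies("PALB2")
  expect_equal(p2[[4]]$rrm_age, 40L)
  expect_equal(p2[[4]]$rrso_age, 45L)

  rc <- base_strategies("RAD51C")
  expect_length(rc, 2)
  expect_true(all(is.na(vapply(rc, `[[`, 1L, "rrm_age"))))
  expect_equal(rc[[1]]$surveillance$tier, "moderate")
  expect_equal(rc[[1]]$chemo_start, 40L)

  br <- base_strategies("BRIP1")
  expect_length(br, 2)
  expect_equal(br[[1]]$label, "no_surgery")
  expect_true(br[[1]]$reference)
  expect_equal(br[[2]]$rrso_age, 45L)

  expect_error(base_strategies("TP53"), "unknown gene")
})

test_that("surveillance schedules enumerate the stated screening events", {
  high <- surveillance_schedule("high")
  expect_length(high$mri, 20)          # annual MRI ages 30-49
  expect_length(high$mammography, 30)  # annual mammography ages 40-69
  expect_equal(range(high$mri), c(30, 49))
  expect_equal(range(high$mammography), c(40, 69))

  # moderate tier: annual 40-59, then every third year
  mod <- surveillance_schedule("moderate")
  expect_setequal(mod$mammography, c(40:59, 60, 63, 66, 69))

  none <- surveillance_schedule("none")
  expect_length(none$mammography, 0)

  # event counts via the per-age resolver agree with direct enumeration
  s <- strategy("surv", "BRCA1", tier = "high", chemo_start = 30)
  acts <- lapply(30:100, function(a) active_interventions(s, a))
  expect_equal(sum(vapply(acts, `[[`, TRUE, "mri")), 20)
  expect_equal(sum(vapply(acts, `[[`, TRUE, "mammography")), 30)

  sm <- strategy("surv", "RAD51C", tier = "moderate", chemo_start = 40)
  mam_ages <- (30:100)[vapply(30:100, function(a)
    active_interventions(sm, a)$mammography, TRUE)]
  expect_setequal(mam_ages, c(40:59, seq(60, 69, 3)))
  expect_true(63 %in% mam_ages)
  expect_false(62 %in% mam_ages)
})

test_that("RRM stops surveillance and chemoprevention; RRSO triggers HT", {
  s <- base_strategies("BRCA1")[[4]]  # RRM@30 + RRSO@35
  a33 <- active_interventions(s, 33)
  expect_true(a33$post_rrm)
  expect_false(a33$mri)
  expect_false(a33$mammography)
  expect_false(a33$chemo_active)

  # BRCA2 RRSO@40 arm at 45: post-RRSO, HT until menopause, mammography on
  s2 <- base_strategies("BRCA2")[[3]]
  a45 <- active_interventions(s2, 45)
  expect_true(a45$post_rrso)
  expect_true(a45$ht_active)
  expect_true(a45$mammography)
  a52 <- active_interventions(s2, 52)
  expect_false(a52$ht_active)      # HT ends at menopause age
  expect_true(a52$chd_exposed)     # exposure persists for the non-HT fraction

  # BRCA2 chemoprevention window 30-34 truncated by RRM at 35
  s4 <- base_strategies("BRCA2")[[4]]
  expect_true(active_interventions(s4, 32)$chemo_active)
  expect_false(active_interventions(s4, 35)$chemo_active)

  expect_error(active_interventions(s, 29), "age")
  expect_error(active_interventions(s, 101), "age")
})

test_that("scenarios modify the configuration as specified and are pure", {
  ps <- default_ps()
  cfg <- model_config(ps, "BRIP1")
  snapshot <- cfg

  ht <- apply_scenario(cfg, scenario_spec("ht_40"))
  expect_equal(param_value(ht$params, "ht_uptake"), 0.40)

  rr <- apply_scenario(cfg, scenario_spec("brip1_rr_5.54"))
  expect_equal(param_value(rr$params, "brip1_oc_rr"), 5.54)
  # relative risk propagates into the BRIP1 ovarian curve
  expect_gt(incidence_at(gene_oc_curve(rr$params, "BRIP1"), 60),
            incidence_at(gene_oc_curve(cfg$params, "BRIP1"), 60))

  nb <- apply_scenario(cfg, scenario_spec("no_rrso_mortality_benefit_nonBRCA"))
  for (g in c("PALB2", "RAD51C", "RAD51D", "BRIP1"))
    expect_equal(param_value(nb$params, paste0("rrso_acm_multiplier_", g)), 1)
  expect_lt(param_value(nb$params, "rrso_acm_multiplier_BRCA1"), 1)

  sa <- apply_scenario(cfg, scenario_spec("start_age_35"))
  expect_equal(sa$start_age, 35L)

  cfg2 <- model_config(ps, "BRCA2")
  shift <- apply_scenario(cfg2, scenario_spec("age_shift", rrm_age = 30,
                                              rrso_age = 35))
  expect_equal(shift$strategies[[4]]$rrm_age, 30L)
  expect_equal(shift$strategies[[4]]$rrso_age, 35L)

  pc <- apply_scenario(cfg2, scenario_spec("parpi_costs"))
  expect_equal(param_value(pc$params, "cost_oc_year1"),
               param_value(ps, "cost_oc_year1") +
                 param_value(ps, "parpi_cost_oc_year1"))
  expect_equal(param_value(pc$params, "cost_bc_year1"),
               param_value(ps, "cost_bc_year1") +
                 param_value(ps, "parpi_cost_bc_year1"))

  # applying a scenario never mutates the base configuration
  expect_identical(cfg, snapshot)
  expect_error(scenario_spec("not_a_scenario"), "unknown scenario")
})
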