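# Relative age shapes (5-year bands, unitless weights) of cancer incidence
# per gene, reflecting the published age patterns: early-onset breast cancer
# for BRCA1, later onset for BRCA2/PALB2, late-onset ovarian cancer for the
# moderate-risk genes and the general population. A single scale factor per
# curve is calibrated so cumulative incidence to the horizon matches the
# target lifetime risk.
SYNTH_OC_SHAPES <- list(
  BRCA1 = data.frame(
    age_lo = c(30, 35, 40, 45, 50, 55, 60, 65, 70, 80),
    age_hi = c(34, 39, 44, 49, 54, 59, 64, 69, 79, 100),
    w = c(0.2, 0.6, 1.0, 1.6, 2.0, 2.0, 1.6, 1.2, 0.8, 0.5)),
  BRCA2 = data.frame(
    age_lo = c(30, 40, 45, 50, 55, 60, 65, 70, 80),
    age_hi = c(39, 44, 49, 54, 59, 64, 69, 79, 100),
    w = c(0.1, 0.4, 0.8, 1.3, 1.8, 2.0, 1.6, 1.0, 0.6)),
  PALB2 = data.frame(
    age_lo = c(30, 40, 45, 50, 55, 60, 65, 70, 80),
    age_hi = c(39, 44, 49, 54, 59, 64, 69, 79, 100),
    w = c(0.1, 0.3, 0.7, 1.2, 1.7, 2.0, 1.7, 1.1, 0.7)),
  RAD51C = data.frame(
    age_lo = c(30, 45, 50, 60, 70, 80),
    age_hi = c(44, 49, 59, 69, 79, 100),
    w = c(0.1, 0.5, 1.5, 2.0, 1.2, 0.7)),
  RAD51D = data.frame(
    age_lo = c(30, 45, 50, 60, 70, 80),
    age_hi = c(44, 49, 59, 69, 79, 100),
    w = c(0.1, 0.5, 1.5, 2.0, 1.2, 0.7)),
  population = data.frame(
    age_lo = c(30, 40, 50, 60, 70, 80),
    age_hi = c(39, 49, 59, 69, 79, 100),
    w = c(0.1, 0.35, 0.8, 1.5, 2.0, 1.6))
)

SYNTH_BC_SHAPES <- list(
  BRCA1 = data.frame(
    age_lo = c(30, 35, 40, 50, 60, 70, 80),
    age_hi = c(34, 39, 49, 59, 69, 79, 100),
    w = c(0.8, 1.6, 2.0, 1.6, 1.3, 1.0, 0.7)),
  BRCA2 = data.frame(
    age_lo = c(30, 35, 40, 50, 60, 70, 80),
    age_hi = c(34, 39, 49, 59, 69, 79, 100),
    w = c(0.5, 1.1, 1.7, 1.7, 1.5, 1.2, 0.8)),
  PALB2 = data.frame(
    age_lo = c(30, 35, 40, 50, 60, 70, 80),
    age_hi = c(34, 39, 49, 59, 69, 79, 100),
    w = c(0.5, 1.0, 1.6, 1.7, 1.5, 1.2, 0.8)),
  RAD51C = data.frame(
    age_lo = c(30, 40, 50, 60, 70, 80),
    age_hi = c(39, 49, 59, 69, 79, 100),
    w = c(0.3, 0.9, 1.4, 1.7, 1.3, 0.9)),
  RAD51D = data.frame(
    age_lo = c(30, 40, 50, 60, 70, 80),
    age_hi = c(39, 49, 59, 69, 79, 100),
    w = c(0.3, 0.9, 1.4, 1.7, 1.3, 0.9))
)

# Lifetime-risk targets: midpoints of the published gene-specific ranges
# (ovarian / breast), plus the general-population ovarian risk that, combined
# with the BRIP1 relative risk, yields the BRIP1 lifetime risk.
SYNTH_LIFETIME_TARGETS <- list(
  BRCA1 = c(oc = 0.46, bc = 0.685),
  BRCA2 = c(oc = 0.185, bc = 0.65),
  PALB2 = c(oc = 0.05, bc = 0.53),
  RAD51C = c(oc = 0.11, bc = 0.21),
  RAD51D = c(oc = 0.13, bc = 0.20),
  population = c(oc = 0.017)
)
BRIP1_RR_BASE <- 3.41  # population-based relative risk; 0.017 * 3.41 = 0.058

#' Specification for the synthetic parameter-set generator
#'
#' @param seed RNG seed used when `jitter = TRUE`.
#' @param lifetime_targets Named list of per-gene lifetime-risk targets
#'   (`oc`, and `bc` where applicable) plus `population`; defaults are the
#'   midpoints of published ranges.
#' @param horizon_age Age to which "lifetime" risk accumulates (default 80).
#' @param q30,gompertz_b Life-table shape: annual death probability at age 30
#'   and the Gompertz log-slope per year of age.
#' @param zero_mortality Generate an all-zero life table (degenerate testing
#'   case).
#' @param jitter Draw cost and utility base values uniformly within +/-10% of
#'   their documented defaults (clipped to the stated range) instead of using
#'   the defaults exactly.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, lifetime_targets = SYNTH_LIFETIME_TARGETS,
                           horizon_age = 80L, q30 = 0.00055,
                           gompertz_b = 0.092, zero_mortality = FALSE,
                           jitter = FALSE) {
  structure(
    list(seed = as.integer(seed), lifetime_targets = lifetime_targets,
         horizon_age = as.integer(horizon_age), q30 = q30,
         gompertz_b = gompertz_b, zero_mortality = isTRUE(zero_mortality),
         jitter = isTRUE(jitter)),
    class = "synthetic_spec"
  )
}

#' Generate a female life table
#'
#' Gompertz-type mortality `qx(a) = q30 * exp(b * (a - 30))` over ages
#' 30..100: strictly increasing, below 0.005 at age 30 and bounded in (0, 1),
#' emulating the shape of a national female life table.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame `age`, `qx`.
#' @export
generate_life_table <- function(spec = synthetic_spec()) {
  ages <- MODEL_AGE_MIN:MODEL_AGE_MAX
  qx <- if (spec$zero_mortality) rep(0, length(ages))
        else pmin(spec$q30 * exp(spec$gompertz_b * (ages - MODEL_AGE_MIN)), 0.999)
  data.frame(age = ages, qx = qx)
}

#' Calibrate an incidence curve to a target lifetime risk
#'
#' Scales an unnormalised non-negative age shape by a single factor `k` so
#' that the cumulative incidence `1 - prod(1 - k * w(a))` over ages 30 to
#' `horizon_age - 1` equals the target (scalar root-find, tolerance well
#' below 1e-4).
#'
#' @param shape Data frame `age_lo`, `age_hi`, `w` (non-negative weights,
#'   not all zero).
#' @param target Target lifetime risk in [0, 1).
#' @param gene,cancer Identifiers for the resulting curve.
#' @param horizon_age Horizon for "lifetime" (default 80).
#' @return An [incidence_curve()] whose cumulative incidence to the horizon
#'   matches `target`.
#' @export
calibrate_incidence <- function(shape, target, gene = "synthetic",
                                cancer = "OC", horizon_age = 80L) {
  stopifnot(is.data.frame(shape), all(shape$w >= 0))
  if (target < 0 || target >= 1) stop("target lifetime risk outside [0, 1)")
  bands0 <- data.frame(age_lo = shape$age_lo, age_hi = shape$age_hi, p = 0)
  if (target == 0 || all(shape$w == 0)) {
    if (target > 0) stop("target unreachable with an all-zero shape")
    return(incidence_curve(gene, cancer, bands0))
  }
  # per-year weights over the accumulation window
  ages <- MODEL_AGE_MIN:(horizon_age - 1L)
  w <- numeric(length(ages))
  for (i in seq_len(nrow(shape))) {
    sel <- ages >= shape$age_lo[i] & ages <= shape$age_hi[i]
    w[sel] <- shape$w[i]
  }
  cum <- function(k) 1 - prod(1 - k * w)
  k_max <- 0.999 / max(shape$w)
  if (cum(k_max) < target)
    stop("target lifetime risk ", target, " unreachable with this shape")
  k <- stats::uniroot(function(k) cum(k) - target, c(0, k_max),
                      tol = 1e-12)$root
  bands <- bands0
  bands$p <- k * shape$w
  cur <- incidence_curve(gene, cancer, bands)
  cur$scale <- k
  cur
}

# cumulative incidence of a curve to the horizon (ignores competing
# mortality, matching the calibration convention)
cumulative_incidence <- function(curve, horizon_age = 80L) {
  sel <- curve$ages < horizon_age
  1 - prod(1 - curve$p[sel])
}

# Documented base values for scalar parameters: (base, low, high, family).
# Effect sizes follow the published in-text figures (RRSO cuts ovarian risk
# by ~96%, chemoprevention cuts premenopausal breast-cancer risk by ~30%,
# 80% HT uptake, 16.3% chemoprevention uptake, 3% mortality excess without
# HT); costs are plausible 2021 UK NHS payer figures and utilities sit in
# commonly used ranges. Ranges are 95% CIs for PSA and one-way bounds.
synth_param_table <- function() {
  p <- list(
    c("rrso_oc_multiplier",          0.04,  0.01,  0.10, "beta"),
    c("rrso_bc_multiplier_BRCA1",    1.00,  1.00,  1.00, "fixed"),
    c("rrso_bc_multiplier_BRCA2",    0.56,  0.40,  0.80, "beta"),
    c("rrso_bc_multiplier_PALB2",    0.56,  0.40,  0.80, "beta"),
    c("rrso_bc_multiplier_RAD51C",   1.00,  1.00,  1.00, "fixed"),
    c("rrso_bc_multiplier_RAD51D",   1.00,  1.00,  1.00, "fixed"),
    c("rrso_bc_multiplier_BRIP1",    1.00,  1.00,  1.00, "fixed"),
    c("rrso_acm_multiplier_BRCA1",   0.85,  0.70,  0.99, "beta"),
    c("rrso_acm_multiplier_BRCA2",   0.85,  0.70,  0.99, "beta"),
    c("rrso_acm_multiplier_PALB2",   0.85,  0.70,  0.99, "beta"),
    c("rrso_acm_multiplier_RAD51C",  0.85,  0.70,  0.99, "beta"),
    c("rrso_acm_multiplier_RAD51D",  0.85,  0.70,  0.99, "beta"),
    c("rrso_acm_multiplier_BRIP1",   0.85,  0.70,  0.99, "beta"),
    c("rrm_bc_multiplier",           0.08,  0.05,  0.15, "beta"),
    c("chemoprev_bc_multiplier_pre", 0.70,  0.55,  0.85, "beta"),
    c("chemoprev_bc_multiplier_post",0.50,  0.35,  0.65, "beta"),
    c("chd_mortality_multiplier",    1.03,  1.00,  1.08, "lognormal"),
    c("ht_uptake",                   0.80,  0.60,  0.95, "beta"),
    c("chemoprev_uptake",            0.163, 0.10,  0.25, "beta"),
    c("fp_prob_mri",                 0.08,  0.04,  0.12, "beta"),
    c("fp_prob_mammo",               0.04,  0.02,  0.06, "beta"),
    c("oc_survival_10yr",            0.35,  0.30,  0.40, "beta"),
    c("bc_survival_10yr_high",       0.81,  0.75,  0.87, "beta"),
    c("bc_survival_10yr_moderate",   0.85,  0.80,  0.90, "beta"),
    c("discount_rate",               0.035, 0.035, 0.035, "fixed"),
    c("menopause_age",               51,    51,    51,   "fixed"),
    c("cost_rrso",                   2950,  2065,  3835, "gamma"),
    c("cost_rrm",                    8100,  5670, 10530, "gamma"),
    c("cost_mri",                    181,   127,   235,  "gamma"),
    c("cost_mammo",                  96,    67,    125,  "gamma"),
    c("cost_fp_workup",              450,   315,   585,  "gamma"),
    c("cost_chemoprev_year",         55,    38,    72,   "gamma"),
    c("cost_ht_year",                130,   91,    169,  "gamma"),
    c("cost_chd_year",               180,   126,   234,  "gamma"),
    c("cost_oc_year1",               17500, 12250, 22750, "gamma"),
    c("cost_oc_subseq",              2600,  1820,  3380, "gamma"),
    c("cost_oc_terminal",            9000,  6300, 11700, "gamma"),
    c("cost_bc_year1",               13600, 9520, 17680, "gamma"),
    c("cost_bc_subseq",              1650,  1155,  2145, "gamma"),
    c("cost_bc_terminal",            7800,  5460, 10140, "gamma"),
    c("util_mult_oc",                0.71,  0.64,  0.78, "lognormal"),
    c("util_mult_bc",                0.79,  0.71,  0.87, "lognormal"),
    c("util_mult_oc_survivor",       0.88,  0.79,  0.97, "lognormal"),
    c("util_mult_bc_survivor",       0.92,  0.83,  0.99, "lognormal"),
    c("disutil_rrso",                0.05,  0.045, 0.055, "gamma"),
    c("disutil_rrm",                 0.10,  0.09,  0.11, "gamma"),
    c("disutil_chemoprev",           0.01,  0.009, 0.011, "gamma"),
    c("disutil_screen",              0.006, 0.0054, 0.0066, "gamma"),
    c("disutil_fp",                  0.05,  0.045, 0.055, "gamma"),
    c("disutil_chd",                 0.05,  0.045, 0.055, "gamma"),
    c("brip1_oc_rr",                 BRIP1_RR_BASE, 2.20, 5.54, "lognormal"),
    c("parpi_cost_oc_year1",         38000, 38000, 38000, "fixed"),
    c("parpi_cost_bc_year1",         21000, 21000, 21000, "fixed")
  )
  out <- data.frame(
    name = vapply(p, `[[`, "", 1),
    base = as.numeric(vapply(p, `[[`, "", 2)),
    low = as.numeric(vapply(p, `[[`, "", 3)),
    high = as.numeric(vapply(p, `[[`, "", 4)),
    dist = vapply(p, `[[`, "", 5),
    stringsAsFactors = FALSE
  )
  out$units <- ifelse(startsWith(out$name, "cost_") |
                        startsWith(out$name, "parpi_"), "GBP-2021",
                      ifelse(out$name == "menopause_age", "years",
                             "probability/weight"))
  out
}

# Age-specific healthy-state utility: quadratic decline with age of the form
# used for UK female population norms.
synth_utility_age <- function() {
  ages <- MODEL_AGE_MIN:MODEL_AGE_MAX
  u <- 0.9508566 - 0.0002587 * ages - 0.0000332 * ages^2
  data.frame(age = ages, utility = pmin(pmax(u, 0), 1))
}

#' Generate a complete synthetic parameter set
#'
#' Builds a fully populated, `validate_parameters()`-clean parameter set:
#' per-gene incidence curves calibrated to the target lifetime risks, a
#' Gompertz life table, an age-declining healthy utility curve and the
#' documented scalar defaults (effect sizes, 10-year survival, costs,
#' utilities, disutilities, uptakes). The BRIP1 ovarian curve is the
#' calibrated population curve times the `brip1_oc_rr` relative risk.
#'
#' @param spec A [synthetic_spec()].
#' @return A `parameter_set`.
#' @export
generate_parameter_set <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  tab <- synth_param_table()
  if (spec$jitter) {
    jit <- startsWith(tab$name, "cost_") | startsWith(tab$name, "util_") |
      startsWith(tab$name, "disutil_")
    for (i in which(jit)) {
      lo <- max(tab$low[i], tab$base[i] * 0.9)
      hi <- min(tab$high[i], tab$base[i] * 1.1)
      tab$base[i] <- stats::runif(1, lo, hi)
    }
  }
  lt <- generate_life_table(spec)
  ua <- synth_utility_age()
  tg <- spec$lifetime_targets
  hz <- spec$horizon_age

  pop <- calibrate_incidence(SYNTH_OC_SHAPES$population, tg$population["oc"],
                             gene = "population", cancer = "OC",
                             horizon_age = hz)
  genes <- list()
  for (g in c("BRCA1", "BRCA2", "PALB2", "RAD51C", "RAD51D")) {
    oc <- calibrate_incidence(SYNTH_OC_SHAPES[[g]], tg[[g]]["oc"],
                              gene = g, cancer = "OC", horizon_age = hz)
    bc <- calibrate_incidence(SYNTH_BC_SHAPES[[g]], tg[[g]]["bc"],
                              gene = g, cancer = "BC", horizon_age = hz)
    genes[[g]] <- list(
      gene = g, oc_curve = oc, bc_curve = bc,
      lifetime_oc_risk = unname(tg[[g]]["oc"]),
      lifetime_bc_risk = unname(tg[[g]]["bc"]),
      surveillance_tier = STRATEGY_CATALOG[[g]]$tier
    )
  }
  rr <- tab$base[tab$name == "brip1_oc_rr"]
  brip1_bands <- pop$bands
  brip1_bands$p <- pmin(brip1_bands$p * rr, 0.999)
  brip1 <- incidence_curve("BRIP1", "OC", brip1_bands)
  genes$BRIP1 <- list(
    gene = "BRIP1", oc_curve = brip1, bc_curve = NULL,
    lifetime_oc_risk = cumulative_incidence(brip1, hz),
    lifetime_bc_risk = NULL,
    surveillance_tier = STRATEGY_CATALOG$BRIP1$tier
  )
  new_parameter_set(genes, lt, tab, ua, pop,
                    meta = list(schema_version = 1L,
                                source = "synthetic",
                                seed = spec$seed,
                                horizon_age = hz))
}

#' Closed-form toy fixtures for oracle tests
#'
#' Small explicit Markov configurations (2-6 states, at most 10 cycles) with
#' analytically known discounted life-years/QALYs, used as independent
#' oracles across the test suite.
#'
#' @param name `"geometric-survival"` (alive/dead, q = 0.2, 3 cycles, no
#'   discounting: life-years `1 + 0.8 + 0.64`), `"pure-discount"` (absorbing
#'   alive state, reward 1, 2 cycles at 3.5%: `1 + 1/1.035`) or
#'   `"zero-world"` (no transitions, zero rewards: zero cost and QALYs, the
#'   cohort stays put).
#' @return List with `matrices`, `cost`, `utility`, `init`, `rate`, `alive`
#'   and the `expected` values.
#' @export
toy_fixture <- function(name) {
  known <- c("geometric-survival", "pure-discount", "zero-world")
  name <- match.arg(name, known)
  if (name == "geometric-survival") {
    M <- matrix(c(0.8, 0.2, 0, 1), 2, 2, byrow = TRUE)
    n <- 3
    list(matrices = rep(list(M), n),
         cost = matrix(0, n, 2),
         utility = cbind(rep(1, n), rep(0, n)),
         init = c(1, 0), rate = 0, alive = 1L,
         expected = list(ly = 1 + 0.8 + 0.64, qaly = 1 + 0.8 + 0.64,
                         cost = 0))
  } else if (name == "pure-discount") {
    M <- matrix(1, 1, 1)
    n <- 2
    list(matrices = rep(list(M), n),
         cost = matrix(0, n, 1),
         utility = matrix(1, n, 1),
         init = 1, rate = 0.035, alive = 1L,
         expected = list(ly = 1 + 1 / 1.035, qaly = 1 + 1 / 1.035, cost = 0))
  } else {
    M <- diag(3)
    n <- 5
    list(matrices = rep(list(M), n),
         cost = matrix(0, n, 3),
         utility = matrix(0, n, 3),
         init = c(1, 0, 0), rate = 0, alive = 1:3,
         expected = list(ly = 5, qaly = 0, cost = 0))
  }
}
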