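# Base-case management catalogue: gene-specific surgery ages, surveillance
# tier and chemoprevention start. RAD51C/RAD51D carriers do not undergo RRM
# (breast-cancer risk below the mastectomy threshold); BRIP1 carriers have no
# breast-cancer management at all.
STRATEGY_CATALOG <- list(
  BRCA1  = list(rrm_age = 30L, rrso_age = 35L, tier = "high",     chemo_start = 30L),
  BRCA2  = list(rrm_age = 35L, rrso_age = 40L, tier = "high",     chemo_start = 30L),
  PALB2  = list(rrm_age = 40L, rrso_age = 45L, tier = "high",     chemo_start = 30L),
  RAD51C = list(rrm_age = NA,  rrso_age = 45L, tier = "moderate", chemo_start = 40L),
  RAD51D = list(rrm_age = NA,  rrso_age = 45L, tier = "moderate", chemo_start = 40L),
  BRIP1  = list(rrm_age = NA,  rrso_age = 45L, tier = "none",     chemo_start = NA)
)

CHEMOPREV_YEARS <- 5L
TRIENNIAL_LAST_AGE <- 70L  # national-programme invitations end around age 70

#' Surveillance schedule for a risk tier
#'
#' High tier: annual breast MRI ages 30-49 plus annual mammography ages
#' 40-69. Moderate tier: annual mammography ages 40-59, then one mammogram
#' every third year (ages 60, 63, 66, 69). `"none"`: no imaging.
#'
#' @param tier `"high"`, `"moderate"` or `"none"`.
#' @return Object of class `surveillance_schedule`: a list with the tier and
#'   per-modality integer age vectors `mri` and `mammography`.
#' @export
surveillance_schedule <- function(tier) {
  tier <- match.arg(tier, c("high", "moderate", "none"))
  sched <- switch(tier,
    high = list(mri = 30:49, mammography = 40:69),
    moderate = list(mri = integer(0),
                    mammography = c(40:59, seq(60L, TRIENNIAL_LAST_AGE, by = 3L))),
    none = list(mri = integer(0), mammography = integer(0))
  )
  structure(c(list(tier = tier), sched), class = "surveillance_schedule")
}

#' Construct a management strategy
#'
#' @param label Short strategy label.
#' @param gene Gene the strategy applies to.
#' @param rrm_age Age at risk-reducing mastectomy, or `NA`.
#' @param rrso_age Age at risk-reducing salpingo-oophorectomy, or `NA`.
#' @param tier Breast surveillance tier (see [surveillance_schedule()]).
#' @param chemo_start Start age of the 5-year chemoprevention window, or `NA`.
#' @param reference Is this the gene's reference (comparator) strategy?
#' @return Object of class `strategy`.
#' @export
strategy <- function(label, gene, rrm_age = NA, rrso_age = NA,
                     tier = "none", chemo_start = NA, reference = FALSE) {
  gene <- match.arg(gene, CSG_GENES)
  structure(
    list(label = label, gene = gene,
         rrm_age = as.integer(rrm_age), rrso_age = as.integer(rrso_age),
         surveillance = surveillance_schedule(tier),
         chemo_start = as.integer(chemo_start),
         chemo_years = CHEMOPREV_YEARS,
         reference = isTRUE(reference)),
    class = "strategy"
  )
}

#' Base-case strategies for a gene
#'
#' Reproduces the gene-specific base-case management options: for BRCA1,
#' BRCA2 and PALB2 four arms (high-risk surveillance + chemoprevention as the
#' reference; RRM; RRSO with continued surveillance/chemoprevention; RRM +
#' RRSO); for RAD51C/RAD51D two arms (moderate surveillance + chemoprevention
#' vs adding RRSO at 45); for BRIP1 two arms (no surgery vs RRSO at 45). The
#' first strategy returned is the reference comparator.
#'
#' @param gene Gene name.
#' @return List of [strategy()] objects, reference first.
#' @export
base_strategies <- function(gene) {
  if (!gene %in% CSG_GENES) stop("unknown gene: ", gene)
  cat <- STRATEGY_CATALOG[[gene]]
  tier <- cat$tier
  cs <- cat$chemo_start
  if (gene %in% c("BRCA1", "BRCA2", "PALB2")) {
    list(
      strategy("surveillance", gene, tier = tier, chemo_start = cs,
               reference = TRUE),
      strategy(sprintf("rrm%d", cat$rrm_age), gene, rrm_age = cat$rrm_age,
               tier = tier, chemo_start = cs),
      strategy(sprintf("rrso%d", cat$rrso_age), gene, rrso_age = cat$rrso_age,
               tier = tier, chemo_start = cs),
      strategy(sprintf("rrm%d_rrso%d", cat$rrm_age, cat$rrso_age), gene,
               rrm_age = cat$rrm_age, rrso_age = cat$rrso_age,
               tier = tier, chemo_start = cs)
    )
  } else if (gene %in% c("RAD51C", "RAD51D")) {
    list(
      strategy("surveillance", gene, tier = tier, chemo_start = cs,
               reference = TRUE),
      strategy(sprintf("rrso%d", cat$rrso_age), gene, rrso_age = cat$rrso_age,
               tier = tier, chemo_start = cs)
    )
  } else {
    list(
      strategy("no_surgery", gene, reference = TRUE),
      strategy(sprintf("rrso%d", cat$rrso_age), gene, rrso_age = cat$rrso_age)
    )
  }
}

#' Active effects and scheduled events of a strategy at an age
#'
#' Resolves the strategy timeline at one age: which hazard multipliers are in
#' force (post-RRSO, post-RRM, chemoprevention window) and which events accrue
#' cost/disutility this cycle. Surgery takes effect at the start of the cycle
#' of its scheduled age. Surveillance and chemoprevention generate no events
#' from the RRM age onwards; hormone therapy runs from a premenopausal RRSO
#' until the menopause age.
#'
#' @param strat A [strategy()].
#' @param age Integer age in 30..100.
#' @param menopause_age Average menopause age (default 51).
#' @return Named list: logicals `post_rrso`, `post_rrm`, `chemo_active`,
#'   `rrso_this_year`, `rrm_this_year`, `mri`, `mammography`, `ht_active`,
#'   `chd_exposed`.
#' @export
active_interventions <- function(strat, age, menopause_age = 51) {
  stopifnot(inherits(strat, "strategy"))
  if (age < MODEL_AGE_MIN || age > MODEL_AGE_MAX)
    stop("age outside model range")
  has_rrm <- !is.na(strat$rrm_age)
  has_rrso <- !is.na(strat$rrso_age)
  post_rrm <- has_rrm && age >= strat$rrm_age
  post_rrso <- has_rrso && age >= strat$rrso_age
  before_rrm <- !has_rrm || age < strat$rrm_age
  chemo_active <- !is.na(strat$chemo_start) &&
    age >= strat$chemo_start &&
    age < strat$chemo_start + strat$chemo_years &&
    before_rrm
  premeno_rrso <- has_rrso && strat$rrso_age < menopause_age
  list(
    post_rrso = post_rrso,
    post_rrm = post_rrm,
    chemo_active = chemo_active,
    rrso_this_year = has_rrso && age == strat$rrso_age,
    rrm_this_year = has_rrm && age == strat$rrm_age,
    mri = before_rrm && age %in% strat$surveillance$mri,
    mammography = before_rrm && age %in% strat$surveillance$mammography,
    ht_active = premeno_rrso && post_rrso && age < menopause_age,
    chd_exposed = premeno_rrso && post_rrso
  )
}

SCENARIO_IDS <- c("age_shift", "start_age_35", "ht_40",
                  "no_rrso_mortality_benefit_nonBRCA", "brip1_rr_5.54",
                  "parpi_costs")

#' Scenario specification
#'
#' @param id One of `"age_shift"`, `"start_age_35"`, `"ht_40"`,
#'   `"no_rrso_mortality_benefit_nonBRCA"`, `"brip1_rr_5.54"`,
#'   `"parpi_costs"`.
#' @param ... Scenario payload. `age_shift` takes `gene`, and `rrm_age` and/or
#'   `rrso_age`; `parpi_costs` optionally takes logicals `oc` and `bc`
#'   selecting which treatment costs gain the PARP-inhibitor increment
#'   (default both).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, ...) {
  if (!id %in% SCENARIO_IDS) stop("unknown scenario id: ", id)
  structure(list(id = id, payload = list(...)), class = "scenario_spec")
}

#' Scenario identifiers
#' @return Character vector of supported scenario ids.
#' @export
list_scenarios <- function() SCENARIO_IDS

#' Model configuration
#'
#' Bundles a parameter set with a gene's strategy list and the model entry
#' age; the unit that [apply_scenario()] modifies and [run_cohort()] consumes.
#'
#' @param params A `parameter_set`.
#' @param gene Gene name.
#' @param strategies List of strategies (default [base_strategies()]).
#' @param start_age Model entry age (default 30).
#' @return Object of class `model_config`.
#' @export
model_config <- function(params, gene, strategies = base_strategies(gene),
                         start_age = 30L) {
  gene <- match.arg(gene, CSG_GENES)
  structure(
    list(params = params, gene = gene, strategies = strategies,
         start_age = as.integer(start_age), scenario = NULL),
    class = "model_config"
  )
}

#' Apply a scenario to a model configuration
#'
#' Pure function: returns a modified copy, the input is untouched, so the
#' base configuration is "reverted to" simply by using the original object.
#'
#' @param config A [model_config()].
#' @param scenario A [scenario_spec()].
#' @return Modified `model_config` carrying the scenario id.
#' @export
apply_scenario <- function(config, scenario) {
  stopifnot(inherits(config, "model_config"), inherits(scenario, "scenario_spec"))
  out <- config
  pl <- scenario$payload
  switch(scenario$id,
    age_shift = {
      gene <- if (!is.null(pl$gene)) pl$gene else config$gene
      out$strategies <- lapply(config$strategies, function(s) {
        if (s$gene != gene) return(s)
        if (!is.null(pl$rrm_age) && !is.na(s$rrm_age))
          s$rrm_age <- as.integer(pl$rrm_age)
        if (!is.null(pl$rrso_age) && !is.na(s$rrso_age))
          s$rrso_age <- as.integer(pl$rrso_age)
        s$label <- paste0(s$label, "_shift")
        s
      })
    },
    start_age_35 = {
      out$start_age <- 35L
    },
    ht_40 = {
      out$params <- set_param(config$params, "ht_uptake", 0.40)
    },
    no_rrso_mortality_benefit_nonBRCA = {
      for (g in c("PALB2", "RAD51C", "RAD51D", "BRIP1"))
        out$params <- set_param(out$params,
                                paste0("rrso_acm_multiplier_", g), 1)
    },
    `brip1_rr_5.54` = {
      out$params <- set_param(config$params, "brip1_oc_rr", 5.54)
    },
    parpi_costs = {
      do_oc <- if (is.null(pl$oc)) TRUE else isTRUE(pl$oc)
      do_bc <- if (is.null(pl$bc)) TRUE else isTRUE(pl$bc)
      p <- config$params
      if (do_oc)
        p <- set_param(p, "cost_oc_year1",
                       param_value(p, "cost_oc_year1") +
                         param_value(p, "parpi_cost_oc_year1"))
      if (do_bc && config$gene %in% c("BRCA1", "BRCA2"))
        p <- set_param(p, "cost_bc_year1",
                       param_value(p, "cost_bc_year1") +
                         param_value(p, "parpi_cost_bc_year1"))
      out$params <- p
    }
  )
  out$scenario <- scenario$id
  out
}

#' @export
print.strategy <- function(x, ...) {
  bits <- c(
    if (!is.na(x$rrm_age)) sprintf("RRM@%d", x$rrm_age),
    if (!is.na(x$rrso_age)) sprintf("RRSO@%d", x$rrso_age),
    if (x$surveillance$tier != "none")
      paste0(x$surveillance$tier, "-risk surveillance"),
    if (!is.na(x$chemo_start))
      sprintf("chemoprevention %d-%d", x$chemo_start,
              x$chemo_start + x$chemo_years - 1L)
  )
  if (!length(bits)) bits <- "no intervention"
  cat(sprintf("<strategy> %s [%s]%s: %s\n", x$label, x$gene,
              if (x$reference) " (reference)" else "",
              paste(bits, collapse = ", ")))
  invisible(x)
}
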