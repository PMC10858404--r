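# Health-state space. Ten tunnel years per cancer carry the 10-year excess
# mortality and first/subsequent-year treatment costs; after year 10
# individuals move to a survivor state with background mortality only.
# Ovarian cancer after breast cancer (OB tunnel) is allowed; breast cancer
# after ovarian cancer is not.
N_TUNNEL <- 10L

make_state_names <- function() {
  c("healthy",
    paste0("oc_y", 1:N_TUNNEL),
    paste0("bc_y", 1:N_TUNNEL),
    paste0("oc_after_bc_y", 1:N_TUNNEL),
    "oc_survivor", "bc_survivor",
    "death_oc", "death_bc", "death_other")
}

STATE_NAMES <- make_state_names()
N_STATES <- length(STATE_NAMES)
I_H <- 1L
I_OC <- 1L + 1:N_TUNNEL
I_BC <- 11L + 1:N_TUNNEL
I_OB <- 21L + 1:N_TUNNEL
I_OS <- 32L
I_BS <- 33L
I_DOC <- 34L
I_DBC <- 35L
I_DOTH <- 36L
ALIVE_STATES <- 1:33

#' Health-state labels
#' @return Character vector of the model's 36 state names.
#' @export
state_names <- function() STATE_NAMES

#' Annual cancer-specific excess mortality from 10-year survival
#'
#' Converts a 10-year survival fraction into the constant annual
#' cancer-specific death probability `p` with `(1 - p)^10 = s10`, applied in
#' tunnel years 1-10 on top of background mortality (and 0 afterwards).
#'
#' @param s10 10-year survival fraction in (0, 1].
#' @return Annual excess death probability.
#' @export
annual_excess_mortality <- function(s10) {
  if (any(s10 <= 0) || any(s10 > 1))
    stop("10-year survival must lie in (0, 1]")
  1 - s10^(1 / N_TUNNEL)
}

#' Effective annual incidence under active interventions
#'
#' Multiplies a base annual incidence by each active hazard multiplier.
#' A multiplier taken up by only a fraction `u` of the cohort contributes its
#' expectation `u * m + (1 - u)`.
#'
#' @param base_p Base annual probability in [0, 1).
#' @param multipliers Numeric vector of hazard multipliers (>= 0).
#' @param uptakes Uptake fraction per multiplier (default full uptake).
#' @return Effective annual probability.
#' @export
effective_incidence <- function(base_p, multipliers = numeric(0),
                                uptakes = rep(1, length(multipliers))) {
  if (base_p < 0 || base_p >= 1) stop("base probability outside [0, 1)")
  if (any(multipliers < 0)) stop("hazard multipliers must be >= 0")
  if (length(uptakes) != length(multipliers))
    stop("one uptake per multiplier required")
  m <- prod(uptakes * multipliers + (1 - uptakes))
  p <- base_p * m
  if (p < 0 || p >= 1)
    stop("effective incidence outside [0, 1): base ", base_p,
         ", combined multiplier ", m)
  p
}

#' Background all-cause mortality under active modifiers
#'
#' Applies (i) the post-RRSO all-cause mortality multiplier for cancer-free
#' women and (ii) the expected coronary-heart-disease excess for the fraction
#' not taking hormone therapy after a premenopausal RRSO; result capped at 1.
#'
#' @param qx Life-table annual death probability.
#' @param rrso_acm_multiplier All-cause multiplier while cancer-free
#'   post-RRSO (1 when not applicable).
#' @param premenopausal_rrso Is the woman past a premenopausal RRSO?
#' @param ht_uptake Hormone-therapy uptake fraction.
#' @param chd_multiplier Mortality multiplier without hormone therapy.
#' @return Modified annual death probability.
#' @export
background_mortality <- function(qx, rrso_acm_multiplier = 1,
                                 premenopausal_rrso = FALSE, ht_uptake = 1,
                                 chd_multiplier = 1.03) {
  if (any(qx < 0) || any(qx > 1)) stop("qx outside [0, 1]")
  m_chd <- if (premenopausal_rrso)
    ht_uptake + (1 - ht_uptake) * chd_multiplier else 1
  pmin(qx * rrso_acm_multiplier * m_chd, 1)
}

# Precompute everything a cohort run needs for one gene x strategy x
# parameter set: a fast named-vector parameter lookup, per-age incidence and
# mortality, and the healthy-utility curve. Avoids repeated data-frame
# lookups in the per-cycle loop.
model_context <- function(gene, strat, params) {
  pvec <- params$params$base
  names(pvec) <- params$params$name
  oc_curve <- gene_oc_curve(params, gene)
  bc_curve <- gene_bc_curve(params, gene)
  ages <- MODEL_AGE_MIN:MODEL_AGE_MAX
  list(
    gene = gene, strat = strat, pvec = pvec,
    ages = ages,
    oc_p = oc_curve$p,
    bc_p = if (!is.null(bc_curve)) bc_curve$p,
    qx = life_table_qx(params, ages),
    u_age = healthy_utility(params, ages),
    moderate_bc = identical(params$genes[[gene]]$surveillance_tier, "moderate")
  )
}

# Per-age hazard ingredients for one gene x strategy: where strategy timing,
# gene profile and parameters meet.
cycle_inputs <- function(ctx, age) {
  pv <- ctx$pvec
  strat <- ctx$strat
  meno <- pv[["menopause_age"]]
  act <- active_interventions(strat, age, menopause_age = meno)
  ai <- age - MODEL_AGE_MIN + 1L
  qx_raw <- ctx$qx[ai]

  ht_u <- pv[["ht_uptake"]]
  chd_m <- pv[["chd_mortality_multiplier"]]
  # CHD exposure persists for the never-HT fraction; RRSO survival benefit is
  # restricted to cancer-free (healthy) occupants.
  q_healthy <- background_mortality(
    qx_raw,
    rrso_acm_multiplier = if (act$post_rrso)
      pv[[paste0("rrso_acm_multiplier_", ctx$gene)]] else 1,
    premenopausal_rrso = act$chd_exposed,
    ht_uptake = ht_u, chd_multiplier = chd_m
  )
  q_cancer <- background_mortality(
    qx_raw, premenopausal_rrso = act$chd_exposed,
    ht_uptake = ht_u, chd_multiplier = chd_m
  )

  p_oc <- effective_incidence(
    ctx$oc_p[ai],
    multipliers = if (act$post_rrso) pv[["rrso_oc_multiplier"]] else numeric(0)
  )

  if (is.null(ctx$bc_p)) {
    p_bc <- 0
  } else {
    mult <- numeric(0); upt <- numeric(0)
    if (act$post_rrm) {
      mult <- c(mult, pv[["rrm_bc_multiplier"]]); upt <- c(upt, 1)
    }
    if (act$post_rrso && !is.na(strat$rrso_age) && strat$rrso_age < meno) {
      mult <- c(mult, pv[[paste0("rrso_bc_multiplier_", ctx$gene)]])
      upt <- c(upt, 1)
    }
    if (act$chemo_active) {
      m <- if (age < meno) pv[["chemoprev_bc_multiplier_pre"]]
           else pv[["chemoprev_bc_multiplier_post"]]
      mult <- c(mult, m); upt <- c(upt, pv[["chemoprev_uptake"]])
    }
    p_bc <- effective_incidence(ctx$bc_p[ai], mult, upt)
  }

  d_oc <- annual_excess_mortality(pv[["oc_survival_10yr"]])
  d_bc <- annual_excess_mortality(
    if (ctx$moderate_bc) pv[["bc_survival_10yr_moderate"]]
    else pv[["bc_survival_10yr_high"]]
  )

  list(act = act, q_healthy = q_healthy, q_cancer = q_cancer,
       p_oc = p_oc, p_bc = p_bc, d_oc = d_oc, d_bc = d_bc,
       ht_uptake = ht_u)
}

#' Build the one-year transition matrix at an age
#'
#' Competing risks within a cycle are resolved by sequential conditioning in
#' the order death, then ovarian cancer, then breast cancer. From breast
#' tunnel and survivor states, ovarian cancer entry remains possible; breast
#' cancer after ovarian cancer is excluded. Tunnel year 10 advances to the
#' survivor state. Death states are absorbing.
#'
#' @param gene Gene name.
#' @param strat A [strategy()].
#' @param params A `parameter_set`.
#' @param age Integer age in 30..100.
#' @return `36 x 36` matrix of transition probabilities; rows sum to 1.
#' @export
build_transition_matrix <- function(gene, strat, params, age) {
  ctx <- model_context(gene, strat, params)
  M <- assemble_matrix(cycle_inputs(ctx, age), age)
  dimnames(M) <- list(STATE_NAMES, STATE_NAMES)
  M
}

assemble_matrix <- function(ci, age) {
  M <- matrix(0, N_STATES, N_STATES)

  # healthy
  qh <- ci$q_healthy
  M[I_H, I_DOTH] <- qh
  M[I_H, I_OC[1]] <- (1 - qh) * ci$p_oc
  M[I_H, I_BC[1]] <- (1 - qh) * (1 - ci$p_oc) * ci$p_bc
  M[I_H, I_H] <- (1 - qh) * (1 - ci$p_oc) * (1 - ci$p_bc)

  qc <- ci$q_cancer
  for (k in 1:N_TUNNEL) {
    nxt_oc <- if (k < N_TUNNEL) I_OC[k + 1] else I_OS
    M[I_OC[k], I_DOTH] <- qc
    M[I_OC[k], I_DOC] <- (1 - qc) * ci$d_oc
    M[I_OC[k], nxt_oc] <- (1 - qc) * (1 - ci$d_oc)

    nxt_bc <- if (k < N_TUNNEL) I_BC[k + 1] else I_BS
    rem <- (1 - qc) * (1 - ci$d_bc)
    M[I_BC[k], I_DOTH] <- qc
    M[I_BC[k], I_DBC] <- (1 - qc) * ci$d_bc
    M[I_BC[k], I_OB[1]] <- M[I_BC[k], I_OB[1]] + rem * ci$p_oc
    M[I_BC[k], nxt_bc] <- M[I_BC[k], nxt_bc] + rem * (1 - ci$p_oc)

    nxt_ob <- if (k < N_TUNNEL) I_OB[k + 1] else I_OS
    M[I_OB[k], I_DOTH] <- qc
    M[I_OB[k], I_DOC] <- (1 - qc) * ci$d_oc
    M[I_OB[k], nxt_ob] <- M[I_OB[k], nxt_ob] + (1 - qc) * (1 - ci$d_oc)
  }

  M[I_OS, I_DOTH] <- qc
  M[I_OS, I_OS] <- 1 - qc
  M[I_BS, I_DOTH] <- qc
  M[I_BS, I_OB[1]] <- (1 - qc) * ci$p_oc
  M[I_BS, I_BS] <- (1 - qc) * (1 - ci$p_oc)

  M[I_DOC, I_DOC] <- 1
  M[I_DBC, I_DBC] <- 1
  M[I_DOTH, I_DOTH] <- 1

  if (any(M < -1e-12))
    stop("negative transition probability at age ", age, ", state ",
         STATE_NAMES[which(M < -1e-12, arr.ind = TRUE)[1, 1]])
  M
}

#' Per-cycle cost and utility of a state at an age
#'
#' Utility is the age-specific healthy utility times the state multiplier,
#' minus additive disutilities for intervention events active this cycle
#' (surgery year, screening attendance, expected false-positive workup,
#' chemoprevention year, expected coronary-heart-disease decrement for the
#' non-HT fraction). Intervention costs and disutilities accrue to healthy
#' occupants; cancer states carry first-year, subsequent-year or survivor
#' treatment costs. Terminal-care costs attach to the transition into a
#' cancer death state and are handled by [run_cohort()], not here.
#'
#' @param state State name (see [state_names()]).
#' @param age Integer age in 30..100.
#' @param strat A [strategy()].
#' @param params A `parameter_set`.
#' @return Named list `cost` (GBP this cycle) and `utility` (QALY weight).
#' @export
cycle_reward <- function(state, age, strat, params) {
  i <- match(state, STATE_NAMES)
  if (is.na(i)) stop("unknown state: ", state)
  rw <- reward_vectors(model_context(strat$gene, strat, params), age)
  list(cost = rw$cost[i], utility = rw$utility[i])
}

# Cost and utility vectors over all states for one cycle.
reward_vectors <- function(ctx, age) {
  pvec <- ctx$pvec
  pv <- function(nm) pvec[[nm]]
  strat <- ctx$strat
  act <- active_interventions(strat, age, menopause_age = pv("menopause_age"))
  u_age <- ctx$u_age[age - MODEL_AGE_MIN + 1L]
  ht_u <- pv("ht_uptake")

  cost <- numeric(N_STATES)
  util <- numeric(N_STATES)

  # healthy-state intervention events
  h_cost <- 0; h_dis <- 0
  if (act$rrso_this_year) { h_cost <- h_cost + pv("cost_rrso"); h_dis <- h_dis + pv("disutil_rrso") }
  if (act$rrm_this_year)  { h_cost <- h_cost + pv("cost_rrm");  h_dis <- h_dis + pv("disutil_rrm") }
  if (act$mri) {
    h_cost <- h_cost + pv("cost_mri") + pv("fp_prob_mri") * pv("cost_fp_workup")
    h_dis <- h_dis + pv("fp_prob_mri") * pv("disutil_fp")
  }
  if (act$mammography) {
    h_cost <- h_cost + pv("cost_mammo") + pv("fp_prob_mammo") * pv("cost_fp_workup")
    h_dis <- h_dis + pv("fp_prob_mammo") * pv("disutil_fp")
  }
  if (act$mri || act$mammography) h_dis <- h_dis + pv("disutil_screen")
  if (act$chemo_active) {
    u <- pv("chemoprev_uptake")
    h_cost <- h_cost + u * pv("cost_chemoprev_year")
    h_dis <- h_dis + u * pv("disutil_chemoprev")
  }
  if (act$ht_active) h_cost <- h_cost + ht_u * pv("cost_ht_year")
  if (act$chd_exposed) {
    h_cost <- h_cost + (1 - ht_u) * pv("cost_chd_year")
    h_dis <- h_dis + (1 - ht_u) * pv("disutil_chd")
  }
  cost[I_H] <- h_cost
  util[I_H] <- u_age - h_dis

  cost[I_OC[1]] <- pv("cost_oc_year1")
  cost[I_OC[2:N_TUNNEL]] <- pv("cost_oc_subseq")
  cost[I_BC[1]] <- pv("cost_bc_year1")
  cost[I_BC[2:N_TUNNEL]] <- pv("cost_bc_subseq")
  cost[I_OB[1]] <- pv("cost_oc_year1")
  cost[I_OB[2:N_TUNNEL]] <- pv("cost_oc_subseq")

  util[I_OC] <- u_age * pv("util_mult_oc")
  util[I_BC] <- u_age * pv("util_mult_bc")
  util[I_OB] <- u_age * pv("util_mult_oc")
  util[I_OS] <- u_age * pv("util_mult_oc_survivor")
  util[I_BS] <- u_age * pv("util_mult_bc_survivor")

  if (any(util < -1 | util > 1))
    stop("state utility outside [-1, 1] at age ", age)
  list(cost = cost, utility = util)
}

# Generic discounted cohort propagation over explicit matrices and rewards.
# Shared by run_cohort and the toy fixtures so the path-enumeration oracle
# exercises exactly the accumulation the full model uses.
#
# matrices: list of n transition matrices; cost/utility: n x S matrices of
# per-cycle state rewards; terminal_cost: per-state cost attached to new
# inflow into that state, discounted at the transition cycle's factor;
# alive: indices counted as alive for life-years; rate: annual discount rate;
# half_cycle: average start/end occupancy for reward accrual.
markov_run <- function(matrices, cost, utility, init, rate,
                       terminal_cost = NULL, alive = seq_along(init),
                       half_cycle = FALSE) {
  n <- length(matrices)
  S <- length(init)
  occ <- init
  trace <- matrix(NA_real_, n + 1L, S)
  trace[1L, ] <- occ
  tot_cost <- 0; tot_qaly <- 0; tot_ly <- 0
  inflow <- matrix(0, n, S)
  for (t in seq_len(n)) {
    M <- matrices[[t]]
    occ_next <- as.numeric(occ %*% M)
    new_in <- occ_next - occ * diag(M)  # inflow excludes self-loops
    inflow[t, ] <- new_in
    disc <- (1 + rate)^(-(t - 1L))
    w <- if (half_cycle) (occ + occ_next) / 2 else occ
    tot_cost <- tot_cost + disc * sum(w * cost[t, ])
    tot_qaly <- tot_qaly + disc * sum(w * utility[t, ])
    tot_ly <- tot_ly + disc * sum(w[alive])
    if (!is.null(terminal_cost))
      tot_cost <- tot_cost + disc * sum(new_in * terminal_cost)
    occ <- occ_next
    trace[t + 1L, ] <- occ
  }
  list(cost = tot_cost, qaly = tot_qaly, ly = tot_ly,
       trace = trace, inflow = inflow)
}

#' Run the cohort simulation for one strategy
#'
#' Propagates a cohort of healthy women from the model entry age to age 100
#' in annual cycles, accruing discounted costs, QALYs and life-years
#' (discount factor `(1 + r)^-t`, `t = 0` for the first cycle) and
#' undiscounted cancer event counts scaled per 1000 carriers.
#'
#' @param gene Gene name.
#' @param strat A [strategy()] (or a `model_config`, in which case `params`
#'   and `start_age` are taken from it and `strat` selects by label or index).
#' @param params A `parameter_set`.
#' @param start_age Model entry age (default 30).
#' @param end_age Horizon age (default 100; the final cycle is absorbing).
#' @param half_cycle Apply a half-cycle correction to reward accrual
#'   (default `FALSE`: rewards follow start-of-cycle occupancy).
#' @return Object of class `cohort_result` with elements `cost`, `qalys`,
#'   `life_years`, `events` (per-1000 counts: `oc_cases`, `bc_cases`,
#'   `oc_deaths`, `bc_deaths`), `trace` (occupancy, cycles x states) and
#'   `event_series` (per-cycle new events).
#' @export
run_cohort <- function(gene, strat, params, start_age = 30L,
                       end_age = MODEL_AGE_MAX, half_cycle = FALSE) {
  gene <- match.arg(gene, CSG_GENES)
  stopifnot(inherits(strat, "strategy"), inherits(params, "parameter_set"))
  if (start_age < MODEL_AGE_MIN || end_age > MODEL_AGE_MAX || start_age >= end_age)
    stop("invalid age range")
  # annual cycles cover ages start..(end_age - 1); the trace's final row is
  # the occupancy snapshot at the horizon age
  ages <- seq.int(start_age, end_age - 1L)
  n <- length(ages)

  ctx <- model_context(gene, strat, params)
  matrices <- vector("list", n)
  cost <- matrix(0, n, N_STATES)
  util <- matrix(0, n, N_STATES)
  for (t in seq_len(n)) {
    matrices[[t]] <- assemble_matrix(cycle_inputs(ctx, ages[t]), ages[t])
    rw <- reward_vectors(ctx, ages[t])
    cost[t, ] <- rw$cost
    util[t, ] <- rw$utility
  }
  terminal <- numeric(N_STATES)
  terminal[I_DOC] <- param_value(params, "cost_oc_terminal")
  terminal[I_DBC] <- param_value(params, "cost_bc_terminal")

  init <- numeric(N_STATES); init[I_H] <- 1
  r <- param_value(params, "discount_rate")
  out <- markov_run(matrices, cost, util, init, r,
                    terminal_cost = terminal, alive = ALIVE_STATES,
                    half_cycle = half_cycle)

  inflow <- out$inflow
  ev <- data.frame(
    age = ages,
    oc_cases = inflow[, I_OC[1]] + inflow[, I_OB[1]],
    bc_cases = inflow[, I_BC[1]],
    oc_deaths = inflow[, I_DOC],
    bc_deaths = inflow[, I_DBC]
  )
  events <- 1000 * c(
    oc_cases = sum(ev$oc_cases), bc_cases = sum(ev$bc_cases),
    oc_deaths = sum(ev$oc_deaths), bc_deaths = sum(ev$bc_deaths)
  )
  trace <- out$trace
  dimnames(trace) <- list(NULL, STATE_NAMES)
  structure(
    list(gene = gene, strategy = strat$label, reference = strat$reference,
         start_age = start_age, cost = out$cost, qalys = out$qaly,
         life_years = out$ly, events = events,
         trace = trace, event_series = ev,
         settings = list(discount_rate = r, half_cycle = half_cycle,
                         end_age = end_age)),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s / %s (entry age %d)\n", x$gene, x$strategy,
              x$start_age))
  cat(sprintf("  discounted cost %.0f GBP, QALYs %.3f, life-years %.3f\n",
              x$cost, x$qalys, x$life_years))
  cat(sprintf("  per 1000: OC cases %.1f, BC cases %.1f, OC deaths %.1f, BC deaths %.1f\n",
              x$events["oc_cases"], x$events["bc_cases"],
              x$events["oc_deaths"], x$events["bc_deaths"]))
  invisible(x)
}

#' @export
summary.cohort_result <- function(object, ...) {
  alive <- rowSums(object$trace[, ALIVE_STATES])
  data.frame(
    gene = object$gene, strategy = object$strategy,
    cost = object$cost, qalys = object$qalys, life_years = object$life_years,
    oc_cases_per_1000 = object$events["oc_cases"],
    bc_cases_per_1000 = object$events["bc_cases"],
    oc_deaths_per_1000 = object$events["oc_deaths"],
    bc_deaths_per_1000 = object$events["bc_deaths"],
    prop_alive_end = alive[length(alive)],
    row.names = NULL
  )
}
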