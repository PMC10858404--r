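# Shared fixtures and independent oracles.

# One synthetic parameter set per test session (generation involves root
# finding; cache it).
default_ps <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- generate_parameter_set(synthetic_spec(seed = 42L))
    ps
  }
})

# A parameter set with overridden incidence curves / life table / scalar
# values, for hand-checkable configurations.
override_ps <- function(ps = default_ps(), qx = NULL, oc_p = NULL, bc_p = NULL,
                        gene = "BRCA2", set = list()) {
  if (!is.null(qx)) ps$life_table$qx <- rep(qx, nrow(ps$life_table))
  flat <- function(p, cancer) incidence_curve(
    gene, cancer, data.frame(age_lo = 30, age_hi = 100, p = p))
  if (!is.null(oc_p)) {
    ps$genes[[gene]]$oc_curve <- flat(oc_p, "OC")
    if (gene == "BRIP1") {
      ps$population_oc_curve <- flat(oc_p, "OC")
      ps$params$base[ps$params$name == "brip1_oc_rr"] <- 1
    }
  }
  if (!is.null(bc_p) && gene != "BRIP1")
    ps$genes[[gene]]$bc_curve <- flat(bc_p, "BC")
  for (nm in names(set))
    ps$params$base[ps$params$name == nm] <- set[[nm]]
  ps
}

# A do-nothing strategy (no surgery, no surveillance, no chemoprevention).
null_strategy <- function(gene = "BRCA2")
  strategy("none", gene, tier = "none", reference = TRUE)

# Exhaustive path-enumeration oracle for expected discounted cost/QALY/LY of
# a small Markov chain: sums over every state path, independently of the
# matrix-product propagation in the engine.
enumerate_expected <- function(matrices, cost, utility, init, rate,
                               alive = seq_along(init)) {
  S <- length(init)
  n <- length(matrices)
  tot <- c(cost = 0, qaly = 0, ly = 0)
  rec <- function(t, s, prob) {
    if (prob == 0) return(invisible())
    disc <- (1 + rate)^(-(t - 1))
    tot["cost"] <<- tot["cost"] + prob * disc * cost[t, s]
    tot["qaly"] <<- tot["qaly"] + prob * disc * utility[t, s]
    if (s %in% alive) tot["ly"] <<- tot["ly"] + prob * disc
    if (t < n) {
      M <- matrices[[t]]
      for (s2 in seq_len(S)) rec(t + 1L, s2, prob * M[s, s2])
    } else {
      invisible()
    }
  }
  for (s in seq_len(S)) rec(1L, s, init[s])
  tot
}

# Random small transition matrices (rows sum to 1) for oracle tests.
random_chain <- function(S, n, seed) {
  set.seed(seed)
  matrices <- replicate(n, {
    M <- matrix(stats::rexp(S * S), S, S)
    M / rowSums(M)
  }, simplify = FALSE)
  list(matrices = matrices,
       cost = matrix(stats::runif(n * S, 0, 100), n, S),
       utility = matrix(stats::runif(n * S, 0, 1), n, S),
       init = { v <- stats::runif(S); v / sum(v) })
}

# Independent frontier oracle: a strategy lies on the cost-effectiveness
# frontier iff it attains the maximum net benefit w*qaly - cost for some
# willingness-to-pay w >= 0. The exact candidate set of w values where the
# argmax can change is the set of pairwise slopes, so testing at those
# breakpoints' midpoints plus the extremes is exhaustive.
frontier_oracle <- function(cost, qalys) {
  n <- length(cost)
  slopes <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dq <- qalys[i] - qalys[j]
    if (abs(dq) > 0) {
      s <- (cost[i] - cost[j]) / dq
      if (s >= 0) slopes <- c(slopes, s)
    }
  }
  ws <- sort(unique(c(0, slopes)))
  test_w <- unique(c(ws, (ws[-1] + ws[-length(ws)]) / 2, max(ws) * 2 + 1))
  on_frontier <- rep(FALSE, n)
  for (w in test_w) {
    nb <- w * qalys - cost
    on_frontier[abs(nb - max(nb)) < 1e-9] <- TRUE
  }
  on_frontier
}
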