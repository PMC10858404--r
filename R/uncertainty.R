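#' Fit a sampling distribution to a parameter by method of moments
#'
#' The mean is the base value; when no standard error is given the
#' (low, high) range is treated as a 95% confidence interval, so
#' `s = (high - low) / 3.92`. Families: gamma `shape = (m/s)^2`,
#' `rate = m/s^2`; beta `nu = m(1-m)/s^2 - 1`, `alpha = m nu`,
#' `beta = (1-m) nu`; log-normal matched so the distribution's mean is `m`
#' and variance `s^2`. Zero spread yields a degenerate (`fixed`) spec that
#' samples exactly the base value.
#'
#' @param base Mean (base-case) value.
#' @param low,high Uncertainty range, read as a 95% CI.
#' @param dist `"gamma"`, `"beta"`, `"lognormal"` or `"fixed"`.
#' @param name Optional parameter name carried through for error messages.
#' @return Object of class `dist_spec` with `family`, `pars` and `base`.
#' @export
fit_distribution <- function(base, low = base, high = base, dist = "fixed",
                             name = NULL) {
  dist <- match.arg(dist, DIST_FAMILIES)
  m <- base
  s <- (high - low) / 3.92
  lbl <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (dist == "fixed" || s <= 0 || isTRUE(all.equal(s, 0)))
    return(structure(list(family = "fixed", pars = list(), base = base,
                          name = name), class = "dist_spec"))
  pars <- switch(dist,
    gamma = {
      if (m <= 0) stop("gamma distribution needs a positive mean", lbl)
      list(shape = (m / s)^2, rate = m / s^2)
    },
    beta = {
      if (m <= 0 || m >= 1)
        stop("beta distribution needs mean in (0, 1)", lbl)
      nu <- m * (1 - m) / s^2 - 1
      if (nu <= 0)
        stop("beta variance too large for the mean", lbl)
      list(alpha = m * nu, beta = (1 - m) * nu)
    },
    lognormal = {
      if (m <= 0) stop("log-normal distribution needs a positive mean", lbl)
      sigma2 <- log(1 + s^2 / m^2)
      list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    }
  )
  structure(list(family = dist, pars = pars, base = base, name = name),
            class = "dist_spec")
}

#' Sample from a fitted distribution spec
#'
#' Uses the session RNG; callers seed once for reproducibility.
#'
#' @param spec A [fit_distribution()] result.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_distribution <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    fixed = rep(spec$base, n),
    gamma = stats::rgamma(n, shape = spec$pars$shape, rate = spec$pars$rate),
    beta = stats::rbeta(n, spec$pars$alpha, spec$pars$beta),
    lognormal = stats::rlnorm(n, spec$pars$meanlog, spec$pars$sdlog)
  )
}

# Analytic mean and variance of a dist_spec (used by the moment round-trip
# tests).
dist_moments <- function(spec) {
  switch(spec$family,
    fixed = c(mean = spec$base, var = 0),
    gamma = c(mean = spec$pars$shape / spec$pars$rate,
              var = spec$pars$shape / spec$pars$rate^2),
    beta = {
      a <- spec$pars$alpha; b <- spec$pars$beta
      c(mean = a / (a + b), var = a * b / ((a + b)^2 * (a + b + 1)))
    },
    lognormal = {
      mu <- spec$pars$meanlog; s2 <- spec$pars$sdlog^2
      m <- exp(mu + s2 / 2)
      c(mean = m, var = (exp(s2) - 1) * m^2)
    }
  )
}

#' Draw one probabilistic parameter set
#'
#' Replaces the base value of every non-fixed scalar parameter by an
#' independent draw from its fitted distribution. Draw order is fixed by
#' sorted parameter name so results are reproducible for a given RNG state.
#' Structural settings (life table, incidence curves, age-utility curve) are
#' untouched.
#'
#' @param params A `parameter_set`.
#' @return A `parameter_set` with sampled base values.
#' @export
sample_parameter_set <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  out <- params
  ord <- order(params$params$name)
  for (i in ord) {
    row <- params$params[i, ]
    spec <- fit_distribution(row$base, row$low, row$high, row$dist,
                             name = row$name)
    if (spec$family != "fixed")
      out$params$base[i] <- sample_distribution(spec, 1)
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Samples all scalar parameters simultaneously from their assigned
#' distributions and reruns the cohort model for every strategy, storing the
#' per-draw discounted (cost, QALY) pair. Draws producing invalid transition
#' probabilities are rejected, logged and redrawn.
#'
#' @param config A [model_config()].
#' @param n Number of draws (default 10 000).
#' @param seed RNG seed; identical seeds reproduce results exactly.
#' @param progress_every Emit a progress message every this many draws
#'   (`0` silences; default 1000).
#' @return Object of class `psa_result`: `draws` data frame (`draw`,
#'   `strategy`, `cost`, `qaly`), `n`, `seed`, `rejections`.
#' @export
run_psa <- function(config, n = 10000, seed = 1L, progress_every = 1000L) {
  stopifnot(inherits(config, "model_config"))
  if (n < 1) stop("at least one draw required")
  set.seed(seed)
  labels <- vapply(config$strategies, `[[`, "", "label")
  res <- vector("list", n)
  rejections <- 0L
  max_rejections <- 100L + n
  for (d in seq_len(n)) {
    repeat {
      ps <- sample_parameter_set(config$params)
      runs <- tryCatch(
        lapply(config$strategies, function(s)
          run_cohort(config$gene, s, ps, start_age = config$start_age)),
        error = function(e) e
      )
      if (!inherits(runs, "error")) break
      rejections <- rejections + 1L
      if (rejections > max_rejections)
        stop("too many rejected PSA draws; last error: ",
             conditionMessage(runs))
    }
    res[[d]] <- data.frame(
      draw = d, strategy = labels,
      cost = vapply(runs, `[[`, 0, "cost"),
      qaly = vapply(runs, `[[`, 0, "qalys"),
      stringsAsFactors = FALSE
    )
    if (progress_every > 0 && d %% progress_every == 0)
      message("PSA draw ", d, "/", n)
  }
  structure(
    list(draws = do.call(rbind, res), n = n, seed = seed,
         rejections = rejections, gene = config$gene,
         labels = labels),
    class = "psa_result"
  )
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that each strategy
#' attains the maximum net monetary benefit across PSA draws (ties split
#' equally). Probabilities sum to 1 at every threshold.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay grid (default 0 to 50 000 by 1 000).
#' @return Object of class `ceac`: data frame `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(psa, "psa_result"))
  dr <- psa$draws
  labels <- psa$labels
  cost <- matrix(dr$cost, nrow = length(labels))
  qaly <- matrix(dr$qaly, nrow = length(labels))
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qaly - cost
    wins <- numeric(length(labels))
    for (d in seq_len(ncol(nmb))) {
      mx <- max(nmb[, d])
      top <- which(nmb[, d] >= mx - 1e-9)
      wins[top] <- wins[top] + 1 / length(top)
    }
    data.frame(wtp = w, strategy = labels,
               probability = wins / ncol(nmb), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("ceac", "data.frame"))
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s: %d draws (seed %s, %d rejected)\n",
              x$gene, x$n, format(x$seed), x$rejections))
  agg <- stats::aggregate(cbind(cost, qaly) ~ strategy, data = x$draws, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x A [ceac()] result (or a `psa_result`, converted on the fly).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ceac <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x), idvar = "wtp",
                         timevar = "strategy", direction = "wide")
  graphics::matplot(wide$wtp, as.matrix(wide[, -1]), type = "l", lty = 1,
                    xlab = "Willingness-to-pay (GBP/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("right", legend = sub("^probability\\.", "",
                                         names(wide)[-1]),
                   lty = 1, col = seq_len(ncol(wide) - 1), cex = 0.8)
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) plot(ceac(x), ...)

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER against the reference strategy and the net monetary
#' benefit of a designated strategy with each parameter set to its low and
#' high value in turn, all else at base. Parameters without a stated range
#' default to +/-10% (probabilities, multipliers, utilities) or +/-30%
#' (costs).
#'
#' @param config A [model_config()].
#' @param strategy_label Strategy to evaluate (default: highest-QALY
#'   non-reference strategy).
#' @param parameters Parameter names to vary (default: all non-fixed).
#' @param wtp Willingness-to-pay threshold for NMB.
#' @return Object of class `owsa_result`: data frame `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `nmb_low`, `nmb_high`, `nmb_spread`,
#'   sorted by decreasing spread.
#' @export
owsa <- function(config, strategy_label = NULL, parameters = NULL,
                 wtp = 20000) {
  stopifnot(inherits(config, "model_config"))
  labels <- vapply(config$strategies, `[[`, "", "label")
  ref_i <- which(vapply(config$strategies, function(s) isTRUE(s$reference), TRUE))
  if (length(ref_i) != 1) ref_i <- 1L
  if (is.null(strategy_label)) {
    base_runs <- lapply(config$strategies, function(s)
      run_cohort(config$gene, s, config$params, start_age = config$start_age))
    qal <- vapply(base_runs, `[[`, 0, "qalys")
    qal[ref_i] <- -Inf
    strategy_label <- labels[which.max(qal)]
  }
  s_i <- match(strategy_label, labels)
  if (is.na(s_i)) stop("unknown strategy label: ", strategy_label)

  if (is.null(parameters)) {
    keep <- config$params$params$dist != "fixed"
    parameters <- config$params$params$name[keep]
  }

  eval_pair <- function(ps) {
    s <- run_cohort(config$gene, config$strategies[[s_i]], ps,
                    start_age = config$start_age)
    r <- run_cohort(config$gene, config$strategies[[ref_i]], ps,
                    start_age = config$start_age)
    c(icer = as.numeric(icer(s, r)), nmb = nmb(s, wtp))
  }

  rows <- lapply(parameters, function(nm) {
    row <- param_row(config$params, nm)
    lo <- row$low; hi <- row$high
    if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
      frac <- if (startsWith(nm, "cost_") || startsWith(nm, "parpi_")) 0.3 else 0.1
      lo <- row$base * (1 - frac); hi <- row$base * (1 + frac)
    }
    vlo <- eval_pair(set_param(config$params, nm, lo))
    vhi <- eval_pair(set_param(config$params, nm, hi))
    data.frame(parameter = nm, low = lo, high = hi,
               icer_low = vlo["icer"], icer_high = vhi["icer"],
               nmb_low = vlo["nmb"], nmb_high = vhi["nmb"],
               nmb_spread = abs(vhi["nmb"] - vlo["nmb"]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nmb_spread), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("owsa_result", "data.frame"),
            strategy = strategy_label, wtp = wtp, gene = config$gene)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param x An [owsa()] result.
#' @param top Number of parameters to show (default 15).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.owsa_result <- function(x, top = 15, ...) {
  d <- utils::head(as.data.frame(x), top)
  d <- d[order(d$nmb_spread), ]
  base_mid <- (d$nmb_low + d$nmb_high) / 2
  rng <- range(c(d$nmb_low, d$nmb_high))
  graphics::barplot(rep(0, nrow(d)), horiz = TRUE, xlim = rng,
                    names.arg = d$parameter, las = 1, cex.names = 0.6,
                    main = paste("Tornado:", attr(x, "strategy")), ...)
  for (i in seq_len(nrow(d)))
    graphics::segments(d$nmb_low[i], i * 1.2 - 0.5, d$nmb_high[i],
                       i * 1.2 - 0.5, lwd = 8, col = "steelblue")
  graphics::abline(v = base_mid[1], lty = 2)
  invisible(x)
}
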