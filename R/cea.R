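#' Incremental cost-effectiveness ratio
#'
#' `(cost_s - cost_ref) / (qaly_s - qaly_ref)` in GBP per QALY. Results may
#' legitimately be negative (cost-saving with a QALY gain, reported as-is).
#' When the QALY difference is below `1e-9` the comparison is flagged
#' `"equal-effect"` and `NA` is returned.
#'
#' @param result,reference `cohort_result` objects (or any lists carrying
#'   `cost` and `qalys`) produced under identical model settings.
#' @return Numeric ICER with attribute `flag` (`"ok"` or `"equal-effect"`).
#' @export
icer <- function(result, reference) {
  if (inherits(result, "cohort_result") && inherits(reference, "cohort_result")) {
    if (!identical(result$gene, reference$gene) ||
        !identical(result$settings, reference$settings) ||
        !identical(result$start_age, reference$start_age))
      stop("ICER requires results from identical model settings")
  }
  dc <- result$cost - reference$cost
  dq <- result$qalys - reference$qalys
  if (abs(dq) < 1e-9)
    return(structure(NA_real_, flag = "equal-effect"))
  structure(dc / dq, flag = "ok")
}

#' Net monetary benefit
#'
#' @param result A `cohort_result` (or list with `cost` and `qalys`).
#' @param wtp Willingness-to-pay threshold in GBP per QALY (>= 0).
#' @return `wtp * qalys - cost` in GBP.
#' @export
nmb <- function(result, wtp = 20000) {
  if (any(wtp < 0)) stop("willingness-to-pay must be >= 0")
  wtp * result$qalys - result$cost
}

#' Cost-effectiveness frontier
#'
#' Flags each strategy as `on-frontier`, `dominated` (weakly costlier and no
#' more effective than another strategy) or `extendedly-dominated` (excluded
#' because a blend of cheaper and more effective alternatives attains its
#' effect at lower cost, i.e. its incremental ICER exceeds that of the next
#' more effective frontier strategy). Frontier ICERs are strictly increasing.
#'
#' @param costs Numeric vector of strategy costs.
#' @param qalys Numeric vector of strategy effects.
#' @param labels Optional strategy labels.
#' @return Data frame `label`, `cost`, `qalys`, `status`, `frontier_icer`
#'   (ICER against the previous frontier strategy; `NA` for the cheapest).
#' @export
frontier <- function(costs, qalys, labels = NULL) {
  n <- length(costs)
  stopifnot(length(qalys) == n, n >= 1)
  if (is.null(labels)) labels <- paste0("strategy_", seq_len(n))
  status <- rep("on-frontier", n)

  for (i in seq_len(n)) {
    dom <- costs >= costs[i] & qalys <= qalys[i] &
      (costs > costs[i] | qalys < qalys[i])
    status[dom] <- "dominated"
  }
  # iteratively remove extendedly dominated strategies among the remainder
  repeat {
    cand <- which(status != "dominated" & status != "extendedly-dominated")
    ord <- cand[order(qalys[cand], costs[cand])]
    changed <- FALSE
    if (length(ord) >= 3) {
      ic <- diff(costs[ord]) / diff(qalys[ord])
      for (j in seq_len(length(ord) - 2L)) {
        if (ic[j] > ic[j + 1] + 1e-12) {
          status[ord[j + 1]] <- "extendedly-dominated"
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  fr_icer <- rep(NA_real_, n)
  onf <- which(status == "on-frontier")
  ord <- onf[order(qalys[onf], costs[onf])]
  if (length(ord) > 1)
    fr_icer[ord[-1]] <- diff(costs[ord]) / diff(qalys[ord])
  data.frame(label = labels, cost = costs, qalys = qalys,
             status = status, frontier_icer = fr_icer,
             stringsAsFactors = FALSE)
}

#' Cancer cases and deaths prevented per 1000 carriers
#'
#' Difference of undiscounted cumulative event tallies (reference minus
#' strategy), scaled per 1000. Negative values are meaningful: a
#' life-prolonging intervention can expose the cohort to more of the other
#' cancer's risk.
#'
#' @param result,reference `cohort_result` objects for the same gene and
#'   settings.
#' @return Named vector: `bc_cases_prevented`, `bc_deaths_prevented`,
#'   `oc_cases_prevented`, `oc_deaths_prevented`.
#' @export
prevention_counts <- function(result, reference) {
  if (!identical(result$gene, reference$gene) ||
      !identical(result$start_age, reference$start_age))
    stop("prevented counts require a shared gene and model settings")
  d <- reference$events - result$events
  c(bc_cases_prevented = unname(d["bc_cases"]),
    bc_deaths_prevented = unname(d["bc_deaths"]),
    oc_cases_prevented = unname(d["oc_cases"]),
    oc_deaths_prevented = unname(d["oc_deaths"]))
}

#' Evaluate all strategies for a gene
#'
#' Runs [run_cohort()] for every strategy of a [model_config()] and derives
#' the decision statistics: ICER and prevented cancer counts against the
#' gene's reference strategy, net monetary benefit at the stated
#' willingness-to-pay threshold, and cost-effectiveness frontier status.
#'
#' @param config A [model_config()]; or a gene name, in which case `params`
#'   must be supplied and base-case strategies are used.
#' @param params A `parameter_set` (ignored when `config` is a
#'   `model_config`).
#' @param wtp Willingness-to-pay threshold for the NMB column (default
#'   20 000 GBP/QALY).
#' @param ... Passed to [run_cohort()] (e.g. `half_cycle`).
#' @return Object of class `cea_result`: a data frame with one row per
#'   strategy (cost, life-years, QALYs, NMB, ICER vs reference, frontier
#'   status, event counts and prevented counts per 1000), with the underlying
#'   `cohort_result` objects in `attr(, "runs")`.
#' @export
evaluate_strategies <- function(config, params = NULL, wtp = 20000, ...) {
  if (is.character(config)) {
    stopifnot(inherits(params, "parameter_set"))
    config <- model_config(params, config)
  }
  stopifnot(inherits(config, "model_config"))
  runs <- lapply(config$strategies, function(s)
    run_cohort(config$gene, s, config$params, start_age = config$start_age, ...))
  names(runs) <- vapply(runs, `[[`, "", "strategy")
  ref_i <- which(vapply(config$strategies, function(s) isTRUE(s$reference), TRUE))
  if (length(ref_i) != 1) ref_i <- 1L
  ref <- runs[[ref_i]]

  rows <- lapply(seq_along(runs), function(i) {
    x <- runs[[i]]
    ic <- if (i == ref_i) NA_real_ else as.numeric(icer(x, ref))
    prev <- if (i == ref_i) rep(NA_real_, 4) else prevention_counts(x, ref)
    data.frame(
      gene = x$gene, strategy = x$strategy,
      reference = i == ref_i,
      cost = x$cost, life_years = x$life_years, qalys = x$qalys,
      nmb = nmb(x, wtp), icer_vs_reference = ic,
      oc_cases = x$events["oc_cases"], bc_cases = x$events["bc_cases"],
      oc_deaths = x$events["oc_deaths"], bc_deaths = x$events["bc_deaths"],
      bc_cases_prevented = prev[1], bc_deaths_prevented = prev[2],
      oc_cases_prevented = prev[3], oc_deaths_prevented = prev[4],
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  fr <- frontier(tab$cost, tab$qalys, tab$strategy)
  tab$frontier_status <- fr$status
  structure(tab, class = c("cea_result", "data.frame"),
            runs = runs, wtp = wtp, gene = config$gene,
            scenario = config$scenario, start_age = config$start_age)
}

#' @export
print.cea_result <- function(x, digits = 2, ...) {
  cat(sprintf("<cea_result> %s, entry age %d, NMB at %s GBP/QALY%s\n",
              attr(x, "gene"), attr(x, "start_age"),
              format(attr(x, "wtp"), big.mark = " "),
              if (!is.null(attr(x, "scenario")))
                paste0(" [scenario ", attr(x, "scenario"), "]") else ""))
  show <- data.frame(
    strategy = paste0(x$strategy, ifelse(x$reference, " (ref)", "")),
    cost = round(x$cost), LYG = round(x$life_years, digits),
    QALYs = round(x$qalys, digits), NMB = round(x$nmb),
    ICER = round(x$icer_vs_reference), frontier = x$frontier_status
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  best <- object$strategy[which.max(object$nmb)]
  cat("Highest-NMB strategy:", best, "\n")
  invisible(as.data.frame(object))
}

#' Cost-effectiveness plane for a gene's strategies
#'
#' @param x A `cea_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cea_result <- function(x, ...) {
  graphics::plot(x$qalys, x$cost, pch = 19,
                 xlab = "Discounted QALYs", ylab = "Discounted cost (GBP)",
                 main = paste("Cost-effectiveness plane:", attr(x, "gene")),
                 ...)
  onf <- x$frontier_status == "on-frontier"
  o <- order(x$qalys[onf])
  graphics::lines(x$qalys[onf][o], x$cost[onf][o], col = "grey50")
  graphics::text(x$qalys, x$cost, x$strategy, pos = 3, cex = 0.7)
  invisible(x)
}
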