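#' Run the base case and write per-gene results tables
#'
#' For each requested gene, evaluates every base-case strategy and writes one
#' CSV combining the cost-effectiveness columns (cost, life-years, QALYs,
#' NMB, ICER vs reference) with the population-level outcome columns (cancer
#' cases/deaths and counts prevented per 1000 carriers). Reruns with the
#' same inputs produce byte-identical files. An optional USD column applies
#' a constant GBP-to-USD factor.
#'
#' @param params A `parameter_set`.
#' @param genes Genes to run (default all six).
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @param wtp Willingness-to-pay threshold for NMB (default 20 000).
#' @param start_age Model entry age (default 30).
#' @param usd_factor If non-`NULL`, adds `cost_usd = cost * usd_factor`
#'   (conventional constant 1.38).
#' @param quiet Suppress progress messages.
#' @return Named list of `cea_result` objects, invisibly when writing.
#' @export
run_base_case <- function(params, genes = csg_genes(), out_dir = NULL,
                          wtp = 20000, start_age = 30L, usd_factor = NULL,
                          quiet = FALSE) {
  unknown <- setdiff(genes, csg_genes())
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (!quiet)
    message("parameter provenance: ",
            if (!is.null(params$meta$source)) params$meta$source else "in-memory")
  out <- list()
  for (g in genes) {
    cfg <- model_config(params, g, start_age = start_age)
    res <- evaluate_strategies(cfg, wtp = wtp)
    out[[g]] <- res
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      tab <- as.data.frame(res)
      if (!is.null(usd_factor)) tab$cost_usd <- tab$cost * usd_factor
      utils::write.csv(format(tab, digits = 10),
                       file.path(out_dir, paste0(tolower(g), "_results.csv")),
                       row.names = FALSE)
    }
    if (!quiet) message("completed ", g)
  }
  if (is.null(out_dir)) out else invisible(out)
}

#' Run a scenario analysis
#'
#' Applies a scenario to the base configuration of each gene, reruns the
#' evaluation and tags every output row with the scenario id.
#'
#' @param params A `parameter_set`.
#' @param scenario A [scenario_spec()] or scenario id string.
#' @param genes Genes to run.
#' @param out_dir Optional output directory for per-gene CSVs.
#' @param wtp Willingness-to-pay threshold.
#' @return Named list of `cea_result` objects with a `scenario` column.
#' @export
run_scenario <- function(params, scenario, genes = csg_genes(),
                         out_dir = NULL, wtp = 20000) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  out <- list()
  for (g in genes) {
    cfg <- apply_scenario(model_config(params, g), scenario)
    res <- evaluate_strategies(cfg, wtp = wtp)
    tab <- as.data.frame(res)
    tab$scenario <- scenario$id
    attr(res, "table") <- tab
    out[[g]] <- res
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(format(tab, digits = 10),
                       file.path(out_dir, paste0(tolower(g), "_scenario_",
                                                 gsub("[^a-z0-9_]", "_",
                                                      scenario$id),
                                                 ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' Run a probabilistic sensitivity analysis and write its outputs
#'
#' @param params A `parameter_set`.
#' @param gene Gene to analyse.
#' @param n Number of draws; must be positive.
#' @param seed RNG seed.
#' @param out_dir Optional directory: writes `"<gene>_psa_draws.csv"`
#'   (draw, strategy, cost, qaly) and `"<gene>_ceac.csv"` (wtp, strategy,
#'   probability).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curves.
#' @return List with the `psa_result` and the `ceac` data frame.
#' @export
run_psa_report <- function(params, gene, n = 10000, seed = 1L,
                           out_dir = NULL, wtp_grid = seq(0, 50000, 1000)) {
  if (!gene %in% csg_genes()) stop("unknown gene: ", gene)
  if (n < 1) stop("at least one PSA draw required")
  cfg <- model_config(params, gene)
  psa <- run_psa(cfg, n = n, seed = seed)
  cc <- ceac(psa, wtp_grid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format(psa$draws, digits = 10),
                     file.path(out_dir, paste0(tolower(gene), "_psa_draws.csv")),
                     row.names = FALSE)
    utils::write.csv(format(as.data.frame(cc), digits = 10),
                     file.path(out_dir, paste0(tolower(gene), "_ceac.csv")),
                     row.names = FALSE)
  }
  list(psa = psa, ceac = cc)
}

#' Run a one-way sensitivity analysis and write the tornado table
#'
#' @param params A `parameter_set`.
#' @param gene Gene to analyse.
#' @param out_dir Optional directory for `"<gene>_tornado.csv"`.
#' @param ... Passed to [owsa()].
#' @return An `owsa_result`.
#' @export
run_owsa_report <- function(params, gene, out_dir = NULL, ...) {
  if (!gene %in% csg_genes()) stop("unknown gene: ", gene)
  res <- owsa(model_config(params, gene), ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(format(as.data.frame(res), digits = 10),
                     file.path(out_dir, paste0(tolower(gene), "_tornado.csv")),
                     row.names = FALSE)
  }
  res
}
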