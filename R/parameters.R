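#' @keywords internal
"_PACKAGE"

# Genes covered by the model. BRIP1 confers ovarian-cancer risk only; its
# breast-cancer states are never occupied.
CSG_GENES <- c("BRCA1", "BRCA2", "PALB2", "RAD51C", "RAD51D", "BRIP1")

MODEL_AGE_MIN <- 30L
MODEL_AGE_MAX <- 100L

#' Genes supported by the model
#'
#' @return Character vector of cancer susceptibility gene names.
#' @export
csg_genes <- function() CSG_GENES

# Scalar parameters every downstream computation may look up by name.
# `validate_parameters()` and the schema-completeness test enforce that a
# ParameterSet carries all of them.
required_parameters <- function() {
  c(
    "rrso_oc_multiplier",
    paste0("rrso_bc_multiplier_", CSG_GENES),
    paste0("rrso_acm_multiplier_", CSG_GENES),
    "rrm_bc_multiplier",
    "chemoprev_bc_multiplier_pre", "chemoprev_bc_multiplier_post",
    "chd_mortality_multiplier",
    "ht_uptake", "chemoprev_uptake",
    "fp_prob_mri", "fp_prob_mammo",
    "oc_survival_10yr", "bc_survival_10yr_high", "bc_survival_10yr_moderate",
    "discount_rate", "menopause_age",
    "cost_rrso", "cost_rrm", "cost_mri", "cost_mammo", "cost_fp_workup",
    "cost_chemoprev_year", "cost_ht_year", "cost_chd_year",
    "cost_oc_year1", "cost_oc_subseq", "cost_oc_terminal",
    "cost_bc_year1", "cost_bc_subseq", "cost_bc_terminal",
    "util_mult_oc", "util_mult_bc",
    "util_mult_oc_survivor", "util_mult_bc_survivor",
    "disutil_rrso", "disutil_rrm", "disutil_chemoprev",
    "disutil_screen", "disutil_fp", "disutil_chd",
    "brip1_oc_rr",
    "parpi_cost_oc_year1", "parpi_cost_bc_year1"
  )
}

DIST_FAMILIES <- c("gamma", "beta", "lognormal", "fixed")

#' Construct an incidence curve
#'
#' An incidence curve stores annual cancer incidence probabilities per year of
#' age over the modelled range. Curves are usually supplied per 5-year age
#' band and expanded to constant per-year probabilities within each band; ages
#' below the first band get probability 0 and ages beyond the last band carry
#' the last band's value.
#'
#' @param gene Gene name.
#' @param cancer `"OC"` or `"BC"`.
#' @param bands Data frame with columns `age_lo`, `age_hi`, `p` (annual
#'   probability, constant within the band).
#' @return An object of class `incidence_curve`.
#' @export
incidence_curve <- function(gene, cancer, bands) {
  stopifnot(is.data.frame(bands), all(c("age_lo", "age_hi", "p") %in% names(bands)))
  cancer <- match.arg(cancer, c("OC", "BC"))
  bands <- bands[order(bands$age_lo), , drop = FALSE]
  if (any(bands$p < 0) || any(bands$p >= 1))
    stop("incidence probabilities must lie in [0, 1): gene ", gene, " ", cancer)
  ages <- MODEL_AGE_MIN:MODEL_AGE_MAX
  p <- numeric(length(ages))
  for (i in seq_len(nrow(bands))) {
    sel <- ages >= bands$age_lo[i] & ages <= bands$age_hi[i]
    p[sel] <- bands$p[i]
  }
  # beyond the last tabulated band: carry the last band's value
  beyond <- ages > max(bands$age_hi)
  p[beyond] <- bands$p[nrow(bands)]
  # below the first band stays 0
  structure(
    list(gene = gene, cancer = cancer, ages = ages, p = p, bands = bands),
    class = "incidence_curve"
  )
}

#' Annual incidence at a given age
#'
#' @param curve An [incidence_curve()].
#' @param age Integer age in 30..100.
#' @return Annual incidence probability at that age.
#' @export
incidence_at <- function(curve, age) {
  stopifnot(inherits(curve, "incidence_curve"))
  if (any(age < MODEL_AGE_MIN | age > MODEL_AGE_MAX))
    stop("age must lie in ", MODEL_AGE_MIN, "..", MODEL_AGE_MAX)
  curve$p[match(age, curve$ages)]
}

#' Look up a scalar parameter by name
#'
#' @param params A `parameter_set`.
#' @param name Parameter name.
#' @return The base value (numeric scalar).
#' @export
param_value <- function(params, name) {
  stopifnot(inherits(params, "parameter_set"))
  i <- match(name, params$params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  params$params$base[i]
}

# Internal: fetch the full (base, low, high, dist) row.
param_row <- function(params, name) {
  i <- match(name, params$params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  params$params[i, ]
}

# Replace the base value of a named parameter, returning a new set.
set_param <- function(params, name, value) {
  i <- match(name, params$params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  params$params$base[i] <- value
  params
}

#' Ovarian-cancer incidence curve for a gene
#'
#' For BRIP1 the curve is constructed as the general-population ovarian-cancer
#' incidence multiplied by the `brip1_oc_rr` relative-risk parameter, so
#' scenario changes to that parameter propagate automatically.
#'
#' @param params A `parameter_set`.
#' @param gene Gene name.
#' @return An `incidence_curve`.
#' @export
gene_oc_curve <- function(params, gene) {
  gene <- match.arg(gene, CSG_GENES)
  if (gene == "BRIP1") {
    rr <- param_value(params, "brip1_oc_rr")
    pop <- params$population_oc_curve
    cur <- pop
    cur$gene <- "BRIP1"
    cur$p <- pmin(pop$p * rr, 0.999)
    cur$bands$p <- pmin(cur$bands$p * rr, 0.999)
    return(cur)
  }
  params$genes[[gene]]$oc_curve
}

#' Breast-cancer incidence curve for a gene
#'
#' @inheritParams gene_oc_curve
#' @return An `incidence_curve`, or `NULL` for BRIP1 (no breast-cancer states).
#' @export
gene_bc_curve <- function(params, gene) {
  gene <- match.arg(gene, CSG_GENES)
  params$genes[[gene]]$bc_curve
}

new_parameter_set <- function(genes, life_table, params, utility_age,
                              population_oc_curve, meta = list()) {
  structure(
    list(
      genes = genes, life_table = life_table, params = params,
      utility_age = utility_age, population_oc_curve = population_oc_curve,
      meta = meta
    ),
    class = "parameter_set"
  )
}

#' Age-specific healthy-state utility
#'
#' @param params A `parameter_set`.
#' @param age Integer age(s) in 30..100.
#' @return Utility weight(s) of the healthy state at that age.
#' @export
healthy_utility <- function(params, age) {
  params$utility_age$utility[match(age, params$utility_age$age)]
}

#' Annual all-cause death probability from the life table
#'
#' @param params A `parameter_set`.
#' @param age Integer age(s) in 30..100.
#' @return Annual probability of death from the female life table.
#' @export
life_table_qx <- function(params, age) {
  params$life_table$qx[match(age, params$life_table$age)]
}

#' Validate a parameter set
#'
#' Checks every schema invariant: probability bounds, `low <= base <= high`
#' ordering, distribution-family support constraints, life-table bounds and
#' monotonic age grids, incidence-curve bounds, presence of every parameter
#' any downstream computation looks up, and BRIP1 carrying no breast-cancer
#' curve. Reporting only: never throws.
#'
#' @param params A `parameter_set`.
#' @return Data frame with columns `component`, `name`, `message`; zero rows
#'   when every invariant holds.
#' @export
validate_parameters <- function(params) {
  v <- list()
  bad <- function(component, name, message) {
    v[[length(v) + 1L]] <<- data.frame(
      component = component, name = name, message = message,
      stringsAsFactors = FALSE
    )
  }
  if (!inherits(params, "parameter_set")) {
    bad("structure", "class", "not a parameter_set")
    return(do.call(rbind, v))
  }

  p <- params$params
  missing <- setdiff(required_parameters(), p$name)
  for (m in missing) bad("params", m, "required parameter missing")
  for (i in seq_len(nrow(p))) {
    nm <- p$name[i]
    if (!is.finite(p$base[i])) bad("params", nm, "non-finite base value")
    if (!p$dist[i] %in% DIST_FAMILIES)
      bad("params", nm, paste0("unknown distribution family '", p$dist[i], "'"))
    if (is.finite(p$low[i]) && is.finite(p$high[i])) {
      if (p$low[i] > p$base[i]) bad("params", nm, "low > base")
      if (p$base[i] > p$high[i]) bad("params", nm, "base > high")
    }
    if (identical(p$dist[i], "beta")) {
      if (p$low[i] < 0 || p$high[i] > 1)
        bad("params", nm, "beta parameter outside [0, 1]")
    }
    if (identical(p$dist[i], "gamma") && p$low[i] < 0)
      bad("params", nm, "gamma parameter with low < 0")
  }
  chk_unit <- function(nm) {
    if (nm %in% p$name) {
      x <- p$base[match(nm, p$name)]
      if (is.finite(x) && (x < 0 || x > 1))
        bad("params", nm, "utility multiplier outside [0, 1]")
    }
  }
  for (nm in c("util_mult_oc", "util_mult_bc",
               "util_mult_oc_survivor", "util_mult_bc_survivor"))
    chk_unit(nm)
  for (nm in grep("^disutil_", p$name, value = TRUE)) {
    if (p$base[match(nm, p$name)] < 0) bad("params", nm, "disutility < 0")
  }
  if ("discount_rate" %in% p$name &&
      p$base[match("discount_rate", p$name)] < 0)
    bad("params", "discount_rate", "discount rate < 0")

  lt <- params$life_table
  if (is.null(lt) || !all(c("age", "qx") %in% names(lt))) {
    bad("life_table", "life_table", "missing or malformed life table")
  } else {
    if (!identical(as.integer(lt$age), MODEL_AGE_MIN:MODEL_AGE_MAX))
      bad("life_table", "age", "ages must be exactly 30..100")
    out <- which(lt$qx < 0 | lt$qx > 1)
    for (i in out)
      bad("life_table", paste0("age ", lt$age[i]),
          paste0("qx = ", format(lt$qx[i]), " outside [0, 1]"))
  }

  for (g in names(params$genes)) {
    gp <- params$genes[[g]]
    for (slot in c("oc_curve", "bc_curve")) {
      cur <- gp[[slot]]
      if (is.null(cur)) next
      out <- which(cur$p < 0 | cur$p >= 1)
      for (i in out)
        bad("incidence", paste0(g, " ", cur$cancer, " age ", cur$ages[i]),
            "annual incidence outside [0, 1)")
    }
    if (g == "BRIP1" && !is.null(gp$bc_curve))
      bad("genes", "BRIP1", "BRIP1 must not carry a breast-cancer curve")
    for (slot in c("lifetime_oc_risk", "lifetime_bc_risk")) {
      x <- gp[[slot]]
      if (!is.null(x) && is.finite(x) && (x < 0 || x > 1))
        bad("genes", paste0(g, " ", slot), "lifetime risk outside [0, 1]")
    }
  }

  ua <- params$utility_age
  if (is.null(ua) || !all(c("age", "utility") %in% names(ua))) {
    bad("utility_age", "utility_age", "missing healthy-utility age curve")
  } else if (any(ua$utility < 0 | ua$utility > 1)) {
    bad("utility_age", "utility", "healthy utility outside [0, 1]")
  }

  if (length(v) == 0L)
    return(data.frame(component = character(), name = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Read a parameter set from disk
#'
#' The on-disk layout is a YAML manifest (`config.yaml`) referencing CSV
#' tables in the same directory: `parameters.csv` (name, base, low, high,
#' dist, units), `life_table.csv` (age, qx), `utility_age.csv` (age, utility)
#' and one `incidence_<gene>_<oc|bc>.csv` (age_lo, age_hi, p) per curve, plus
#' `incidence_population_oc.csv` for the general-population ovarian curve
#' behind BRIP1.
#'
#' @param path Directory containing `config.yaml`, or the manifest file itself.
#' @return A validated `parameter_set`; invalid files raise an error naming
#'   the offending entry.
#' @export
read_parameter_set <- function(path) {
  manifest <- if (dir.exists(path)) file.path(path, "config.yaml") else path
  if (!file.exists(manifest)) stop("no parameter manifest at ", manifest)
  dir <- dirname(manifest)
  cfg <- yaml::read_yaml(manifest)
  for (key in c("schema_version", "parameters", "life_table", "utility_age",
                "population_oc", "genes"))
    if (is.null(cfg[[key]])) stop("parameter manifest missing required key '", key, "'")

  read_tbl <- function(rel, cols) {
    f <- file.path(dir, rel)
    if (!file.exists(f)) stop("referenced table not found: ", rel)
    x <- utils::read.csv(f, stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(x))
    if (length(miss))
      stop("table ", rel, " missing column(s): ", paste(miss, collapse = ", "))
    x
  }

  p <- read_tbl(cfg$parameters, c("name", "base", "low", "high", "dist", "units"))
  for (cc in c("base", "low", "high")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(p[[cc]]))))
    if (length(bad))
      stop("non-numeric ", cc, " for parameter '", p$name[bad[1]], "'")
    p[[cc]] <- as.numeric(p[[cc]])
  }
  lt <- read_tbl(cfg$life_table, c("age", "qx"))
  bad <- which(lt$qx < 0 | lt$qx > 1)
  if (length(bad))
    stop("life table qx out of [0, 1] at age row ", lt$age[bad[1]])
  ua <- read_tbl(cfg$utility_age, c("age", "utility"))
  pop <- incidence_curve("population", "OC",
                         read_tbl(cfg$population_oc, c("age_lo", "age_hi", "p")))

  genes <- list()
  for (g in names(cfg$genes)) {
    gc <- cfg$genes[[g]]
    oc <- incidence_curve(g, "OC", read_tbl(gc$oc, c("age_lo", "age_hi", "p")))
    bc <- if (!is.null(gc$bc))
      incidence_curve(g, "BC", read_tbl(gc$bc, c("age_lo", "age_hi", "p")))
    genes[[g]] <- list(
      gene = g, oc_curve = oc, bc_curve = bc,
      lifetime_oc_risk = gc$lifetime_oc_risk,
      lifetime_bc_risk = gc$lifetime_bc_risk,
      surveillance_tier = gc$surveillance_tier
    )
  }

  ps <- new_parameter_set(genes, lt, p, ua, pop,
                          meta = list(schema_version = cfg$schema_version,
                                      source = manifest))
  rep <- validate_parameters(ps)
  if (nrow(rep))
    stop("invalid parameter set: ", rep$name[1], " - ", rep$message[1],
         if (nrow(rep) > 1) paste0(" (and ", nrow(rep) - 1L, " more)"))
  ps
}

#' Write a parameter set to disk
#'
#' Emits the same YAML + CSV schema that [read_parameter_set()] consumes, so
#' `read_parameter_set(write_parameter_set(ps, d))` round-trips.
#'
#' @param params A `parameter_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_parameter_set <- function(params, dir) {
  stopifnot(inherits(params, "parameter_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, rel) {
    utils::write.csv(x, file.path(dir, rel), row.names = FALSE)
    rel
  }
  cfg <- list(
    schema_version = 1L,
    parameters = wr(params$params, "parameters.csv"),
    life_table = wr(params$life_table, "life_table.csv"),
    utility_age = wr(params$utility_age, "utility_age.csv"),
    population_oc = wr(params$population_oc_curve$bands,
                       "incidence_population_oc.csv"),
    genes = list()
  )
  for (g in names(params$genes)) {
    gp <- params$genes[[g]]
    entry <- list(
      oc = wr(gp$oc_curve$bands, paste0("incidence_", tolower(g), "_oc.csv")),
      lifetime_oc_risk = gp$lifetime_oc_risk,
      surveillance_tier = gp$surveillance_tier
    )
    if (!is.null(gp$bc_curve)) {
      entry$bc <- wr(gp$bc_curve$bands, paste0("incidence_", tolower(g), "_bc.csv"))
      entry$lifetime_bc_risk <- gp$lifetime_bc_risk
    }
    cfg$genes[[g]] <- entry
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 12)
  invisible(dir)
}

#' Packaged default (synthetic) parameter set
#'
#' Loads the parameter files shipped under `inst/extdata/default_parameters`.
#' These are synthetic defaults: incidence curves calibrated to published
#' lifetime risks and plausible UK cost/utility values, not a transcription of
#' any study's supplementary tables. Replace with
#' [read_parameter_set()] on your own files for a bespoke analysis.
#'
#' @return A `parameter_set`.
#' @export
default_parameters <- function() {
  read_parameter_set(system.file("extdata", "default_parameters",
                                 package = "csgprev", mustWork = TRUE))
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>", nrow(x$params), "scalar parameters,",
      length(x$genes), "gene profiles\n")
  for (g in names(x$genes)) {
    gp <- x$genes[[g]]
    cat(sprintf("  %-7s lifetime OC %.3f%s, surveillance %s\n", g,
                gp$lifetime_oc_risk,
                if (!is.null(gp$bc_curve))
                  sprintf(", BC %.3f", gp$lifetime_bc_risk) else "",
                gp$surveillance_tier))
  }
  invisible(x)
}
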