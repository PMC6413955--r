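#' Configuration for a full scFBA run
#'
#' Bundles inputs and options for [run_pipeline()]. `model` and
#' `expression` may be file paths (SBML; TSV/CSV) or in-memory objects
#' ([template_network()], [expression_data()]).
#'
#' The `mode` selects which constraint layers apply:
#' * `popFBA` — type-1 (medium) constraints only, on the unmodified
#'   template; every cell is identical.
#' * `bulkFBA` — the isolated template with the bulk-off genes `G_off`
#'   deleted (`A*`), type-1 constraints, no per-cell modulation.
#' * `scFBA` — type-1 plus type-2: per-cell activity-score bounds on `A*`.
#'
#' @param model SBML path or `template_network`.
#' @param expression matrix path or `expression_data`.
#' @param bulk optional bulk TSV path (gene, TPM; no header), or `"mean"`
#'   to use the mean of the single-cell profiles.
#' @param medium a [medium_spec()], or `NULL` for the toy default
#'   ([toy_medium()] scaled by the number of cells).
#' @param mode `"scFBA"`, `"popFBA"` or `"bulkFBA"`.
#' @param epsilon flux floor for type-2 bounds (default `1e-3` nmol/h).
#' @param objective `"biomass"` or `"atp"`.
#' @param min_genes cell filter threshold (default 5000; use 0/1 for toy
#'   gene panels).
#' @param gpr_excluded reaction ids whose GPR is ignored when scoring.
#' @param blood_metabolites passed to [build_population_model()].
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param seed seed recorded in the provenance record and used for any
#'   stochastic post-processing.
#' @return an object of class `run_config`.
#' @export
run_config <- function(model, expression, bulk = NULL, medium = NULL,
                       mode = c("scFBA", "popFBA", "bulkFBA"),
                       epsilon = 1e-3, objective = c("biomass", "atp"),
                       min_genes = 5000, gpr_excluded = character(),
                       blood_metabolites = NULL, out_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  stopifnot(epsilon >= 0)
  structure(list(model = model, expression = expression, bulk = bulk,
                 medium = medium, mode = mode, epsilon = epsilon,
                 objective = objective, min_genes = min_genes,
                 gpr_excluded = gpr_excluded,
                 blood_metabolites = blood_metabolites,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

load_config_network <- function(config) {
  if (inherits(config$model, "template_network")) return(config$model)
  if (!file.exists(config$model)) {
    stop("pipeline stage 'network': model file not found: ", config$model)
  }
  read_sbml_network(config$model, gpr_excluded = config$gpr_excluded)
}

load_config_expression <- function(config) {
  if (inherits(config$expression, "expression_data")) return(config$expression)
  if (!file.exists(config$expression)) {
    stop("pipeline stage 'expression': file not found: ", config$expression)
  }
  bulk_path <- if (!is.null(config$bulk) && !identical(config$bulk, "mean"))
    config$bulk else NULL
  load_expression(config$expression, bulk_path = bulk_path)
}

#' Run the scFBA workflow end to end
#'
#' Executes preprocess -> activity scores -> population build -> capacities
#' -> bounds -> optimization for the configured mode, and (optionally)
#' writes flux tables plus a provenance record. Two runs with the same
#' configuration and seed produce identical numbers: the LP solver is
#' deterministic and all stochastic steps are seeded.
#'
#' @param config a [run_config()].
#' @return list with elements `solution` ([optimize_population()] result),
#'   `model`, `net_star`, `ras` (`NULL` unless mode is `scFBA`), `caps`
#'   (`NULL` unless `scFBA`), `g_off`, `expression`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  net <- load_config_network(config)
  expr <- load_config_expression(config)
  expr <- filter_cells(expr, min_genes_detected = config$min_genes)
  bulk_mode <- if (identical(config$bulk, "mean")) "mean" else "measured"
  rec <- reconcile_with_bulk(expr, bulk = bulk_mode)
  expr <- rec$data
  g_off <- rec$g_off
  n_cells <- ncol(expr$mat)

  use_star <- config$mode %in% c("scFBA", "bulkFBA")
  net_run <- if (use_star) delete_genes(net, g_off) else net
  model_cells <- if (config$mode == "bulkFBA") 1L else n_cells
  model <- build_population_model(net_run, model_cells,
                                  blood_metabolites = config$blood_metabolites)
  medium <- config$medium
  if (is.null(medium)) medium <- toy_medium(n_pop = n_cells)
  model <- apply_medium(model, medium)

  ras <- NULL
  caps <- NULL
  if (config$mode == "scFBA") {
    overlap <- intersect(network_genes(net_run), rownames(expr$mat))
    if (length(overlap) == 0L) {
      stop("pipeline stage 'ras': no gene overlap between network and expression")
    }
    caps <- compute_flux_capacities(model)
    ras <- normalize_ras(compute_ras_matrix(net_run, expr))
    model <- apply_ras_bounds(model, caps, ras, epsilon = config$epsilon)
  }
  sol <- optimize_population(model, objective = config$objective,
                             parsimonious = TRUE)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(config, model, sol, ras, g_off)
  }
  list(solution = sol, model = model, net_star = net_run, ras = ras,
       caps = caps, g_off = g_off, expression = expr, config = config)
}

write_pipeline_outputs <- function(config, model, sol, ras, g_off) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sol$v)) {
    flux <- data.frame(model$columns,
                       flux = unname(sol$v[model$columns$col]))
    data.table::fwrite(flux, file.path(config$out_dir, "fluxes.tsv"), sep = "\t")
  }
  if (!is.null(ras)) write_ras(ras, config$out_dir)
  bounds <- data.frame(col = colnames(model$S), lb = unname(model$lb),
                       ub = unname(model$ub))
  data.table::fwrite(bounds, file.path(config$out_dir, "bounds.tsv"), sep = "\t")
  prov <- list(mode = config$mode, epsilon = config$epsilon,
               objective = config$objective, seed = config$seed,
               n_cells = model$n_cells, g_off = as.list(g_off),
               status = sol$status, objective_value = sol$objective_value,
               timestamp = format(Sys.time(), tz = "UTC"),
               package_version = as.character(utils::packageVersion("scfba")))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Scan the epsilon flux floor
#'
#' Re-applies the type-2 bounds for each epsilon in `eps_values` (the
#' capacity analysis and activity scores are computed once) and records the
#' optimal total biomass. The problem stays feasible at `epsilon = 0`;
#' larger floors relax the model, so the biomass curve is non-decreasing.
#'
#' @param config a [run_config()] with `mode = "scFBA"`.
#' @param eps_values epsilon values to scan (default
#'   `0, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1`).
#' @return data.frame `epsilon`, `objective_value`, `status`.
#' @export
eps_scan <- function(config, eps_values = c(0, 1e-6, 1e-5, 1e-4, 1e-3,
                                            1e-2, 1e-1, 1)) {
  stopifnot(inherits(config, "run_config"), config$mode == "scFBA")
  base <- run_pipeline(stripped_config(config))
  pre <- build_population_model(base$net_star, base$model$n_cells,
                                blood_metabolites = config$blood_metabolites)
  medium <- base$model$medium
  pre <- apply_medium(pre, medium)
  out <- lapply(eps_values, function(eps) {
    m <- apply_ras_bounds(pre, base$caps, base$ras, epsilon = eps)
    s <- optimize_population(m, objective = config$objective, need_x = FALSE)
    data.frame(epsilon = eps, objective_value = s$objective_value,
               status = s$status)
  })
  do.call(rbind, out)
}

stripped_config <- function(config) {
  config$out_dir <- NULL
  config
}
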