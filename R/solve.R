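#' Optimize a population model
#'
#' Solves the linear program `maximize c'v subject to S v = 0,
#' lb <= v <= ub`. The `biomass` objective maximizes the blood drain of the
#' pooled biomass metabolite (the total biomass of the population); the
#' `atp` objective maximizes the summed per-cell flux through the template's
#' ATP-demand (hydrolysis) reaction.
#'
#' @param model a bounded [build_population_model()] result.
#' @param objective `"biomass"` or `"atp"`.
#' @param atp_reaction template reaction id used for the ATP objective;
#'   by default the first internal reaction whose id matches
#'   `"ATPM"`, `"ATP_demand"` or `"ATPase"` (case-insensitive).
#' @param need_x return the full flux vector (default `TRUE`).
#' @param parsimonious when `TRUE`, the returned flux vector is the
#'   parsimonious optimum: among all flux distributions attaining the LP
#'   optimum, the one of minimal total absolute flux. The objective value
#'   is unchanged; degenerate coordinates stop carrying arbitrary-vertex
#'   values, which matters when fluxes are used as features downstream.
#' @return object of class `flux_solution`: `status`, `objective_value`,
#'   `v` (named flux vector when optimal and requested).
#' @export
optimize_population <- function(model, objective = c("biomass", "atp"),
                                atp_reaction = NULL, need_x = TRUE,
                                parsimonious = FALSE) {
  stopifnot(inherits(model, "population_model"))
  objective <- match.arg(objective)
  obj_cols <- objective_columns(model, objective, atp_reaction)
  res <- solve_lp_batch(model$S, model$lb, model$ub, list(
    list(obj_idx = match(obj_cols, colnames(model$S)),
         obj_val = rep(1, length(obj_cols)), sense = "max", need_x = need_x,
         parsimonious = parsimonious && need_x)
  ))[[1]]
  v <- NULL
  if (identical(res$status, "optimal") && need_x) {
    v <- stats::setNames(unlist(res$x), colnames(model$S))
  }
  structure(list(status = res$status,
                 objective_value = if (identical(res$status, "optimal"))
                   res$objective else NA_real_,
                 objective = objective, v = v),
            class = "flux_solution")
}

objective_columns <- function(model, objective, atp_reaction = NULL) {
  if (objective == "biomass") {
    if (is.na(model$objective_column)) stop("model has no biomass objective column")
    return(model$objective_column)
  }
  if (is.null(atp_reaction)) {
    ids <- internal_reactions(model$net)
    hit <- ids[grepl("^(ATPM|ATP_demand|ATPase)$", ids, ignore.case = TRUE)]
    if (!length(hit)) {
      stop("no ATP-demand reaction found; pass atp_reaction explicitly")
    }
    atp_reaction <- hit[1]
  }
  cols <- model_columns(model, atp_reaction)
  cols[cols %in% colnames(model$S)]
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s; %s objective: %s\n",
              x$status, x$objective,
              format(x$objective_value, digits = 10)))
  invisible(x)
}

#' Per-cell biomass variability at the population optimum
#'
#' Fixes the total-biomass objective at its optimum and computes, for each
#' cell, the minimal and maximal flux its biomass export can still take —
#' the per-cell slice of the optimal-solution space. Without single-cell
#' constraints every cell can span the whole range `[0, total]`; activity
#' score integration collapses each span to (essentially) a point.
#'
#' @param model a bounded [build_population_model()] result.
#' @param fix_tol relative slack when fixing the optimum (default `1e-9`),
#'   guarding against solver-tolerance infeasibility.
#' @return data.frame with columns `cell`, `min`, `max`, `frac_min`,
#'   `frac_max` (fractions of the total) plus attribute `total`.
#' @export
per_cell_biomass_span <- function(model, fix_tol = 1e-9) {
  stopifnot(inherits(model, "population_model"))
  sol <- optimize_population(model, "biomass", need_x = FALSE)
  if (sol$status != "optimal") stop("population model not solvable: ", sol$status)
  total <- sol$objective_value
  slack <- fix_tol * max(1, abs(total))
  biomass_exchange <- names(which(exchange_species(model$net) == model$biomass_species))
  cols <- paste0(biomass_exchange[1], "_cell", seq_len(model$n_cells))
  fva <- model_fva(model, cols,
                   fix_lb = stats::setNames(total - slack, model$objective_column),
                   fix_ub = stats::setNames(total + slack, model$objective_column))
  out <- data.frame(cell = seq_len(model$n_cells), min = fva$min, max = fva$max)
  out$frac_min <- if (total > 0) out$min / total else NA_real_
  out$frac_max <- if (total > 0) out$max / total else NA_real_
  attr(out, "total") <- total
  out
}

#' Single-gene deletion screen
#'
#' For each gene, reactions whose GPR evaluates `FALSE` with that gene off
#' are disabled (zero-bounded) in every cell simultaneously, the model is
#' re-optimized, and the growth ratio `grRatio` (optimum after deletion
#' over baseline optimum) is recorded. Genes appearing in no GPR — or whose
#' deletion disables no reaction, e.g. because an isoform survives — have
#' `grRatio = 1` by construction. Deleting can only restrict the feasible
#' region, so `grRatio` lies in `[0, 1]`.
#'
#' @param model a bounded [build_population_model()] result.
#' @param genes genes to screen; defaults to all genes of the model's
#'   template network.
#' @param objective passed to [optimize_population()].
#' @return object of class `deletion_report`: data.frame with `gene`,
#'   `grRatio`, `n_disabled`, `disabled` (comma-separated reaction ids);
#'   attribute `baseline` holds the reference optimum.
#' @export
single_gene_deletion <- function(model, genes = NULL,
                                 objective = c("biomass", "atp")) {
  stopifnot(inherits(model, "population_model"))
  objective <- match.arg(objective)
  net <- model$net
  if (is.null(genes)) genes <- network_genes(net)
  base <- optimize_population(model, objective, need_x = FALSE)
  if (base$status != "optimal") stop("baseline model not solvable: ", base$status)
  b0 <- base$objective_value

  disabled <- lapply(genes, function(g) disabled_reactions(net, g))
  todo <- which(lengths(disabled) > 0L)
  gr <- rep(1, length(genes))
  if (length(todo) && b0 > 0) {
    obj_cols <- objective_columns(model, objective)
    obj_idx <- match(obj_cols, colnames(model$S))
    problems <- lapply(todo, function(i) {
      cols <- unlist(lapply(disabled[[i]], function(id)
        model_columns(model, id)))
      cols <- cols[cols %in% colnames(model$S)]
      idx <- match(cols, colnames(model$S))
      list(obj_idx = obj_idx, obj_val = rep(1, length(obj_idx)), sense = "max",
           lb_idx = idx, lb_val = rep(0, length(idx)),
           ub_idx = idx, ub_val = rep(0, length(idx)))
    })
    res <- solve_lp_batch(model$S, model$lb, model$ub, problems)
    vals <- vapply(res, function(r) {
      if (identical(r$status, "optimal")) r$objective else 0
    }, numeric(1))
    gr[todo] <- pmin(1, pmax(0, vals / b0))
  } else if (b0 <= 0) {
    gr[todo] <- NA_real_
  }
  out <- data.frame(gene = genes, grRatio = gr,
                    n_disabled = lengths(disabled),
                    disabled = vapply(disabled, paste, character(1),
                                      collapse = ","),
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- b0
  class(out) <- c("deletion_report", "data.frame")
  out
}

#' Cooperation-knockout ratio
#'
#' Severs metabolite exchange between cells for the designated nutrient
#' species — never the biomass pooling route — re-optimizes, and reports
#' the ratio of the blocked optimum over the open optimum. Cooperation is
#' blocked by forbidding uptake from the TME pool (`lb = 0` on every
#' cooperation column of the species): no cell can consume what another
#' secretes, while each cell can still rid itself of excess metabolites
#' through the TME into the blood, so the knockout measures the loss of
#' cooperation rather than a waste-disposal block. A ratio below 1 means
#' the population relies on metabolite exchange between cells; because
#' blocking only restricts the feasible region the ratio never exceeds 1,
#' and for a population of identical cells it is exactly 1 (the symmetric
#' optimum never needs TME uptake of a secretable species).
#'
#' @param model a bounded [build_population_model()] result.
#' @param objective passed to [optimize_population()].
#' @param species species whose cooperation columns are blocked; defaults
#'   to all blood species except biomass.
#' @return list with `ratio` (`NA` when the open optimum is 0), `open`,
#'   `blocked`.
#' @export
cooperation_knockout_ratio <- function(model, objective = c("biomass", "atp"),
                                       species = NULL) {
  stopifnot(inherits(model, "population_model"))
  objective <- match.arg(objective)
  if (is.null(species)) {
    # default: the dual-route (secretable) species. Nutrients whose only
    # entry is the TME route must not be blocked, or the knockout would
    # measure starvation rather than loss of cooperation.
    species <- if (!is.null(model$medium)) {
      intersect(model$medium$secrete, model$blood_species)
    } else {
      setdiff(model$blood_species, model$biomass_species)
    }
  }
  no_secrete <- species[model$ub[paste0("B_", species)] <= 0]
  if (length(no_secrete)) {
    warning("blocked species without a blood secretion route: ",
            paste(no_secrete, collapse = ", "),
            " (knockout may conflate cooperation with waste disposal)")
  }
  open <- optimize_population(model, objective, need_x = FALSE)
  if (open$status != "optimal") stop("open model not solvable: ", open$status)
  coop_cols <- model$columns$col[model$columns$kind == "cooperation" &
                                   model$columns$species %in% species]
  idx <- match(coop_cols, colnames(model$S))
  obj_cols <- objective_columns(model, objective)
  obj_idx <- match(obj_cols, colnames(model$S))
  blocked <- solve_lp_batch(model$S, model$lb, model$ub, list(
    list(obj_idx = obj_idx, obj_val = rep(1, length(obj_idx)), sense = "max",
         lb_idx = idx, lb_val = pmax(0, model$lb[coop_cols]))
  ))[[1]]
  bval <- if (identical(blocked$status, "optimal")) blocked$objective else 0
  ratio <- if (open$objective_value > 0) bval / open$objective_value else NA_real_
  list(ratio = ratio, open = open$objective_value, blocked = bval)
}

#' Per-cell flux feature matrix from a solved model
#'
#' Arranges a flux vector into a (template reaction) x (cell) matrix over
#' the internal and cooperation reactions — the single-cell fluxome
#' features used for clustering.
#'
#' @param model the `population_model` the solution belongs to.
#' @param solution a `flux_solution` with a flux vector.
#' @return numeric matrix, rows = template reaction ids, columns = cells.
#' @export
flux_feature_matrix <- function(model, solution) {
  stopifnot(inherits(model, "population_model"),
            inherits(solution, "flux_solution"))
  if (is.null(solution$v)) stop("solution carries no flux vector")
  cols <- model$columns
  keep <- cols$kind %in% c("internal", "cooperation")
  ids <- cols$template_id[keep & cols$cell == 1L]
  out <- vapply(seq_len(model$n_cells), function(cc) {
    unname(solution$v[cols$col[keep & cols$cell == cc]])
  }, numeric(length(ids)))
  rownames(out) <- ids
  colnames(out) <- paste0("cell", seq_len(model$n_cells))
  out
}

#' Flux variability of cooperation fluxes at the optimum
#'
#' Optimal cooperation fluxes come from one vertex among possibly many;
#' rather than pretending uniqueness, this reports the FVA range of each
#' cooperation column with the biomass objective fixed at its optimum.
#'
#' @param model a bounded [build_population_model()] result.
#' @param species restrict to these species (default: all blood species
#'   except biomass).
#' @param fix_tol relative slack when fixing the optimum.
#' @return data.frame `col`, `cell`, `species`, `min`, `max`.
#' @export
cooperation_flux_ranges <- function(model, species = NULL, fix_tol = 1e-7) {
  stopifnot(inherits(model, "population_model"))
  if (is.null(species)) {
    species <- setdiff(model$blood_species, model$biomass_species)
  }
  sol <- optimize_population(model, "biomass", need_x = FALSE)
  if (sol$status != "optimal") stop("population model not solvable: ", sol$status)
  slack <- fix_tol * max(1, abs(sol$objective_value))
  keep <- model$columns$kind == "cooperation" & model$columns$species %in% species
  cols <- model$columns$col[keep]
  fva <- model_fva(model, cols,
                   fix_lb = stats::setNames(sol$objective_value - slack,
                                            model$objective_column))
  data.frame(col = cols, cell = model$columns$cell[keep],
             species = model$columns$species[keep],
             min = fva$min, max = fva$max, stringsAsFactors = FALSE)
}
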