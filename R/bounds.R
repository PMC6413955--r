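# Flux variability analysis over selected columns of a population model.
# fix: optional list(col=, lb=, ub=) bound overrides applied to every LP.
model_fva <- function(model, cols, fix_lb = numeric(), fix_ub = numeric()) {
  idx <- match(cols, colnames(model$S))
  if (anyNA(idx)) stop("unknown columns: ",
                       paste(cols[is.na(idx)], collapse = ", "))
  lb_idx <- match(names(fix_lb), colnames(model$S))
  ub_idx <- match(names(fix_ub), colnames(model$S))
  problems <- vector("list", 2L * length(idx))
  for (i in seq_along(idx)) {
    common <- list(obj_idx = idx[i], obj_val = 1,
                   lb_idx = lb_idx, lb_val = unname(fix_lb),
                   ub_idx = ub_idx, ub_val = unname(fix_ub))
    problems[[2L * i - 1L]] <- c(common, sense = "min")
    problems[[2L * i]] <- c(common, sense = "max")
  }
  res <- solve_lp_batch(model$S, model$lb, model$ub, problems)
  bad <- vapply(res, function(r) r$status != "optimal", logical(1))
  if (any(bad)) {
    stop("FVA subproblem not optimal (", res[[which(bad)[1]]]$status,
         "); is the medium configured and feasible?")
  }
  data.frame(col = cols,
             min = vapply(res[seq(1, length(res), 2)], `[[`, numeric(1), "objective"),
             max = vapply(res[seq(2, length(res), 2)], `[[`, numeric(1), "objective"),
             stringsAsFactors = FALSE)
}

#' Compute flux capacities under medium constraints
#'
#' For every template reaction (internal and cooperation), computes the
#' maximal flux achievable in the forward (`F_f`) and backward (`F_b`)
#' direction when only type-1 (medium) constraints are set — a flux
#' variability analysis with no optimality requirement (the objective is
#' ignored) and no biomass demand. The capacity is
#' `F_j = max(|F_f|, |F_b|)`; a single symmetric value is used for both
#' directions because the activity score reflects the expression of the
#' competent enzyme, which works equally in either direction.
#'
#' Cells are identical before activity scores are applied, so the analysis
#' runs on one representative cell's columns and the result is broadcast —
#' an `n_cells`-fold cost reduction justified by symmetry.
#'
#' @param model a medium-constrained [build_population_model()] result.
#' @param zero_tol capacities below this magnitude are floored to 0
#'   (default `1e-9`).
#' @return object of class `capacity_table`: data.frame with columns
#'   `template_id`, `f_forward`, `f_backward`, `F`.
#' @export
compute_flux_capacities <- function(model, zero_tol = 1e-9) {
  stopifnot(inherits(model, "population_model"))
  if (is.null(model$medium)) {
    warning("computing capacities on a model without an applied medium")
  }
  ids <- c(internal_reactions(model$net), model$net$exchanges)
  cols <- model_columns(model, ids, cells = 1L)
  cols <- paste0(ids, "_cell1")
  fva <- model_fva(model, cols)
  F <- pmax(abs(fva$min), abs(fva$max))
  F[F < zero_tol] <- 0
  structure(data.frame(template_id = ids, f_forward = fva$max,
                       f_backward = fva$min, F = F,
                       stringsAsFactors = FALSE),
            class = c("capacity_table", "data.frame"))
}

#' Project activity scores onto per-cell flux bounds
#'
#' Implements the capacity-remapping (type-2) constraints of scFBA. For
#' each scored reaction `j` (including cooperation reactions whose template
#' exchange carries a GPR, i.e. transporters) and each cell `c`, the upper
#' bound is the share of the capacity proportional to the cell's relative
#' activity:
#'
#' `U_j^c = epsilon + (F_j^c - epsilon) * RASbar_j^c`
#'
#' so that the bounds sum across cells to (approximately) the capacity,
#' and a cell with zero relative activity keeps the small epsilon floor
#' instead of a hard zero — mitigating scRNA-seq false negatives. The
#' lower bound is `0` for irreversible reactions and `-U_j^c` otherwise.
#' Unscored reactions receive their capacity as bounds (`[0, F]` or
#' `[-F, F]`). Blood exchanges (type-1 constraints) are untouched.
#'
#' @param model a medium-constrained [build_population_model()] result.
#' @param caps a [compute_flux_capacities()] table.
#' @param ras a [normalize_ras()]-processed `ras_matrix` (normalization is
#'   applied on the fly if missing), or `NULL` to apply capacity bounds
#'   only (the popFBA limit).
#' @param epsilon the flux floor in nmol/h (default `1e-3`). Must be
#'   `>= 0`. If `epsilon` exceeds a reaction's capacity the bound is
#'   clamped to `epsilon` with a warning.
#' @return the bounded `population_model`.
#' @export
apply_ras_bounds <- function(model, caps, ras, epsilon = 1e-3) {
  stopifnot(inherits(model, "population_model"),
            inherits(caps, "capacity_table"), epsilon >= 0)
  if (!is.null(ras)) {
    stopifnot(inherits(ras, "ras_matrix"))
    if (is.null(ras$normalized)) ras <- normalize_ras(ras)
    cells_expected <- model$n_cells
    if (ncol(ras$normalized) != cells_expected) {
      stop(sprintf("ras has %d cells but the model has %d",
                   ncol(ras$normalized), cells_expected))
    }
  }
  clamped <- character()
  for (i in seq_len(nrow(caps))) {
    id <- caps$template_id[i]
    Fj <- caps$F[i]
    is_coop <- id %in% model$net$exchanges
    reversible <- if (is_coop) TRUE else model$net$reactions[[id]]$reversible
    cols <- paste0(id, "_cell", seq_len(model$n_cells))
    cols <- cols[cols %in% colnames(model$S)]
    if (!length(cols)) next
    closed <- model$lb[cols] == 0 & model$ub[cols] == 0
    scored <- !is.null(ras) && id %in% ras$scored_reactions
    if (scored) {
      rbar <- ras$normalized[id, ]
      U <- epsilon + (Fj - epsilon) * rbar
      if (Fj < epsilon) {
        U <- pmax(U, epsilon)
        clamped <- c(clamped, id)
      }
    } else {
      U <- rep(Fj, length(cols))
    }
    L <- if (reversible) -U else rep(0, length(U))
    model$ub[cols] <- ifelse(closed, 0, U)
    model$lb[cols] <- ifelse(closed, 0, L)
  }
  if (length(clamped)) {
    warning("epsilon exceeds the capacity of ", length(clamped),
            " reaction(s) (e.g. ", clamped[1], "); bounds clamped to epsilon")
  }
  model
}
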