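#' Build the multi-scale population model
#'
#' Replicates the template network into `n_cells` single-cell blocks that
#' share a tumour-microenvironment (TME) compartment. Every exchange
#' reaction `E_j` of every cell `c` is replaced by a reversible cooperation
#' reaction `C_j^c : Y_j^c <-> Y'_j` (stoichiometry `-1` on the cell-side
#' metabolite, `+1` on the TME pool), and each blood-exchangeable TME
#' metabolite `K_j` gets one unbalanced blood exchange `B_j : K_j <-> 0`
#' (single `-1` entry; negative flux = uptake from blood). The biomass
#' pseudo-metabolite is always blood-exchangeable: each cell exports biomass
#' through its own cooperation reaction into the TME biomass pool, which is
#' drained by the blood exchange whose flux is the optimization objective —
#' the total biomass of the population.
#'
#' The assembled sparse matrix has exactly
#' `(n_cells * M + N_blood)` rows and `(n_cells * (N + N_ext) + N_blood)`
#' columns, where `M`, `N`, `N_ext` are the template's metabolite, internal
#' reaction and exchange counts. Only blood-exchangeable species receive a
#' TME mass-balance row; cooperation columns of species without a blood
#' exchange are closed (`lb = ub = 0`), i.e. a species absent from the
#' blood/TME configuration is not exchangeable at all (see the methods
#' vignette for the rationale).
#'
#' Column order is stable: all of cell 1 (internal reactions in template
#' order, then cooperation reactions in exchange order), ..., cell N, then
#' the blood exchanges. Ids are suffixed `_cell<k>` and `_TME`.
#'
#' @param net a [template_network()] (for scFBA, the subnetwork `A*`).
#' @param n_cells number of single-cell replicates (>= 1).
#' @param blood_metabolites ordered subset of exchanged species to connect
#'   to the blood compartment; defaults to all exchanged species. The
#'   biomass pseudo-metabolite is added automatically.
#' @param coop_big magnitude of the default cooperation-reaction bounds
#'   (nmol/h, default `1e4`). It must exceed the total medium uptake so
#'   that a single cell can in principle carry the whole population's
#'   exchange flux; cooperation bounds are meant to be non-binding until
#'   activity scores restrict them.
#' @return an object of class `population_model`.
#' @export
build_population_model <- function(net, n_cells,
                                   blood_metabolites = NULL,
                                   coop_big = 1e4) {
  stopifnot(inherits(net, "template_network"), n_cells >= 1)
  n_cells <- as.integer(n_cells)
  ex_sp <- exchange_species(net)          # exchange id -> species
  if (is.null(blood_metabolites)) {
    blood_metabolites <- unique(unname(ex_sp))
  } else {
    bad <- setdiff(blood_metabolites, unname(ex_sp))
    if (length(bad)) {
      stop("blood metabolite(s) with no exchanged counterpart in the template: ",
           paste(bad, collapse = ", "))
    }
    blood_metabolites <- unique(blood_metabolites)
  }
  bm <- biomass_species(net)
  if (!is.na(bm) && !(bm %in% blood_metabolites)) {
    blood_metabolites <- c(blood_metabolites, bm)
  }

  M <- n_metabolites(net)
  internal <- internal_reactions(net)
  N <- length(internal)
  Next <- n_exchanges(net)
  Nblood <- length(blood_metabolites)

  row_names <- c(paste0(rep(net$metabolites, times = n_cells), "_cell",
                        rep(seq_len(n_cells), each = M)),
                 paste0(blood_metabolites, "_TME"))
  met_row <- function(met, cell) (cell - 1L) * M + match(met, net$metabolites)
  tme_row <- stats::setNames(n_cells * M + seq_len(Nblood), blood_metabolites)

  per_cell <- N + Next
  ncols <- n_cells * per_cell + Nblood
  col_names <- character(ncols)
  col_kind <- character(ncols)
  col_cell <- rep(NA_integer_, ncols)
  col_template <- character(ncols)
  col_species <- rep(NA_character_, ncols)
  lb <- numeric(ncols)
  ub <- numeric(ncols)

  ti <- tj <- tx <- vector("list", ncols)
  put <- function(k, rows, vals) {
    ti[[k]] <<- rows; tj[[k]] <<- rep.int(k, length(rows)); tx[[k]] <<- vals
  }

  for (cell in seq_len(n_cells)) {
    base <- (cell - 1L) * per_cell
    for (i in seq_along(internal)) {
      r <- net$reactions[[internal[i]]]
      k <- base + i
      col_names[k] <- paste0(r$id, "_cell", cell)
      col_kind[k] <- "internal"
      col_cell[k] <- cell
      col_template[k] <- r$id
      lb[k] <- r$lb; ub[k] <- r$ub
      put(k, vapply(names(r$stoich), met_row, integer(1), cell = cell),
          unname(r$stoich))
    }
    for (j in seq_len(Next)) {
      eid <- net$exchanges[j]
      sp <- ex_sp[[eid]]
      k <- base + N + j
      col_names[k] <- paste0(eid, "_cell", cell)
      col_kind[k] <- "cooperation"
      col_cell[k] <- cell
      col_template[k] <- eid
      col_species[k] <- sp
      if (sp %in% blood_metabolites) {
        lb[k] <- -coop_big; ub[k] <- coop_big
        put(k, c(met_row(sp, cell), tme_row[[sp]]), c(-1, 1))
      } else {
        lb[k] <- 0; ub[k] <- 0  # no TME pool: species not exchangeable
        put(k, met_row(sp, cell), -1)
      }
    }
  }
  for (j in seq_len(Nblood)) {
    sp <- blood_metabolites[j]
    k <- n_cells * per_cell + j
    col_names[k] <- paste0("B_", sp)
    col_kind[k] <- "blood"
    col_template[k] <- sp
    col_species[k] <- sp
    lb[k] <- -coop_big * n_cells; ub[k] <- coop_big * n_cells
    put(k, tme_row[[sp]], -1)
  }

  S <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n_cells * M + Nblood, ncols),
                            dimnames = list(row_names, col_names))
  columns <- data.frame(col = col_names, kind = col_kind, cell = col_cell,
                        template_id = col_template, species = col_species,
                        stringsAsFactors = FALSE)
  names(lb) <- names(ub) <- col_names

  objective_column <- if (!is.na(bm)) paste0("B_", bm) else NA_character_
  structure(list(S = S, columns = columns, lb = lb, ub = ub,
                 n_cells = n_cells, net = net,
                 blood_species = blood_metabolites,
                 biomass_species = bm,
                 objective_column = objective_column,
                 medium = NULL, coop_big = coop_big),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d cells; S: %d x %d; blood species: %d%s\n",
              x$n_cells, nrow(x$S), ncol(x$S), length(x$blood_species),
              if (is.null(x$medium)) "" else "; medium applied"))
  invisible(x)
}

# column names for a template reaction across cells
model_columns <- function(model, template_id, cells = seq_len(model$n_cells)) {
  paste0(template_id, "_cell", cells)
}

#' Specify the medium / boundary configuration
#'
#' Type-1 constraints: what the population as a whole may take up from or
#' secrete into the blood. Uptake rates are per-cell rates in nmol/h,
#' scaled by the population size `n_pop` (total uptake bound
#' `n_pop * rate`). Secretable species keep both their TME cooperation
#' route and an unbounded direct blood-secretion route, so that blocking
#' cooperation never prevents mere waste disposal.
#'
#' @param uptake named numeric vector: species -> maximal per-cell uptake
#'   rate (nmol/h); the population bound is `n_pop * rate`.
#' @param secrete character vector of species that may be secreted into
#'   the blood.
#' @param n_pop population size used to scale uptake bounds.
#' @return an object of class `medium_spec`.
#' @export
medium_spec <- function(uptake, secrete = character(), n_pop) {
  stopifnot(is.numeric(uptake), !is.null(names(uptake)), all(uptake >= 0),
            n_pop >= 1)
  structure(list(uptake = uptake, secrete = as.character(secrete),
                 n_pop = n_pop), class = "medium_spec")
}

#' Apply a medium to a population model
#'
#' Sets the blood-exchange bounds: uptake species get `[-n_pop * rate, 0]`
#' (plus secretion when also listed as secretable), secretable species get
#' `[0, Inf)`, the biomass drain stays `[0, Inf)`, and every other blood
#' exchange is closed. Cooperation bounds are untouched, so secretable
#' species retain their TME route.
#'
#' @param model a [build_population_model()] result.
#' @param medium a [medium_spec()].
#' @return the constrained `population_model`.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "population_model"), inherits(medium, "medium_spec"))
  known <- model$blood_species
  unknown <- setdiff(c(names(medium$uptake), medium$secrete), known)
  if (length(unknown)) {
    stop("medium names species without a blood exchange: ",
         paste(unknown, collapse = ", "))
  }
  for (sp in known) {
    col <- paste0("B_", sp)
    up <- if (sp %in% names(medium$uptake)) medium$uptake[[sp]] else NA_real_
    sec <- sp %in% medium$secrete || identical(sp, model$biomass_species)
    model$lb[col] <- if (!is.na(up)) -medium$n_pop * up else 0
    model$ub[col] <- if (sec) Inf else 0
  }
  model$medium <- medium
  model
}
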