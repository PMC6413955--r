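#' Construct a template metabolic network
#'
#' The template network `A = (X_A, R_A, E_A)` is the single-cell map that the
#' population model replicates: `X_A` the metabolites, `R_A` the internal
#' reactions and `E_A` the exchange (unbalanced, single-metabolite) reactions
#' through which a subset `Y` of metabolites — including the biomass
#' pseudo-metabolite — enters or leaves the system.
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions list of reaction records. Each record is a list with
#'   elements `id`, `stoich` (named numeric, metabolite -> coefficient,
#'   negative = consumed), `reversible` (logical), optional `lb`/`ub`
#'   (defaults `-1000/0` and `1000` nmol/h depending on reversibility),
#'   optional `gpr` (a `gpr_rule` or a GPR string).
#' @param exchanges character vector of reaction ids to classify as
#'   exchanges. When `NULL`, exchanges are auto-detected as the reactions
#'   with exactly one metabolite participant.
#' @param biomass_reaction_id id of the reaction producing the biomass
#'   pseudo-metabolite. When `NULL`, the first internal reaction whose id
#'   matches `"biomass"` (case-insensitively) is used.
#' @param gpr_excluded reaction ids whose GPR must be ignored when scoring
#'   (e.g. electron-transport-chain complexes whose AND rules over dozens of
#'   subunits would unrealistically zero the score).
#' @return an object of class `template_network`.
#' @export
template_network <- function(metabolites, reactions, exchanges = NULL,
                             biomass_reaction_id = NULL,
                             gpr_excluded = character()) {
  stopifnot(is.character(metabolites), length(metabolites) >= 1L,
            !anyDuplicated(metabolites), is.list(reactions))
  rxns <- lapply(reactions, normalize_reaction_record, metabolites = metabolites)
  ids <- vapply(rxns, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(rxns) <- ids

  if (is.null(exchanges)) {
    exchanges <- ids[vapply(rxns, function(r) length(r$stoich) == 1L, logical(1))]
  } else {
    missing <- setdiff(exchanges, ids)
    if (length(missing)) stop("unknown exchange reaction ids: ",
                              paste(missing, collapse = ", "))
  }
  for (e in exchanges) {
    if (length(rxns[[e]]$stoich) != 1L) {
      stop(sprintf("exchange reaction '%s' must touch exactly one metabolite", e))
    }
  }

  if (is.null(biomass_reaction_id)) {
    cand <- setdiff(ids[grepl("biomass", ids, ignore.case = TRUE)], exchanges)
    biomass_reaction_id <- if (length(cand)) cand[1] else NA_character_
  } else if (!biomass_reaction_id %in% ids) {
    stop("biomass_reaction_id '", biomass_reaction_id, "' not among reactions")
  }

  bad <- setdiff(gpr_excluded, ids)
  if (length(bad)) stop("gpr_excluded names unknown reactions: ",
                        paste(bad, collapse = ", "))

  structure(list(metabolites = metabolites, reactions = rxns,
                 exchanges = exchanges,
                 biomass_reaction_id = biomass_reaction_id,
                 gpr_excluded = gpr_excluded),
            class = "template_network")
}

normalize_reaction_record <- function(r, metabolites) {
  stopifnot(is.list(r), !is.null(r$id), !is.null(r$stoich))
  st <- r$stoich
  if (is.null(names(st)) || any(!nzchar(names(st)))) {
    stop("reaction '", r$id, "': stoichiometry must be a named numeric vector")
  }
  unknown <- setdiff(names(st), metabolites)
  if (length(unknown)) {
    stop("reaction '", r$id, "': unknown metabolites ",
         paste(unknown, collapse = ", "))
  }
  st <- st[st != 0]
  rev <- isTRUE(r$reversible)
  lb <- if (!is.null(r$lb)) as.numeric(r$lb) else if (rev) -1000 else 0
  ub <- if (!is.null(r$ub)) as.numeric(r$ub) else 1000
  if (lb > ub) stop("reaction '", r$id, "': lb > ub")
  gpr <- r$gpr
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (!is.null(gpr) && !inherits(gpr, "gpr_rule")) {
    stop("reaction '", r$id, "': gpr must be a string or gpr_rule")
  }
  list(id = as.character(r$id), stoich = st, reversible = rev,
       lb = lb, ub = ub, gpr = gpr)
}

#' @export
print.template_network <- function(x, ...) {
  cat(sprintf("<template_network> %d metabolites, %d internal reactions, %d exchanges\n",
              n_metabolites(x), n_internal(x), n_exchanges(x)))
  cat(sprintf("  biomass reaction: %s; genes: %d; GPR-excluded: %d\n",
              x$biomass_reaction_id, length(network_genes(x)),
              length(x$gpr_excluded)))
  invisible(x)
}

#' @rdname template_network
#' @param net a `template_network`.
#' @export
n_metabolites <- function(net) length(net$metabolites)

#' @rdname template_network
#' @export
n_internal <- function(net) length(internal_reactions(net))

#' @rdname template_network
#' @export
n_exchanges <- function(net) length(net$exchanges)

#' @rdname template_network
#' @export
internal_reactions <- function(net) setdiff(names(net$reactions), net$exchanges)

#' Species reachable through the exchange reactions
#'
#' @param net a `template_network`.
#' @return named character vector: exchange reaction id -> its metabolite.
#' @export
exchange_species <- function(net) {
  vapply(net$reactions[net$exchanges],
         function(r) names(r$stoich), character(1))
}

#' All genes appearing in any GPR of the network
#'
#' @param net a `template_network`.
#' @param include_excluded also count genes of GPR-excluded reactions
#'   (default `TRUE`; exclusion affects scoring, not membership).
#' @return character vector of gene ids.
#' @export
network_genes <- function(net, include_excluded = TRUE) {
  ids <- names(net$reactions)
  if (!include_excluded) ids <- setdiff(ids, net$gpr_excluded)
  gs <- lapply(net$reactions[ids], function(r) {
    if (is.null(r$gpr)) character() else gpr_genes(r$gpr)
  })
  unique(unlist(gs, use.names = FALSE))
}

# Biomass pseudo-metabolite: the exchanged product of the biomass reaction.
biomass_species <- function(net) {
  if (is.na(net$biomass_reaction_id)) return(NA_character_)
  st <- net$reactions[[net$biomass_reaction_id]]$stoich
  prod <- names(st)[st > 0]
  hit <- intersect(prod, unname(exchange_species(net)))
  if (length(hit)) hit[1] else if (length(prod)) prod[1] else NA_character_
}

#' Delete genes from a template network
#'
#' Evaluates every GPR with the deleted genes set to `FALSE` and all other
#' genes `TRUE`, removes reactions whose rule becomes `FALSE` (their enzyme
#' can no longer be formed), simplifies the surviving rules (pruned isoforms
#' stay pruned, so deletions compose), and drops metabolites that no longer
#' participate in any reaction. Reactions without a GPR are untouched.
#'
#' @param net a `template_network`.
#' @param genes character vector of gene ids; ids absent from the network
#'   are ignored. An empty set returns the network unchanged.
#' @return the reduced `template_network` (the subnetwork `A*` when applied
#'   to the bulk-off gene set `G_off`).
#' @export
delete_genes <- function(net, genes) {
  stopifnot(inherits(net, "template_network"))
  genes <- as.character(genes)
  if (length(genes) == 0L) return(net)
  keep <- character()
  rxns <- list()
  for (id in names(net$reactions)) {
    r <- net$reactions[[id]]
    if (!is.null(r$gpr)) {
      r$gpr <- gpr_delete(r$gpr, genes)
      if (is.null(r$gpr)) next  # rule is FALSE: reaction removed
    }
    rxns[[id]] <- r
    keep <- c(keep, id)
  }
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoich)),
                        use.names = FALSE))
  mets <- intersect(net$metabolites, used)
  biomass <- if (!is.na(net$biomass_reaction_id) &&
                 net$biomass_reaction_id %in% keep) net$biomass_reaction_id else NULL
  template_network(metabolites = mets, reactions = rxns,
                   exchanges = intersect(net$exchanges, keep),
                   biomass_reaction_id = biomass,
                   gpr_excluded = intersect(net$gpr_excluded, keep))
}

#' Reactions disabled by a gene deletion
#'
#' @param net a `template_network`.
#' @param genes genes set to `FALSE`.
#' @return character vector of reaction ids whose GPR evaluates `FALSE`.
#' @export
disabled_reactions <- function(net, genes) {
  ids <- names(net$reactions)
  hit <- vapply(ids, function(id) {
    g <- net$reactions[[id]]$gpr
    !is.null(g) && !eval_gpr(g, genes)
  }, logical(1))
  ids[hit]
}

#' Serialize a template network to a plain list / JSON
#'
#' @param net a `template_network`.
#' @param path optional file; when given, pretty-printed JSON is written.
#' @return (invisibly) the plain-list representation.
#' @export
network_to_json <- function(net, path = NULL) {
  obj <- list(
    metabolites = net$metabolites,
    reactions = lapply(unname(net$reactions), function(r) {
      list(id = r$id, stoich = as.list(r$stoich), reversible = r$reversible,
           lb = r$lb, ub = r$ub,
           gpr = if (is.null(r$gpr)) NULL else format(r$gpr))
    }),
    exchanges = net$exchanges,
    biomass_reaction_id = net$biomass_reaction_id,
    gpr_excluded = net$gpr_excluded
  )
  if (!is.null(path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  }
  invisible(obj)
}
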