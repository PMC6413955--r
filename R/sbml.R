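#' Read a template metabolic network from SBML
#'
#' Supports SBML Level 3 with the `fbc` package (gene associations as
#' `fbc:geneProductAssociation`, bounds as flux-bound parameters) as well as
#' the older COBRA dialect (GPR strings in `GENE_ASSOCIATION:` notes, bounds
#' as kinetic-law parameters). When both dialects carry a GPR for the same
#' reaction the `fbc` association wins. Exchange reactions are auto-detected
#' as reactions touching exactly one (non-boundary) species; an explicit
#' `exchange_ids` list overrides the detection. Reversibility is taken from
#' the lower bound (`lb < 0`), falling back on the `reversible` attribute
#' when no bound information is present.
#'
#' @param path SBML file.
#' @param gpr_excluded reaction ids whose GPR is dropped from scoring (the
#'   rule is parsed but not attached); unknown ids raise an error.
#' @param gene_map optional two-column data.frame (`from`, `to`) applied to
#'   gene identifiers at load time (e.g. Ensembl to HGNC).
#' @param exchange_ids optional explicit exchange reaction ids.
#' @return a [template_network()].
#' @export
read_sbml_network <- function(path, gpr_excluded = character(),
                              gene_map = NULL, exchange_ids = NULL) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))

  species_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(species_nodes) == 0L) stop("malformed SBML: no <species> elements in ", path)
  sp_attr <- lapply(species_nodes, xml2::xml_attrs)
  sp_id <- vapply(sp_attr, function(a) a[["id"]], character(1))
  sp_boundary <- vapply(sp_attr, function(a) {
    isTRUE(tolower(a["boundaryCondition"]) %in% "true")
  }, logical(1))
  metabolites <- sp_id[!sp_boundary]

  # flux-bound parameters (fbc style)
  par_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(par_nodes, function(p) as.numeric(xml2::xml_attr(p, "value")), numeric(1)),
    vapply(par_nodes, function(p) xml2::xml_attr(p, "id"), character(1)))

  # fbc gene products: fbc:id -> label (fall back on id)
  gp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='geneProduct']")
  gp_map <- character()
  if (length(gp_nodes)) {
    gp_ids <- vapply(gp_nodes, function(n) attr_any(n, c("fbc:id", "id")), character(1))
    gp_lab <- vapply(gp_nodes, function(n) attr_any(n, c("fbc:label", "label")), character(1))
    gp_lab[is.na(gp_lab)] <- gp_ids[is.na(gp_lab)]
    gp_map <- stats::setNames(gp_lab, gp_ids)
  }

  rxn_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxn_nodes) == 0L) stop("malformed SBML: no <reaction> elements in ", path)

  reactions <- lapply(rxn_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    st <- sbml_stoichiometry(node, keep = metabolites)
    rev_attr <- isTRUE(tolower(xml2::xml_attr(node, "reversible")) %in% "true")
    b <- sbml_bounds(node, par_val, rev_attr)
    gpr <- sbml_gpr(node, gp_map, rid)
    if (!is.null(gpr) && !is.null(gene_map)) gpr <- remap_gpr(gpr, gene_map)
    reversible <- if (is.na(b$lb)) rev_attr else b$lb < 0
    list(id = rid, stoich = st, reversible = reversible,
         lb = if (is.na(b$lb)) NULL else b$lb,
         ub = if (is.na(b$ub)) NULL else b$ub,
         gpr = gpr)
  })
  rids <- vapply(reactions, `[[`, character(1), "id")

  bad <- setdiff(gpr_excluded, rids)
  if (length(bad)) stop("gpr_excluded names unknown reactions: ",
                        paste(bad, collapse = ", "))
  for (i in which(rids %in% gpr_excluded)) reactions[[i]]$gpr <- NULL

  # biomass: fbc objective wins, then id heuristic inside template_network()
  obj_node <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  biomass_id <- NULL
  if (!inherits(obj_node, "xml_missing")) {
    cand <- attr_any(obj_node, c("fbc:reaction", "reaction"))
    if (!is.na(cand) && cand %in% rids) biomass_id <- cand
  }

  template_network(metabolites = metabolites, reactions = reactions,
                   exchanges = exchange_ids,
                   biomass_reaction_id = biomass_id,
                   gpr_excluded = gpr_excluded)
}

attr_any <- function(node, names) {
  a <- xml2::xml_attrs(node)
  for (nm in names) {
    hit <- match(nm, names(a))
    if (!is.na(hit)) return(unname(a[hit]))
    # namespace prefixes may differ; match on local part too
    loc <- sub(".*:", "", names(a))
    hit <- match(sub(".*:", "", nm), loc)
    if (!is.na(hit)) return(unname(a[hit]))
  }
  NA_character_
}

sbml_stoichiometry <- function(node, keep) {
  st <- numeric()
  add <- function(refs, sign) {
    for (ref in refs) {
      sp <- xml2::xml_attr(ref, "species")
      coef <- xml2::xml_attr(ref, "stoichiometry")
      coef <- if (is.na(coef)) 1 else as.numeric(coef)
      if (is.na(coef)) stop("malformed SBML: non-numeric stoichiometry for species '",
                            sp, "'")
      if (sp %in% keep) st[sp] <<- (if (sp %in% names(st)) st[[sp]] else 0) + sign * coef
    }
  }
  add(xml2::xml_find_all(node, "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']"), -1)
  add(xml2::xml_find_all(node, "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']"), +1)
  st[st != 0]
}

sbml_bounds <- function(node, par_val, rev_attr) {
  lb_ref <- attr_any(node, c("fbc:lowerFluxBound", "lowerFluxBound"))
  ub_ref <- attr_any(node, c("fbc:upperFluxBound", "upperFluxBound"))
  lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]] else NA_real_
  ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]] else NA_real_
  if (is.na(lb) || is.na(ub)) {  # legacy kinetic-law parameters
    kl <- xml2::xml_find_all(node, ".//*[local-name()='parameter']")
    for (p in kl) {
      pid <- toupper(xml2::xml_attr(p, "id"))
      val <- as.numeric(xml2::xml_attr(p, "value"))
      if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- val
      if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- val
    }
  }
  list(lb = lb, ub = ub)
}

sbml_gpr <- function(node, gp_map, rid) {
  gpa <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
  if (!inherits(gpa, "xml_missing")) {
    kids <- xml2::xml_find_all(gpa, "./*")
    if (length(kids) != 1L) {
      stop("unresolvable GPR for reaction '", rid,
           "': geneProductAssociation must have one child")
    }
    tree <- fbc_gpr_tree(kids[[1]], gp_map, rid)
    return(structure(tree, class = "gpr_rule"))
  }
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (!inherits(notes, "xml_missing")) {
    txt <- xml2::xml_text(notes)
    m <- regmatches(txt, regexec("GENE[ _]ASSOCIATION:\\s*([^\n<]+)", txt))[[1]]
    if (length(m) == 2L && nzchar(trimws(m[2]))) {
      rule <- tryCatch(parse_gpr(trimws(m[2])),
                       error = function(e) stop("unresolvable GPR for reaction '",
                                                rid, "': ", conditionMessage(e),
                                                call. = FALSE))
      return(rule)
    }
  }
  NULL
}

fbc_gpr_tree <- function(node, gp_map, rid) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- attr_any(node, c("fbc:geneProduct", "geneProduct"))
    if (is.na(ref)) stop("unresolvable GPR for reaction '", rid,
                         "': geneProductRef without target")
    gene <- if (ref %in% names(gp_map)) gp_map[[ref]] else ref
    return(list(gene = gene))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_find_all(node, "./*"), fbc_gpr_tree,
                   gp_map = gp_map, rid = rid)
    if (length(kids) == 1L) return(kids[[1]])
    return(list(op = nm, children = kids))
  }
  stop("unresolvable GPR for reaction '", rid, "': unknown element <", nm, ">")
}

remap_gpr <- function(rule, gene_map) {
  stopifnot(ncol(gene_map) >= 2L)
  from <- as.character(gene_map[[1]]); to <- as.character(gene_map[[2]])
  walk <- function(node) {
    if (is_gpr_leaf(node)) {
      i <- match(node$gene, from)
      if (!is.na(i)) node$gene <- to[i]
      return(node)
    }
    node$children <- lapply(node$children, walk)
    node
  }
  structure(walk(rule), class = "gpr_rule", source = attr(rule, "source", exact = TRUE))
}

#' Write a template network as SBML Level 3 (fbc v2)
#'
#' Emits a self-contained SBML document with one compartment, flux-bound
#' parameters, `fbc` gene-product associations and a biomass objective, such
#' that [read_sbml_network()] round-trips the network exactly and standard
#' readers (e.g. COBRA implementations) can load it.
#'
#' @param net a [template_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_network <- function(net, path) {
  stopifnot(inherits(net, "template_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  genes <- network_genes(net)
  gene_fbc_id <- stats::setNames(paste0("G_", gsub("[^A-Za-z0-9_]", "_", genes)), genes)

  bvals <- sort(unique(unlist(lapply(net$reactions, function(r) c(r$lb, r$ub)))))
  par_id <- stats::setNames(paste0("fb_", seq_along(bvals)),
                            vapply(bvals, format, character(1), digits = 17))
  pid_of <- function(v) par_id[[format(v, digits = 17)]]

  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
                'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
                'level="3" version="1" fbc:required="false">'),
         '  <model id="model" fbc:strict="true">',
         '    <listOfCompartments>',
         '      <compartment id="c" constant="true"/>',
         '    </listOfCompartments>',
         '    <listOfSpecies>')
  for (m in net$metabolites) {
    L <- c(L, sprintf('      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>', esc(m)))
  }
  L <- c(L, '    </listOfSpecies>', '    <listOfParameters>')
  for (i in seq_along(bvals)) {
    L <- c(L, sprintf('      <parameter id="fb_%d" value="%s" constant="true"/>',
                      i, format(bvals[i], digits = 17)))
  }
  L <- c(L, '    </listOfParameters>', '    <listOfReactions>')
  for (r in net$reactions) {
    L <- c(L, sprintf('      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
                      esc(r$id), tolower(as.character(r$reversible)),
                      pid_of(r$lb), pid_of(r$ub)))
    if (!is.null(r$gpr)) {
      L <- c(L, '        <fbc:geneProductAssociation>',
             gpr_to_fbc(r$gpr, gene_fbc_id, indent = "          "),
             '        </fbc:geneProductAssociation>')
    }
    reac <- r$stoich[r$stoich < 0]; prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      L <- c(L, '        <listOfReactants>',
             sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                     esc(names(reac)), format(-unname(reac), digits = 17)),
             '        </listOfReactants>')
    }
    if (length(prod)) {
      L <- c(L, '        <listOfProducts>',
             sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                     esc(names(prod)), format(unname(prod), digits = 17)),
             '        </listOfProducts>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>')
  if (length(genes)) {
    L <- c(L, '    <fbc:listOfGeneProducts>',
           sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                   unname(gene_fbc_id), esc(names(gene_fbc_id))),
           '    </fbc:listOfGeneProducts>')
  }
  if (!is.na(net$biomass_reaction_id)) {
    L <- c(L, '    <fbc:listOfObjectives fbc:activeObjective="obj">',
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           '        <fbc:listOfFluxObjectives>',
           sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                   esc(net$biomass_reaction_id)),
           '        </fbc:listOfFluxObjectives>',
           '      </fbc:objective>',
           '    </fbc:listOfObjectives>')
  }
  L <- c(L, '  </model>', '</sbml>')
  writeLines(L, path)
  invisible(path)
}

gpr_to_fbc <- function(node, gene_fbc_id, indent) {
  if (is_gpr_leaf(node)) {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   indent, gene_fbc_id[[node$gene]]))
  }
  inner <- unlist(lapply(node$children, gpr_to_fbc, gene_fbc_id = gene_fbc_id,
                         indent = paste0(indent, "  ")))
  c(sprintf("%s<fbc:%s>", indent, node$op), inner,
    sprintf("%s</fbc:%s>", indent, node$op))
}
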