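#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses a Boolean gene association string (genes combined with `and` / `or`,
#' case-insensitive, with optional parentheses) into an expression tree. `and`
#' binds tighter than `or`, matching the standard precedence used in
#' constraint-based modelling toolboxes: `"g1 or g2 and g3"` is read as
#' `OR(g1, AND(g2, g3))`.
#'
#' @param text a single non-empty GPR string. Gene identifiers are opaque
#'   tokens: any run of characters that is not whitespace, a parenthesis, or
#'   one of the two operators.
#' @return an object of class `gpr_rule`: a tree whose internal nodes are
#'   `and` / `or` with two or more children and whose leaves are gene ids.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("GPR rule must be a single non-empty string")
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("GPR parse error in '%s': unexpected token '%s' at position %d",
                 text, st$toks[st$pos], st$pos))
  }
  structure(node, class = "gpr_rule", source = text)
}

gpr_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  regmatches(text, list(m))[[1]]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_take <- function(st) {
  t <- gpr_peek(st)
  st$pos <- st$pos + 1L
  t
}

gpr_parse_or <- function(st, text) {
  children <- list(gpr_parse_and(st, text))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    gpr_take(st)
    children <- c(children, list(gpr_parse_and(st, text)))
  }
  if (length(children) == 1L) children[[1]] else list(op = "or", children = children)
}

gpr_parse_and <- function(st, text) {
  children <- list(gpr_parse_atom(st, text))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    gpr_take(st)
    children <- c(children, list(gpr_parse_atom(st, text)))
  }
  if (length(children) == 1L) children[[1]] else list(op = "and", children = children)
}

gpr_parse_atom <- function(st, text) {
  tok <- gpr_take(st)
  if (is.na(tok)) {
    stop(sprintf("GPR parse error in '%s': dangling operator at position %d",
                 text, st$pos - 1L))
  }
  if (tok == "(") {
    node <- gpr_parse_or(st, text)
    closing <- gpr_take(st)
    if (is.na(closing) || closing != ")") {
      stop(sprintf("GPR parse error in '%s': unbalanced parenthesis at position %d",
                   text, st$pos - 1L))
    }
    return(node)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop(sprintf("GPR parse error in '%s': unexpected '%s' at position %d",
                 text, tok, st$pos - 1L))
  }
  list(gene = tok)
}

is_gpr_leaf <- function(node) !is.null(node$gene)

#' Genes referenced by a GPR rule
#'
#' @param rule a `gpr_rule` (or internal node).
#' @return character vector of distinct gene ids, in first-appearance order.
#' @export
gpr_genes <- function(rule) {
  if (is_gpr_leaf(rule)) return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_genes), use.names = FALSE))
}

#' Evaluate a GPR rule with true/false gene states
#'
#' Genes listed in `false_genes` evaluate to `FALSE`, all others to `TRUE`.
#' Used for gene-deletion analysis: a reaction whose rule evaluates `FALSE`
#' loses its catalyst and is disabled.
#'
#' @param rule a `gpr_rule`.
#' @param false_genes character vector of deleted gene ids.
#' @return logical scalar.
#' @export
eval_gpr <- function(rule, false_genes = character()) {
  if (is_gpr_leaf(rule)) return(!(rule$gene %in% false_genes))
  vals <- vapply(rule$children, eval_gpr, logical(1), false_genes = false_genes)
  if (rule$op == "and") all(vals) else any(vals)
}

#' Reaction activity score of a GPR rule for one expression profile
#'
#' Scores a rule against a named vector of transcript abundances (TPM):
#' `and` nodes (enzyme subunits) take the minimum of their children, `or`
#' nodes (isoforms) take the sum, applied recursively through composite
#' rules. Genes absent from `expr` are treated as non-limiting: they are
#' dropped from `or` sums and ignored (as if infinitely abundant) in `and`
#' minima. If no gene of the rule is measured the score is `NA` and the
#' reaction is left unscored.
#'
#' @param rule a `gpr_rule`.
#' @param expr named numeric vector, gene id -> TPM, for a single cell.
#' @return numeric score (>= 0), or `NA_real_` if no leaf is measured.
#' @export
eval_ras <- function(rule, expr) {
  if (is_gpr_leaf(rule)) {
    idx <- match(rule$gene, names(expr))
    return(if (is.na(idx)) NA_real_ else as.numeric(expr[[idx]]))
  }
  vals <- vapply(rule$children, eval_ras, numeric(1), expr = expr)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (rule$op == "and") min(vals) else sum(vals)
}

# Substitute FALSE for the given genes and simplify the tree.
# Returns the simplified rule, or NULL when the whole rule is FALSE.
# Simplification keeps deletion composable: pruned isoforms stay pruned,
# so a later deletion of the surviving isoform disables the reaction.
gpr_delete <- function(rule, genes) {
  simplified <- gpr_delete_node(rule, genes)
  if (is.null(simplified)) return(NULL)
  structure(simplified, class = "gpr_rule",
            source = attr(rule, "source", exact = TRUE))
}

gpr_delete_node <- function(node, genes) {
  if (is_gpr_leaf(node)) {
    return(if (node$gene %in% genes) NULL else node)
  }
  kids <- lapply(node$children, gpr_delete_node, genes = genes)
  if (node$op == "and") {
    if (any(vapply(kids, is.null, logical(1)))) return(NULL)
    return(list(op = "and", children = kids))
  }
  kids <- kids[!vapply(kids, is.null, logical(1))]
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1]])
  list(op = "or", children = kids)
}

#' @export
format.gpr_rule <- function(x, ...) gpr_deparse(x, top = TRUE)

gpr_deparse <- function(node, top = FALSE) {
  if (is_gpr_leaf(node)) return(node$gene)
  parts <- vapply(node$children, function(ch) {
    s <- gpr_deparse(ch)
    needs_paren <- !is_gpr_leaf(ch) && node$op == "and" && ch$op == "or"
    if (needs_paren) paste0("(", s, ")") else s
  }, character(1))
  s <- paste(parts, collapse = paste0(" ", node$op, " "))
  if (top) s else s
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", format(x), "\n", sep = "")
  invisible(x)
}
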