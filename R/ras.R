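#' Compute the reaction activity score matrix
#'
#' For every reaction carrying a usable GPR — a rule exists, the reaction is
#' not GPR-excluded, and at least one of its genes is present in the
#' expression matrix — the per-cell score is computed with [eval_ras()]:
#' minimum over enzyme subunits (`and`), sum over isoforms (`or`). Scores
#' are computed on the post-reconciliation matrix so that bulk-replaced
#' rows contribute their bulk value.
#'
#' @param net a [template_network()], normally the post-deletion subnetwork
#'   `A*`.
#' @param data an [expression_data()], preprocessed via
#'   [reconcile_with_bulk()].
#' @return an object of class `ras_matrix` with fields `ras` (scored
#'   reactions x cells), `normalized` (`NULL` until [normalize_ras()]) and
#'   `scored_reactions`.
#' @export
compute_ras_matrix <- function(net, data) {
  stopifnot(inherits(net, "template_network"), inherits(data, "expression_data"))
  if (is.null(data$gene_status)) {
    warning("expression data has no gene_status; run reconcile_with_bulk() first")
  }
  m <- data$mat
  measured <- rownames(m)
  candidates <- setdiff(names(net$reactions), net$gpr_excluded)
  candidates <- candidates[vapply(candidates, function(id) {
    g <- net$reactions[[id]]$gpr
    !is.null(g) && length(intersect(gpr_genes(g), measured)) > 0L
  }, logical(1))]
  if (length(candidates) == 0L) {
    stop("no reaction has a GPR overlapping the expression matrix genes")
  }
  ras <- matrix(0, nrow = length(candidates), ncol = ncol(m),
                dimnames = list(candidates, colnames(m)))
  for (cell in seq_len(ncol(m))) {
    expr <- stats::setNames(m[, cell], rownames(m))  # names drop when nrow==1
    for (id in candidates) {
      ras[id, cell] <- eval_ras(net$reactions[[id]]$gpr, expr)
    }
  }
  structure(list(ras = ras, normalized = NULL, scored_reactions = candidates),
            class = "ras_matrix")
}

#' Normalize activity scores across cells
#'
#' Divides each reaction's scores by its total activity over all cells,
#' giving the relative activity share of each cell in `[0, 1]` (rows sum to
#' 1). Reactions with zero total activity get an all-zero normalized row:
#' downstream, every cell then receives the epsilon flux floor, mitigating
#' scRNA-seq false negatives.
#'
#' @param ras a `ras_matrix`.
#' @return the `ras_matrix` with the `normalized` field filled.
#' @export
normalize_ras <- function(ras) {
  stopifnot(inherits(ras, "ras_matrix"))
  totals <- rowSums(ras$ras)
  norm <- ras$ras / ifelse(totals > 0, totals, 1)
  norm[totals == 0, ] <- 0
  ras$normalized <- norm
  ras
}

#' @export
print.ras_matrix <- function(x, ...) {
  cat(sprintf("<ras_matrix> %d scored reactions x %d cells (%s)\n",
              nrow(x$ras), ncol(x$ras),
              if (is.null(x$normalized)) "raw" else "raw + normalized"))
  invisible(x)
}

#' Export raw and normalized scores as TSV
#'
#' @param ras a `ras_matrix`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_ras <- function(ras, dir) {
  stopifnot(inherits(ras, "ras_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ras.tsv", "ras_normalized.tsv"))
  write_matrix_tsv(ras$ras, paths[1], "reaction")
  if (!is.null(ras$normalized)) write_matrix_tsv(ras$normalized, paths[2], "reaction")
  invisible(paths)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
}
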