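#' Construct a single-cell expression container
#'
#' Holds the genes x cells matrix `T` of normalized read counts (TPM), the
#' optional matched bulk profile, and — after preprocessing — a per-gene
#' status classifying how single-cell zeros were reconciled against the bulk.
#'
#' @param mat numeric matrix, genes as rows (rownames = gene ids), cells as
#'   columns (colnames = cell ids); entries must be finite and `>= 0`.
#' @param bulk optional named numeric vector of bulk TPM; must cover every
#'   gene of `mat`.
#' @return an object of class `expression_data` with fields `mat`, `bulk`,
#'   `gene_status` (`NULL` until [reconcile_with_bulk()] is run).
#' @export
expression_data <- function(mat, bulk = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(mat))) stop("duplicate cell ids")
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid expression value at (gene '%s', cell '%s'): %s",
                 rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]],
                 format(mat[bad[1, , drop = FALSE]])))
  }
  if (!is.null(bulk)) {
    if (is.null(names(bulk))) stop("bulk vector must be named by gene")
    missing <- setdiff(rownames(mat), names(bulk))
    if (length(missing)) {
      stop("bulk profile missing genes: ", paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10) else "")
    }
    bulk <- bulk[rownames(mat)]
  }
  structure(list(mat = mat, bulk = bulk, gene_status = NULL),
            class = "expression_data")
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("<expression_data> %d genes x %d cells; bulk: %s; status: %s\n",
              nrow(x$mat), ncol(x$mat),
              if (is.null(x$bulk)) "absent" else "present",
              if (is.null(x$gene_status)) "unset" else "set"))
  invisible(x)
}

#' Load an expression matrix from TSV/CSV or MatrixMarket files
#'
#' TSV/CSV files must have genes as rows, a header row of cell ids, and gene
#' ids in the first column. MatrixMarket (`.mtx`) input additionally needs
#' two plain-text index files with one gene id (rows) or cell id (columns)
#' per line.
#'
#' @param path matrix file (`.tsv`, `.csv`, `.txt` or `.mtx`).
#' @param bulk_path optional two-column (gene, TPM) headerless TSV/CSV with
#'   the matched bulk profile.
#' @param genes_path,cells_path index files, required for `.mtx` input.
#' @return an [expression_data()] with `gene_status` unset.
#' @export
load_expression <- function(path, bulk_path = NULL,
                            genes_path = NULL, cells_path = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("MTX input needs genes_path and cells_path index files")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop(sprintf("MTX dimensions %dx%d do not match index files (%d genes, %d cells)",
                   nrow(m), ncol(m), length(genes), length(cells)))
    }
    dimnames(m) <- list(genes, cells)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    genes <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(apply(dt[, -1, drop = FALSE], 2, as.numeric))),
                   arr.ind = TRUE)
      stop("non-numeric expression values in ", path)
    }
    rownames(m) <- genes
  }
  bulk <- NULL
  if (!is.null(bulk_path)) {
    if (!file.exists(bulk_path)) stop("bulk file not found: ", bulk_path)
    bdt <- data.table::fread(bulk_path, header = FALSE, data.table = FALSE)
    bulk <- stats::setNames(as.numeric(bdt[[2]]), as.character(bdt[[1]]))
  }
  expression_data(m, bulk = bulk)
}

#' Drop cells with too few detected genes
#'
#' A gene counts as detected in a cell when its value is strictly positive.
#' Cells with strictly fewer than `min_genes_detected` detected genes are
#' removed; the gene set is left unchanged.
#'
#' @param data an [expression_data()].
#' @param min_genes_detected detection threshold (default 5000, the cutoff
#'   used for full-transcriptome single-cell datasets).
#' @return the filtered [expression_data()].
#' @export
filter_cells <- function(data, min_genes_detected = 5000) {
  stopifnot(inherits(data, "expression_data"), min_genes_detected >= 0)
  detected <- colSums(data$mat > 0)
  keep <- detected >= min_genes_detected
  if (!any(keep)) {
    stop(sprintf(paste0("all %d cells have fewer than %d detected genes; ",
                        "lower min_genes_detected"),
                 ncol(data$mat), min_genes_detected))
  }
  data$mat <- data$mat[, keep, drop = FALSE]
  if (!is.null(data$gene_status)) data$gene_status <- NULL
  data
}

#' Reconcile single-cell zeros against the bulk profile
#'
#' scRNA-seq dropouts make zeros ambiguous. With a matched bulk profile,
#' every gene falls into one of three false-negative scenarios plus the
#' regular case:
#'
#' * `OFF_EVERYWHERE` — zero in the bulk and in every cell: the gene is
#'   considered genuinely off, collected in `G_off`, and should be deleted
#'   from the template network ([delete_genes()]), yielding the subnetwork
#'   `A*`.
#' * `BULK_REPLACED` — expressed in the bulk but zero in every cell: the
#'   single-cell signal cannot be trusted, so each cell's value is replaced
#'   by the bulk value.
#' * `HETEROGENEOUS_ZEROS` — expressed in the bulk, zero in only some cells:
#'   values are kept; the zeros are later mapped to the epsilon flux floor
#'   rather than shutting the reaction.
#' * `EXPRESSED` — everything else.
#'
#' Bulk zeros are tested exactly (`== 0`): TPM zeros in these files are
#' literal. Without a bulk profile (and `bulk = "measured"`), all-zero genes
#' become `OFF_EVERYWHERE` and no replacement occurs (with a warning).
#'
#' @param data an [expression_data()].
#' @param bulk `"measured"` to use the stored bulk profile, `"mean"` to use
#'   the per-gene mean of the single-cell matrix as a bulk surrogate. A
#'   measured profile wins when present.
#' @return list with elements `data` (statuses set, replacements applied)
#'   and `g_off` (character vector of off-everywhere genes).
#' @export
reconcile_with_bulk <- function(data, bulk = c("measured", "mean")) {
  stopifnot(inherits(data, "expression_data"))
  bulk <- match.arg(bulk)
  m <- data$mat
  bv <- data$bulk
  if (is.null(bv) && bulk == "mean") bv <- rowMeans(m)
  if (is.null(bv)) {
    warning("no bulk profile available; all-zero genes are treated as off, ",
            "no replacement performed")
    bv <- stats::setNames(rep(NA_real_, nrow(m)), rownames(m))
  }
  bv <- bv[rownames(m)]
  all_zero <- rowSums(m > 0) == 0
  any_zero <- rowSums(m == 0) > 0
  bulk_zero <- !is.na(bv) & bv == 0
  bulk_pos <- !is.na(bv) & bv > 0
  bulk_na <- is.na(bv)

  status <- rep("EXPRESSED", nrow(m))
  status[(bulk_zero | bulk_na) & all_zero] <- "OFF_EVERYWHERE"
  status[bulk_pos & all_zero] <- "BULK_REPLACED"
  status[bulk_pos & !all_zero & any_zero] <- "HETEROGENEOUS_ZEROS"
  names(status) <- rownames(m)
  if (!is.null(data$gene_status)) {
    # re-running is a no-op: rows already bulk-replaced keep their label
    prev <- data$gene_status[rownames(m)]
    status[!is.na(prev) & prev == "BULK_REPLACED"] <- "BULK_REPLACED"
  }

  repl <- which(status == "BULK_REPLACED")
  if (length(repl)) m[repl, ] <- matrix(bv[repl], nrow = length(repl),
                                        ncol = ncol(m))
  data$mat <- m
  data$bulk <- if (all(is.na(bv))) NULL else bv
  data$gene_status <- status
  list(data = data, g_off = names(status)[status == "OFF_EVERYWHERE"])
}
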