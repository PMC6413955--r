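# Linear-programming backend.
#
# No LP solver is available in the R dependency stack of this package's
# target environment, so LPs (FBA, FVA, deletion screens) are delegated to
# the HiGHS solver shipped with SciPy through a small batch bridge: one
# python process per call solves an arbitrary number of LPs sharing the
# same equality matrix S (S v = 0) with per-problem objectives and bound
# overrides. HiGHS is deterministic, so optima are reproducible across
# runs and pivot orders.

LP_INF <- 1e30  # JSON-safe infinity sentinel shared with the python side

lp_python <- function() {
  opt <- getOption("scfba.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found; set options(scfba.python = ...)")
}

lp_script <- function() {
  p <- system.file("python", "lp_batch.py", package = "scfba")
  if (!nzchar(p)) {
    # during development (pkgload) fall back on the source tree
    p <- file.path("inst", "python", "lp_batch.py")
  }
  if (!file.exists(p)) stop("lp_batch.py backend script not found")
  p
}

#' Solve a batch of linear programs sharing one stoichiometric matrix
#'
#' Each problem maximizes (or minimizes) a sparse linear objective subject
#' to `S v = 0` and box constraints, with optional per-problem bound
#' overrides. Used internally for FBA, FVA and deletion screens; exposed
#' for testing and advanced use.
#'
#' @param S sparse (or dense) equality-constraint matrix.
#' @param lb,ub numeric base bounds, length `ncol(S)`; `Inf` allowed.
#' @param problems list of problems; each a list with `obj_idx` (1-based
#'   column indices), `obj_val`, optional `sense` (`"max"` default or
#'   `"min"`), optional `lb_idx`/`lb_val`, `ub_idx`/`ub_val` overrides and
#'   `need_x` (return the flux vector).
#' @return list of results: `status`, `objective` (when optimal), `x`
#'   (when requested).
#' @keywords internal
#' @export
solve_lp_batch <- function(S, lb, ub, problems) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"), "TsparseMatrix")
  stopifnot(length(lb) == ncol(S), length(ub) == ncol(S), length(problems) >= 1L)
  enc <- function(v) {
    v <- as.numeric(v)
    v[v == Inf] <- LP_INF
    v[v == -Inf] <- -LP_INF
    v
  }
  payload <- list(
    S = list(i = S@i, j = S@j, x = S@x, dims = dim(S)),
    lb = enc(lb), ub = enc(ub),
    problems = lapply(problems, function(p) {
      list(sense = if (is.null(p$sense)) "max" else p$sense,
           obj_idx = as.integer(p$obj_idx) - 1L,
           obj_val = as.numeric(p$obj_val),
           lb_idx = as.integer(if (is.null(p$lb_idx)) integer() else p$lb_idx) - 1L,
           lb_val = enc(if (is.null(p$lb_val)) numeric() else p$lb_val),
           ub_idx = as.integer(if (is.null(p$ub_idx)) integer() else p$ub_idx) - 1L,
           ub_val = enc(if (is.null(p$ub_val)) numeric() else p$ub_val),
           need_x = isTRUE(p$need_x),
           parsimonious = isTRUE(p$parsimonious))
    })
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(lp_python(), c(lp_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("LP backend failed (exit ", code, "):\n", paste(status, collapse = "\n"))
  }
  if (!file.exists(fout)) stop("LP backend produced no output")
  jsonlite::fromJSON(fout, simplifyVector = FALSE)
}
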