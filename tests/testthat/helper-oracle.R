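# Independent LP oracle: enumerate basic solutions of
#   max c'x  s.t.  S x = 0, lb <= x <= ub
# For a bounded feasible LP the optimum is attained at a basic solution:
# choose a basis B of |rows| columns, fix the nonbasic variables at one of
# their bounds, solve the square system, keep feasible candidates. Only
# viable for tiny instances (n - m <= ~6); deliberately independent of the
# package's LP backend.
oracle_lp_max <- function(S, lb, ub, obj, tol = 1e-7) {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(obj) == n)
  best <- -Inf
  best_x <- NULL
  consider <- function(x) {
    if (any(x < lb - tol) || any(x > ub + tol)) return()
    if (max(abs(S %*% x)) > tol * max(1, max(abs(x)))) return()
    val <- sum(obj * x)
    if (val > best) {
      best <<- val
      best_x <<- x
    }
  }
  k <- min(m, n)
  basis_sets <- utils::combn(n, k)
  for (bi in seq_len(ncol(basis_sets))) {
    B <- basis_sets[, bi]
    NB <- setdiff(seq_len(n), B)
    SB <- S[, B, drop = FALSE]
    qr_b <- qr(SB)
    if (qr_b$rank < length(B)) next
    if (length(NB) == 0L) {
      xb <- qr.coef(qr_b, rep(0, m))
      x <- numeric(n); x[B] <- xb
      consider(x)
      next
    }
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(NB))))
    for (gi in seq_len(nrow(grid))) {
      xn <- ifelse(grid[gi, ], ub[NB], lb[NB])
      if (any(!is.finite(xn))) next
      rhs <- -S[, NB, drop = FALSE] %*% xn
      xb <- tryCatch(qr.coef(qr_b, rhs), error = function(e) NULL)
      if (is.null(xb) || anyNA(xb)) next
      x <- numeric(n)
      x[B] <- xb
      x[NB] <- xn
      consider(x)
    }
  }
  list(objective = best, x = best_x)
}

# Oracle wrapper over a population model
oracle_optimize <- function(model, obj_cols = model$objective_column) {
  obj <- as.numeric(colnames(model$S) %in% obj_cols)
  lb <- unname(model$lb); ub <- unname(model$ub)
  cap <- 1e5  # the oracle needs finite bounds; far above any toy optimum
  lb[lb == -Inf] <- -cap; ub[ub == Inf] <- cap
  oracle_lp_max(as.matrix(model$S), lb, ub, obj)
}

# Adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  sa <- sc(rowSums(tab)); sb <- sc(colSums(tab))
  expected <- sa * sb / choose(n, 2)
  (sc(as.vector(tab)) - expected) / ((sa + sb) / 2 - expected)
}

# Brute-force recursive GPR interpreter, independent of eval_ras()
brute_ras <- function(node, expr) {
  if (!is.null(node$gene)) {
    if (node$gene %in% names(expr)) return(unname(expr[[node$gene]]))
    return(NA_real_)
  }
  vals <- vapply(node$children, brute_ras, numeric(1), expr = expr)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  if (node$op == "and") min(vals) else sum(vals)
}

# Random GPR tree over a gene pool (for property tests)
random_gpr_tree <- function(genes, depth = 2) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(list(gene = sample(genes, 1)))
  }
  op <- sample(c("and", "or"), 1)
  kids <- lapply(seq_len(sample(2:3, 1)), function(i)
    random_gpr_tree(genes, depth - 1))
  list(op = op, children = kids)
}
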