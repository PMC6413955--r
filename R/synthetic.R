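#' Build a self-contained toy metabolic network
#'
#' Two variants:
#'
#' * `"chain"` — a minimal linear pathway (uptake -> A -> B -> biomass)
#'   used for hand-solvable capacity and LP checks.
#' * `"glycolysis_oxphos_toy"` — a 14-metabolite, 19-reaction cartoon of
#'   core cancer energy metabolism with genuine cooperation potential:
#'   glucose uptake feeds a lumped glycolysis (2 ATP + 1 NADH per glucose),
#'   pyruvate either goes to lactate (regenerating the NADH pool, lactate
#'   exportable to the microenvironment) or is respired with oxygen for 12
#'   ATP; palmitate can be synthesized (4 pyruvate + 7 ATP) or imported, and
#'   biomass consumes pyruvate, ATP and palmitate. GPRs deliberately cover
#'   one isoform (`or`) pair (`glut1 or glut2`, with `glut2` silent in the
#'   simulated data), one subunit (`and`) pair (`fasn1 and fasn2`,
#'   `pdha and pdhb`) and one composite rule
#'   (`(pgk1 or pgk2) and gapdh`), so every scoring path is exercised.
#'   The ATP/ADP moiety is conserved, so ATP can only be spent where it is
#'   regenerated; `ATPM` is the ATP-demand (hydrolysis) reaction used by
#'   the ATP objective. Exchanges carry no GPR.
#'
#' @param variant `"glycolysis_oxphos_toy"` (default) or `"chain"`.
#' @return a [template_network()].
#' @export
make_toy_network <- function(variant = c("glycolysis_oxphos_toy", "chain")) {
  variant <- match.arg(variant)
  if (variant == "chain") {
    return(template_network(
      metabolites = c("n_e", "a", "b", "biomass_met"),
      reactions = list(
        list(id = "T", stoich = c(n_e = -1, a = 1), gpr = "t1"),
        list(id = "C1", stoich = c(a = -1, b = 1), gpr = "c1a or c1b"),
        list(id = "BIOMASS", stoich = c(b = -1, biomass_met = 1),
             gpr = "c2a and c2b"),
        list(id = "EX_n", stoich = c(n_e = -1), reversible = TRUE),
        list(id = "EX_biomass", stoich = c(biomass_met = -1))
      ),
      biomass_reaction_id = "BIOMASS"))
  }
  big <- 1e4  # roomy caps: no internal reaction should bind before the medium does
  net <- template_network(
    metabolites = c("glc_e", "glc", "pyr", "pyr_e", "lac", "lac_e", "o2_e",
                    "o2", "atp", "adp", "nadh", "palm", "palm_e",
                    "biomass_met"),
    reactions = list(
      list(id = "GLUT", stoich = c(glc_e = -1, glc = 1),
           gpr = "glut1 or glut2"),
      list(id = "GLYC", stoich = c(glc = -1, adp = -2, pyr = 2, atp = 2, nadh = 1),
           gpr = "(pgk1 or pgk2) and gapdh"),
      list(id = "LDH", stoich = c(pyr = -1, nadh = -1, lac = 1),
           reversible = TRUE, gpr = "ldha or ldhb"),
      list(id = "MCT", stoich = c(lac = -1, lac_e = 1),
           reversible = TRUE, gpr = "mct1"),
      list(id = "PYRT", stoich = c(pyr = -1, pyr_e = 1), gpr = "pyrt1"),
      list(id = "O2T", stoich = c(o2_e = -1, o2 = 1), gpr = "o2t1"),
      list(id = "NOX", stoich = c(nadh = -1, o2 = -1, adp = -2, atp = 2),
           gpr = "nox1"),
      list(id = "OX", stoich = c(pyr = -1, o2 = -3, adp = -12, atp = 12),
           gpr = "pdha and pdhb"),
      list(id = "PALMS", stoich = c(pyr = -4, atp = -7, palm = 1, adp = 7),
           gpr = "fasn1 and fasn2"),
      list(id = "PALMT", stoich = c(palm_e = -1, palm = 1), gpr = "cd36"),
      list(id = "ATPM", stoich = c(atp = -1, adp = 1), gpr = "atpm1"),
      list(id = "BIOMASS",
           stoich = c(pyr = -3, atp = -10, palm = -1, adp = 10, biomass_met = 1)),
      list(id = "EX_glc", stoich = c(glc_e = -1), reversible = TRUE),
      list(id = "EX_lac", stoich = c(lac_e = -1), reversible = TRUE),
      list(id = "EX_pyr", stoich = c(pyr_e = -1), reversible = TRUE),
      list(id = "EX_o2", stoich = c(o2_e = -1), reversible = TRUE),
      list(id = "EX_palm", stoich = c(palm_e = -1), reversible = TRUE),
      list(id = "EX_biomass", stoich = c(biomass_met = -1))
    ),
    biomass_reaction_id = "BIOMASS")
  for (id in names(net$reactions)) {
    net$reactions[[id]]$ub <- big
    net$reactions[[id]]$lb <- if (net$reactions[[id]]$reversible) -big else 0
  }
  net
}

#' Default medium for the toy network
#'
#' Glucose and oxygen can be taken up from the blood (up to
#' `n_pop * rate` nmol/h for the whole population); lactate and palmitate
#' can be secreted to the blood and exchanged through the
#' microenvironment. Mirrors the baseline setting of core cancer models:
#' the main exogenous nutrients are bounded, overflow metabolites have
#' both a cooperation and a direct secretion route.
#'
#' @param n_pop population size used to scale uptake bounds.
#' @param rate per-cell uptake rate in nmol/h (default 100).
#' @param extra_uptake named numeric vector of additional uptake rates
#'   (e.g. `c(palm_e = 10)` to supply exogenous palmitate, or
#'   `c(lac_e = 100)` for exogenous lactate).
#' @param secrete species secretable to blood (default lactate and
#'   pyruvate, the overflow metabolites).
#' @return a [medium_spec()].
#' @export
toy_medium <- function(n_pop, rate = 100, extra_uptake = NULL,
                       secrete = c("lac_e", "pyr_e")) {
  uptake <- c(glc_e = rate, o2_e = rate)
  if (!is.null(extra_uptake)) uptake <- c(uptake, extra_uptake)
  medium_spec(uptake = uptake, secrete = secrete, n_pop = n_pop)
}

#' Specify a synthetic single-cell fixture
#'
#' The stated world of the generator: `n_cells` cells split into
#' metabolic subpopulations (default two, equally mixed — a glycolytic,
#' lactate-secreting program and an oxidative, lactate-consuming program),
#' mean TPM `expression_scale` for a program's active genes over a 20-fold
#' lower background, multiplicative lognormal noise, expression-dependent
#' dropout, and a block of `n_noise_genes` housekeeping "panel" genes that
#' belong to no GPR — like the bulk of a real metabolic gene panel, they
#' add variance to transcript space that carries no flux information.
#'
#' @param n_cells number of cells (default 20).
#' @param n_subpops 1, 2 or 3 subpopulations.
#' @param proportions mixing proportions (default equal, must sum to 1).
#' @param dropout_rate asymptotic dropout probability for lowly expressed
#'   genes (default 0.3, a typical plate-based scRNA-seq level). The
#'   realized per-entry probability decays logistically with log
#'   expression (midpoint at the background level
#'   `expression_scale / 20`, shape 2), emulating the strong expression
#'   dependence of real dropouts: strongly expressed program genes
#'   essentially never read zero, background genes often do.
#' @param expression_scale mean TPM of a program's active genes
#'   (default 100).
#' @param noise_sdlog sdlog of the multiplicative lognormal noise
#'   (default 0.25, a moderate biological CV).
#' @param n_noise_genes number of non-GPR housekeeping panel genes added
#'   to the matrix (default 32; they are ignored by the activity scores
#'   but participate in transcript clustering, as in real panels).
#' @param seed integer seed; all randomness in the generator derives from
#'   it.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_cells = 20, n_subpops = 2,
                         proportions = rep(1 / n_subpops, n_subpops),
                         dropout_rate = 0.3, expression_scale = 100,
                         noise_sdlog = 0.25, n_noise_genes = 32, seed = 1) {
  stopifnot(n_cells >= 1, n_subpops %in% 1:3,
            length(proportions) == n_subpops,
            abs(sum(proportions) - 1) < 1e-8,
            dropout_rate >= 0, dropout_rate < 1, expression_scale > 0)
  stopifnot(n_noise_genes >= 0)
  structure(list(n_cells = as.integer(n_cells), n_subpops = n_subpops,
                 proportions = proportions, dropout_rate = dropout_rate,
                 expression_scale = expression_scale,
                 noise_sdlog = noise_sdlog,
                 n_noise_genes = as.integer(n_noise_genes),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Mean-TPM programs for the toy network's genes. s = active, m = moderate,
# l = background. The programs are engineered so that, at the scFBA
# optimum, every cell's biomass is pinned by its own scored capacities:
# lactate intake of oxidative cells saturates their (low) mct1 share, and
# palmitate is sourced locally (moderate fasn in glycolytic cells, no
# import transporter in oxidative ones), leaving no slack-capacity
# cross-feeding route along which optimal per-cell biomass could float.
toy_programs <- function(scale) {
  s <- scale; l <- scale / 20
  genes <- c("glut1", "glut2", "pgk1", "pgk2", "gapdh", "ldha", "ldhb",
             "mct1", "pyrt1", "o2t1", "nox1", "pdha", "pdhb", "fasn1",
             "fasn2", "cd36", "atpm1")
  glycolytic <- c(glut1 = s, glut2 = 0, pgk1 = s, pgk2 = l, gapdh = s,
                  ldha = s, ldhb = l, mct1 = s, pyrt1 = s, o2t1 = l,
                  nox1 = l, pdha = l, pdhb = l, fasn1 = s, fasn2 = s,
                  cd36 = l, atpm1 = l)
  oxidative <- c(glut1 = l, glut2 = 0, pgk1 = l, pgk2 = l, gapdh = l,
                 ldha = l, ldhb = s, mct1 = l, pyrt1 = l, o2t1 = s,
                 nox1 = s, pdha = s, pdhb = s, fasn1 = s, fasn2 = s,
                 cd36 = l, atpm1 = l)
  mixed <- (glycolytic + oxidative) / 2
  list(glycolytic = glycolytic[genes], oxidative = oxidative[genes],
       mixed = mixed[genes])
}

#' Simulate a single-cell expression matrix over a toy network
#'
#' Each subpopulation expresses its metabolic program (see
#' [fixture_spec()]); values are multiplied by lognormal noise and zeroed
#' with probability `dropout_rate`. The bulk profile is the per-gene mean
#' of the pre-dropout matrix — bulk RNA-seq does not suffer single-cell
#' dropout, which is exactly what makes the three-scenario reconciliation
#' informative. The gene `glut2` is silent in every program and therefore
#' lands in `G_off`, providing the engineered "redundant isoform turns
#' essential" case. Deterministic for a given seed.
#'
#' @param net the toy [template_network()] (genes must match the programs;
#'   only the `glycolysis_oxphos_toy` variant is supported).
#' @param spec a [fixture_spec()].
#' @return an [expression_data()] (gene_status unset) with attribute
#'   `labels`: the true subpopulation of each cell.
#' @export
simulate_expression <- function(net, spec) {
  stopifnot(inherits(net, "template_network"), inherits(spec, "fixture_spec"))
  progs <- toy_programs(spec$expression_scale)[seq_len(spec$n_subpops)]
  missing <- setdiff(network_genes(net), names(progs[[1]]))
  if (length(missing)) {
    stop("network genes without a program: ", paste(missing, collapse = ", "))
  }
  genes <- names(progs[[1]])
  out <- NULL
  with_local_seed(spec$seed, {
    labels <- sample(rep(seq_len(spec$n_subpops),
                         times = round_proportions(spec$proportions, spec$n_cells)))
    mu <- vapply(labels, function(p) progs[[p]], numeric(length(genes)))
    if (spec$n_noise_genes > 0) {
      hk_mean <- stats::rlnorm(spec$n_noise_genes,
                               meanlog = log(spec$expression_scale / 4),
                               sdlog = 0.75)
      hk <- matrix(rep(hk_mean, spec$n_cells), ncol = spec$n_cells)
      rownames(hk) <- sprintf("panel%02d", seq_len(spec$n_noise_genes))
      mu <- rbind(mu, hk)
      genes <- c(genes, rownames(hk))
    }
    noise <- matrix(stats::rlnorm(length(mu), meanlog = 0, sdlog = spec$noise_sdlog),
                    nrow = nrow(mu))
    true_mat <- mu * noise
    bulk <- rowMeans(true_mat)
    # expression-dependent dropout (logistic on log expression, as in
    # standard scRNA-seq simulators): genes around the background level
    # drop out at close to dropout_rate, highly expressed program genes
    # (~20x background) essentially never do — plate-based protocols with
    # thousands of genes detected per cell do not zero out strong signals.
    x0 <- spec$expression_scale / 20
    p_drop <- spec$dropout_rate *
      (1 - stats::plogis(2 * log(pmax(true_mat, .Machine$double.xmin) / x0)))
    drop <- matrix(stats::runif(length(mu)) < p_drop, nrow = nrow(mu))
    obs <- true_mat
    obs[drop] <- 0
    dimnames(obs) <- list(genes, paste0("cell", seq_len(spec$n_cells)))
    names(bulk) <- genes
    data <- expression_data(obs, bulk = bulk)
    attr(data, "labels") <- stats::setNames(names(progs)[labels], colnames(obs))
    out <- data
  })
  out
}

round_proportions <- function(p, n) {
  counts <- floor(p * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_order <- order(p * n - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  counts
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the toy SBML model, the expression TSV, the bulk TSV and the true
#' subpopulation labels — everything needed to run the pipeline end to end
#' without downloads.
#'
#' @param dir output directory (created).
#' @param spec a [fixture_spec()].
#' @param variant network variant for [make_toy_network()].
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(dir, spec = fixture_spec(),
                          variant = "glycolysis_oxphos_toy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- make_toy_network(variant)
  data <- simulate_expression(net, spec)
  paths <- c(model = file.path(dir, "model.xml"),
             expression = file.path(dir, "expression.tsv"),
             bulk = file.path(dir, "bulk.tsv"),
             labels = file.path(dir, "labels.csv"))
  write_sbml_network(net, paths["model"])
  write_matrix_tsv(data$mat, paths["expression"], "gene")
  data.table::fwrite(data.frame(gene = names(data$bulk), tpm = data$bulk),
                     paths["bulk"], sep = "\t", col.names = FALSE)
  labs <- attr(data, "labels")
  data.table::fwrite(data.frame(cell = names(labs), label = labs),
                     paths["labels"])
  invisible(paths)
}
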