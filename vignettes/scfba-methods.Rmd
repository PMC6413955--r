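---
title: "Methods: single-cell flux balance analysis on population models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell flux balance analysis on population models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the model it implements, the
assumptions behind it, the tunable parameters, the synthetic world used for
testing, and the numerical and design choices that were genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

### Population construction

The unit of modelling is a template metabolic network
$A = (X_A, R_A, E_A)$: $M$ metabolites, $N$ internal reactions and
$N_{ext}$ exchange reactions, each exchange touching exactly one boundary
metabolite. A population of $N_{cells}$ cells is built by replicating $A$
and coupling the replicates through a shared tumour-microenvironment (TME)
compartment: exchange $E_j$ of cell $c$ becomes a reversible cooperation
reaction $C_j^c: Y_j^c \leftrightarrow Y'_j$ (stoichiometry $-1/+1$), and
each blood-exchangeable TME metabolite $K_j$ receives one unbalanced blood
exchange $B_j: K_j \leftrightarrow \emptyset$ with negative flux meaning
uptake. The biomass pseudo-metabolite is always blood-exchangeable; its
pooled drain is the default objective, so the optimum is the total biomass
of the population and per-cell growth rates are free to differ — the
population is *not* assumed to be at a demographic steady state, only each
cell's metabolism is.

The assembled sparse matrix has exactly
$(N_{cells} M + N_{blood}) \times (N_{cells}(N + N_{ext}) + N_{blood})$
entries of shape. A consequence of adopting this size formula is that TME
pools exist only for blood-exchangeable species. The cooperation columns
of other species are retained (the column count honours the formula) but
closed: a species absent from the blood/TME configuration is not
exchangeable at all. If a TME-only shuttle (cell-to-cell exchange of a
species with no blood route) is wanted, the species is simply listed among
the blood metabolites with its blood exchange closed by the medium — the
TME row then exists and cross-feeding is possible without any blood flux.

### Constraint layers

*Type 1 (medium).* Uptake species get blood bounds
$[-N_{pop}\cdot r, 0]$ with $r$ a per-cell rate in nmol/h (default 100);
secretable species get $[0, \infty)$ and keep their TME route; everything
else is closed. A secretable species therefore always has a disposal path
that does not depend on another cell taking the metabolite up.

*Type 2 (single-cell transcriptomes).* For every reaction with a usable
gene–protein–reaction rule, per-cell scores are
$RAS_j^c = \min$ over subunit genes / $\sum$ over isoform genes
(composite rules recurse, `and` binding tighter than `or`), computed on
the reconciled expression matrix. Normalized shares
$\overline{RAS}_j^c = RAS_j^c / \sum_c RAS_j^c$ distribute the
medium-limited capacity $F_j = \max(|F_f|, |F_b|)$ (flux variability with
no optimality requirement, objective ignored) across cells:
$$U_j^c = \epsilon + (F_j - \epsilon)\,\overline{RAS}_j^c,\qquad
L_j^c = \begin{cases}0 & \text{irreversible}\\ -U_j^c & \text{reversible,}\end{cases}$$
so $\sum_c U_j^c = F_j + (N_{cells}-1)\epsilon$. A single symmetric
capacity serves both directions because transcript abundance carries no
information about the direction an enzyme works in. Because cells are
identical before scores are applied, capacities are computed once on a
representative cell's columns and broadcast — an $N_{cells}$-fold saving
justified by symmetry. The alternative (template-level FVA) differs only
when cross-cell routes inflate a single cell's reachable flux; we prefer
the population-model variant because those routes exist in the final model
too.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `epsilon` | `1e-3` nmol/h | flux floor for zero-share reactions; mitigates scRNA-seq false negatives. The scan set `{0, 1e-6, ..., 1}` reproduces the sensitivity analysis; biomass is non-decreasing in `epsilon` (pure relaxation) and the problem stays feasible at 0. |
| uptake rate | 100 nmol/h per cell | population uptake bound is `n_pop * rate`. |
| `coop_big` | `1e4` nmol/h | default cooperation bounds; deliberately above any total medium uptake so that exchange topology, never this cap, is the binding structure. |
| `min_genes` | 5000 | cell filter (detected = strictly positive), counted over all genes in the matrix; use 0/1 for small gene panels. |
| solver | HiGHS (SciPy) | deterministic; feasibility tolerances around `1e-9`; objective values reproducible across runs. |

### Preprocessing: the three zero scenarios

With a matched bulk profile (bulk zeros tested exactly — TPM zeros are
literal): off everywhere (bulk 0, all cells 0) → gene deleted from the
template by true/false GPR logic, giving the subnetwork $A^*$; bulk-only
(bulk > 0, all cells 0) → single-cell values replaced by the bulk value;
heterogeneous zeros → values kept, the $\epsilon$ floor absorbs the risk.
Deletion simplifies the surviving rules (a pruned isoform stays pruned),
which is what makes deletion composable and lets a gene that is redundant
in the full template become essential in $A^*$ — the pattern the deletion
screen looks for. Genes in a rule but absent from the matrix are treated
as non-limiting (dropped from `or` sums, ignored in `and` minima): an
unmeasured subunit must not zero a reaction out.

## Modes

* `popFBA` — type-1 constraints only, template $A$; all cells identical.
* `bulkFBA` — the isolated template $A^*$ (bulk-driven deletions only)
  under population-level medium; no per-cell modulation is possible
  because relative expression across cells is undefined for one profile.
* `scFBA` — type 1 + type 2 on $A^*$.

## Experiments

*Per-cell biomass spans.* With the total fixed at its optimum, each cell's
biomass export is minimized/maximized (FVA). popFBA spans are $[0, total]$
— any cell can do everything; scFBA spans collapse to points when every
cell's biomass is pinned by its own score-derived caps.

*Deletion screens.* A gene deletion disables, in every cell
simultaneously, the reactions whose rule evaluates false; `grRatio` is the
re-optimized objective over the baseline, in $[0,1]$ by construction.

*Cooperation knockout.* Exchange between cells is severed by forbidding
TME *uptake* (`lb = 0` on the species' cooperation columns) rather than
closing the columns: each cell can still dispose of overflow through the
TME into the blood, so the ratio compares like with like (loss of
cross-feeding, not loss of waste disposal). For identical cells the
symmetric optimum never uptakes a secretable species from the TME, so the
ratio is exactly 1; heterogeneous populations can drop below 1. The ratio
never exceeds 1 because the knockout is a pure restriction.

*ATP objective.* "Total ATP produced" is implemented as maximization of
the summed per-cell flux through the template's ATP-demand (hydrolysis)
reaction — the conventional demand-reaction reading, since ATP production
is otherwise not a single flux.

*Flux reporting and degeneracy.* FBA optima are vertex-degenerate; fluxes
in degenerate coordinates are arbitrary solver choices. The pipeline
therefore reports the parsimonious optimum (minimal total absolute flux at
the optimal objective — the standard pFBA device), and
`cooperation_flux_ranges()` exposes FVA intervals for cooperation fluxes
instead of pretending vertex uniqueness. Objective values are unaffected.

## Analytics

Features (fluxes or transcripts) are min–max normalized per feature to
$[0,1]$ (constant features → all zeros) so high-magnitude fluxes do not
dominate Euclidean distances. k-means uses 100 random-centroid restarts,
keeping the run with maximal between-cluster sum of squares — with the
total fixed this equals minimal within-cluster error, which keeps the
elbow bookkeeping consistent. Cluster-count diagnostics: SSE over
$k = 1..20$ and average silhouette (Euclidean on the normalized features)
for $k \ge 2$. Hierarchical clustering uses Euclidean distances with
average linkage (the linkage was not constrained; average is the common
clustergram default). The two-group contrast is a Welch-form two-sample
z statistic with a per-feature two-sided normal threshold (2.576 at 99%);
no multiple-testing correction, matching the per-feature confidence
convention. All stochastic steps take explicit seeds.

## The synthetic world

`make_toy_network()` builds a 14-metabolite cartoon of core cancer energy
metabolism: glucose transport (`glut1 or glut2` — an isoform pair with
`glut2` silent in all simulated cells, hence pruned via the bulk),
lumped glycolysis (`(pgk1 or pgk2) and gapdh`; 2 ATP + 1 NADH per
glucose), reversible lactate dehydrogenase and lactate transport,
an export-only pyruvate overflow valve, oxygen transport, NADH
oxidation, pyruvate respiration (`pdha and pdhb`, 12 ATP), palmitate
synthesis (`fasn1 and fasn2`, 4 pyruvate + 7 ATP) with an *uptake-only*
transporter, an ATP-demand reaction, and a biomass reaction
(3 pyruvate + 10 ATP + 1 palmitate). The ATP/ADP moiety is conserved.
Small integers keep the brute-force LP oracle cheap.

Two structural choices deserve explanation because they were forced by
the mathematics of optimal-solution uniqueness:

* the pyruvate valve exists because an ATP-limited fermenting cell has an
  obligatory pyruvate surplus (1 NADH per 2 pyruvate); without an export
  route its only sink is respiration and a single dropout on the
  respiration rule kills the whole cell;
* palmitate is not exportable because an exportable pool whose producers
  and consumers have slack transport capacity creates zero-cost
  reallocations of biomass between cells — per-cell optima would not be
  unique, and the span-collapse pattern could not be exhibited by any
  parameter setting.

`simulate_expression()` draws two programs (glycolytic, lactate-secreting
vs oxidative, lactate-consuming; a third intermediate program is the
elementwise mean) with a 20-fold active/background contrast, multiplicative
lognormal noise (`sdlog = 0.25`), and expression-dependent dropout:
the per-entry zero probability is `dropout_rate` times a logistic decay in
log expression (midpoint at the background level, shape 2), so background
genes read zero often while strong program genes essentially never do —
the behaviour of plate-based protocols after a detected-genes filter, and
a necessary property: with uniform dropout on a 17-gene panel, whole
pathway chains die in a way the emulated datasets do not show. The matrix
additionally carries 32 "panel" housekeeping genes that belong to no GPR:
like the bulk of a real metabolic gene panel they add transcript variance
that carries no flux information (the expression module logs and ignores
them downstream). The bulk profile is the pre-dropout per-gene mean —
bulk RNA-seq does not suffer single-cell dropout, which is exactly what
makes the reconciliation scenarios informative.

What a green test establishes: the arithmetic of scores, bounds and the
population matrix; the qualitative patterns (span collapse, cooperation
benefit and its knockout, silent-isoform essentiality switches,
boundary-condition effects, flux-over-transcript clusterability) on a
world constructed to exhibit them. What it does not establish: that those
patterns appear in any particular real dataset, nor the realistic
magnitude of cooperation effects; the generator makes no attempt at
negative-binomial count realism, library-size effects, or genome-scale
network structure.

## Numerical choices

* LPs are solved by HiGHS through SciPy (`inst/python/lp_batch.py`), one
  batched process call per analysis stage; HiGHS is deterministic, so
  identical configurations give identical outputs.
* Capacities below `1e-9` are treated as 0. If `epsilon` exceeds a
  capacity the bound is clamped to `epsilon` with a warning (bound
  inversion would otherwise make the LP ill-posed).
* Fixing the objective for span/cooperation FVA uses a relative slack of
  `1e-9` to stay clear of solver-tolerance infeasibility.
* Reversibility on SBML input is `lb < 0` when bounds are present, the
  `reversible` attribute otherwise; `fbc` gene associations win over
  notes-field strings when both exist.
* Ties in k-means restarts resolve to the first-seen best run under the
  seeded restart order; `k = N_cells` short-circuits to singleton
  clusters (SSE 0) without invoking `kmeans()`, which rejects duplicate
  centers.

## Known limitations

* No thermodynamic loop-law correction: internal loops are only bounded
  by template default bounds (the cooperation structure removes the
  gross loops through the environment).
* The LP backend requires a Python with SciPy on the PATH; there is no
  pure-R fallback because no LP solver is available in the targeted
  dependency set.
* Genome-scale templates work in principle but the per-reaction FVA and
  the JSON bridge are tuned for core-model scale.
* `bulkFBA` deliberately supports on/off information only; it cannot
  modulate capacities because single-profile relative expression is
  undefined.
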