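---
title: "Multi-cell population metabolic modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cell population metabolic modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicellfba)
```

## The modeling problem

A tissue-level culture such as a brain organoid is a community of
metabolically distinct cell populations sharing one medium. Bulk metabolic
models cannot separate, say, a glycolytic astrocyte population from
oxidative neurons, yet exactly that separation is needed to reason about
cross-feeding such as the astrocyte-neuron lactate shuttle. `multicellfba`
builds a *multi-cell population model*: one namespaced copy of a generic
genome-scale reconstruction per cell type, every copy wired to a shared
medium compartment, with each copy's reaction content determined by that
cell type's own single-cell expression.

The pipeline has five stages.

1. **Discretization.** Per cell type and condition, UMI counts are
   pseudobulked (per-cell counts-per-10k, `log2(x + 1)`, averaged over the
   stratum's cells) and split into core / unknown / inactive genes by two
   thresholds on the distribution of nonzero values.
2. **Core mapping.** Core genes are mapped to *core reactions* by
   evaluating each reaction's gene-protein-reaction (GPR) boolean rule;
   reactions without a rule never enter the core by expression.
3. **Model multiplication.** The flux-consistent part of the generic
   network is duplicated per retained cell type. Each generic exchange
   `x[e] <-> (out)` becomes one transport `x[e]_type <-> x[u]` per type
   plus a single shared environment exchange `x[u] <-> (out)`, so all
   inter-cell-type traffic passes through the medium compartment `u`.
4. **Completion.** A FASTCORE-style extraction returns a compact
   flux-consistent subnetwork containing the union of namespaced core
   reactions, every cell type's biomass-maintenance reaction, and the
   environment exchanges of the actual medium components.
5. **FBA.** Medium concentrations map directly to maximal uptake bounds;
   a two-stage weighted-biomass FBA distributes the medium across cell
   types; a zero-norm (minimal-cardinality) step selects a parsimonious
   flux distribution from which all readouts (FluxSum, exchange tables)
   derive.

## Flux analysis details

**Steady state and units.** All programs optimize a flux vector $v$ with
$S v = 0$ and $l \le v \le u$; bounds default to $\pm 1000$ in arbitrary
units (a.u.), the common reconstruction convention. Exchange fluxes are
positive out of the system, so uptake is negative flux and the uptake
bound acts on the lower bound.

**Medium rule.** Listed components get their concentration as uptake
bound; unlisted medium species get uptake 0 with secretion unrestricted
(closed medium). The oxygen bound is never taken from the table: it is
`o2_glucose_ratio` times the glucose bound (default 2, the culture-medium
convention; 5 approximates the physiological brain oxygen:glucose ratio).
Thymidine and linoleate uptakes are pinned to 1 by default so biomass
precursors are never the artifactual bottleneck.

**Two-stage objective.** Stage 1 maximizes each type's
biomass-maintenance flux alone, giving that type's solo maximum $b^{max}_t$.
Stage 2 solves
$\max \sum_t w_t\, b_t$ subject to $b_t \ge 0.1\, b^{max}_t$, with $w_t$
the cluster cell count. The floors guarantee every population a minimal
maintenance share; computing them from solo maxima (not from the weighted
optimum) keeps them independent of the other types' demands.

**Minimal cardinality.** The stage-2 optimum usually lies on a large
optimal face; we report a vertex minimizing the number of active
reactions. Models up to `exact_threshold = 25` reactions use an exact
mixed-integer program (binary activity indicators, LP-based branch and
bound, down-branch first). Larger models use iteratively reweighted
1-norm minimization — five fixed reweighting rounds with weights
$1/(|v|+10^{-3})$ — followed by a polish step that pins the zero set and
re-maximizes the objective on the chosen support. The zero norm has no
unique minimizer in general; what the package guarantees is
run-to-run reproducibility (fixed pivoting rules, fixed schedules, no
randomness), and on every small model we tested the heuristic support is
within one reaction of the exact MILP support.

**Readouts.** The FluxSum of metabolite $i$ is
$\sum_j \max(S_{ij} v_j, 0)$, the producing turnover. Pathway scores sum
FluxSum over key metabolites; the shipped keys for the toy network are
glycolysis = {glc_D[c], g6p[c], pyr[c]}, TCA = {cit[m], akg[m], succ[m]},
OXPHOS = {nadh[m], h[m], atp[c]}, FAO = {accoa[c], accoa[m]}. Glycolysis
deliberately uses *upstream* intermediates: a cell type that imports and
oxidizes lactate would otherwise register lactate/pyruvate turnover as
glycolytic activity, which inverts comparisons between fermenting and
lactate-consuming populations. Medium reports use uptake-positive sign;
inter-cellular reports use the production-negative / uptake-positive
convention with a medium-balance row, and rows sum to zero by mass
balance of the medium species.

## Consistency and extraction

A reaction is flux-consistent when some steady-state flux vector gives it
at least `epsilon` absolute flux. `epsilon = 1e-4` a.u. separates genuine
activity from solver noise (feasibility tolerances are `1e-7`-`1e-9`);
reversible reactions are handled by direction flipping inside the LPs, so
reaction identities are preserved for Jaccard comparisons. The extraction
follows the FASTCORE scheme (LP7 to push core reactions above threshold,
LP10 to minimize penalized 1-norm through non-core reactions), iterating
with direction flips, with candidate sets processed in lexicographic
reaction-id order for bit-reproducible output. Because LP7 greedily fixes
flux orientations, the raw extraction can occasionally carry a redundant
branch; on networks up to 30 reactions a greedy prune removes any
non-core addition whose deletion leaves a consistent model still covering
the core (one consistency test per candidate; a single pass suffices
because consistency is monotone under taking subsets). Larger models skip
the prune and keep the plain extraction's documented heuristic slack.

Consistency is enforced twice: once on the generic reconstruction before
multiplication, and again on the assembled multi-cell network before
extraction — duplication plus medium rewiring can block reactions that
were consistent in isolation. After extraction, the environment exchange
of any medium species still transported by some cell type is re-added:
these exchanges are boundary plumbing, and dropping them would silently
forbid secretion of, e.g., surplus lactate into the medium.

## The LP/MILP kernel

No external linear-programming solver is assumed: the package ships a
dense bounded-variable two-phase revised simplex (entering variable by
largest reduced-cost violation, ties to the smallest index, Bland's rule
after a fixed iteration count to exclude cycling, periodic
refactorization of the basis inverse) and a small LP-based branch and
bound for the binary cardinality indicators. The kernel is validated in
the test suite against an independent simplex implementation
(`boot::simplex`) on random programs and against hand-solved and
enumerated optima. Problems in this package are small (tens to a few
hundred variables), where a dense pure-R kernel solves each LP in
milliseconds.

## What the synthetic data emulate — and what they do not

`make_toy_network()` is a ~33-reaction central-carbon network (glycolysis,
lactate exchange, TCA, OXPHOS with an explicit proton-motive proxy, FAO,
acetate and 3-hydroxybutyrate branches, thymidine-dependent
biomass-maintenance) whose coefficients are fixed constants chosen for
clean hand-verifiable optima, not literature P/O ratios: one glucose
yields 2 ATP by substrate-level phosphorylation and 12 mitochondrial NADH
when fully oxidized; each NADH yields exactly 2.5 ATP against 0.5 O2. Any
NADH-producing route therefore buys 5 ATP per O2, and with glucose bound
10 and oxygen bound 20 the community optimum is $2\cdot10 + 5\cdot20 =
120$ maintenance units — the value the FBA contract tests assert to
`1e-6` relative.

`simulate_counts()` draws negative-binomial UMI counts per gene and cell
(program mean on the `log2(1+count)` scale, lognormal per-cell depth
factors with unit mean, independent dropout) — the first-order
statistical structure of droplet scRNA-seq. The shuttle scenario uses two
60-gene programs, 300 cells each, dispersion 2, dropout 0.3, library
~1500 UMI: small enough that a full end-to-end run takes about a second,
large enough that pseudobulk means are stable and the discretization
recovers each program's high tier in essentially every seed.

The generator deliberately does **not** emulate: ambient RNA and doublets,
gene-gene correlation structure, batch effects, cell-type abundance
imbalance, the many-cluster census of a real organoid, or genome-scale
reconstruction size (human reconstructions such as Recon3D carry on the
order of 10k reactions). Passing tests therefore demonstrate that the
algorithms are correct and that the designed cross-feeding structure is
recoverable from noisy counts — not that any real organoid's numbers are
reproduced; analyses at that scale take a real count matrix and a full
reconstruction through the same file interfaces.

## Discretization: the open design point

The upstream workflow this stage follows describes discretization only as
"default parameters", so the scheme here is explicit and recorded in run
metadata. On the nonzero pseudobulk values we estimate a kernel density;
modes above 10% of the maximum density count as peaks. With two or more
peaks, the upper threshold is placed below the rightmost
(high-expression) peak by twice its left half-width at half-maximum
(about 2.4 sd for a Gaussian mode — far enough down that the expressed
component is recovered near-completely, which a threshold *at* the peak
would not achieve), and the lower threshold one further width below;
between the thresholds genes stay "unknown" and take no part in core
mapping. Unimodal distributions fall back to the 66th/33rd percentiles;
degenerate (constant) distributions do the same with a warning. Both
thresholds can be forced through `discretization` parameters, and core
sets are monotone in the upper threshold by construction.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `epsilon` | `1e-4` | a.u. | flux-activation threshold for consistency/extraction |
| `o2_glucose_ratio` | 2 | — | oxygen uptake bound as multiple of glucose bound |
| `special_bounds` | thymd = 1, lnlc = 1 | a.u. | pinned uptakes enabling biomass |
| `floor_fraction` | 0.1 | — | per-type minimal maintenance share of solo max |
| `min_cells` | 50 | cells | cluster-size retention threshold |
| `require_shared` | `TRUE` | — | drop types absent from any condition |
| `exact_threshold` | 25 | reactions | exact-MILP vs reweighted-1-norm switch |
| `objective_tol` | `1e-6` | relative | slack when fixing the stage-2 optimum |

The objective is fixed with relative slack `1e-6` rather than exactly, so
rounding never cuts off the optimal face; the cardinality step's polish
re-maximization returns the attained optimum to the same precision.

## Known limitations

* Biomass maintenance is a single ATP-consuming pseudo-reaction shared by
  all cell types; cell-type-specific biomass compositions are not
  modeled.
* Zero-norm solutions are reproducible but not unique in principle;
  alternative optima (flux variability, sampling) are out of scope.
* The discretization operates on pseudobulk per stratum; per-cell
  heterogeneity within a cluster is collapsed by design.
* Thermodynamic constraints and formula/charge balancing are not checked;
  the containers treat all ids as opaque strings.
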