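---
title: "Methods: metabolic features, ternary labels, and classifier validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic features, ternary labels, and classifier validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metoncokit` predicts, per metabolic gene and cancer context, a ternary
fitness call — increased, neutral, or decreased — for three targets
(differential expression, copy-number gain/loss, survival impact), from
features derived entirely from a constraint-based metabolic model and
curated biochemistry. This vignette documents the model and its
assumptions, the parameters that matter, the numerical choices, and what
the synthetic test bed does and does not demonstrate.

## The metabolite graph and epicenter scores

The topological features assume that proximity to nutrients and to biomass
precursors is informative about a gene's metabolic role. The model's
reactions are converted into an unweighted directed graph over metabolites:
each irreversible reaction contributes one edge per (reactant, product)
pair; reversible reactions contribute both directions; parallel edges are
collapsed, which cannot change hop counts. No metabolite is excluded by
default — hub ("currency") metabolites such as water or ATP shorten many
paths, and an exclusion list is available (`exclude` in
`metabolite_graph()`) for users who consider those shortcuts artefactual,
but the default applies no filtering.

A gene's position is anchored at the **product** metabolites of the
reactions it catalyses, in both directions: media distances run from the
component *to* the products, biomass distances from the products *to* the
component. Anchoring the biomass direction at products rather than
reactants was a genuinely open choice; products were chosen for symmetry
with the media direction, and the anchor is the `direction` argument of
`gene_component_distance()` should the other convention be wanted. For
genes catalysing several reactions the minimum over all their products is
taken. Boolean structure of the gene association is deliberately ignored
for topology — any appearance in a rule counts as catalysis.

Epicenter scores are plain sums of these distances over the declared media
and biomass component sets. Components unreachable in the graph are
assigned a finite sentinel of `n_metabolites + 1` — one more than any
realisable hop count — and included in the sums, keeping scores finite and
ordinal while penalising disconnection; the sentinel is the `unreachable`
argument throughout. Setting it to `Inf` instead would make a single
disconnected component absorb the whole score, which is why a finite
default was preferred.

## Flux analysis

Fluxes are computed by flux balance analysis: maximise the biomass
pseudo-reaction's flux $v_{bio}$ subject to steady state $Sv = 0$ and
bounds $lb \le v \le ub$ (mmol/gDW/h). Because the optimal flux space is
usually degenerate, a second stage fixes biomass at its optimum (minus a
$10^{-9}$ slack against numerical infeasibility) and minimises
$\sum_i |v_i|$, splitting each flux into non-negative forward and backward
parts. The reported solution is the stage-2 optimum: a single,
reproducible, parsimonious flux distribution. No thermodynamic loop-law
constraints are applied. The linear programs are solved by a dense
two-phase primal simplex with Bland's anti-cycling rule implemented in the
package; tolerances are $10^{-9}$ solver-side and $10^{-6}$ for the
steady-state assertions in the tests, and fluxes below $10^{-9}$ are
reported as exact zeros.

Single-gene deletions clamp to zero the bounds of every reaction whose
gene-association tree evaluates inactive (AND = complex, all subunits
required; OR = isozymes, any suffices; empty = spontaneous), then re-run
the full two-stage procedure. Re-minimising total flux after each knockout,
rather than only for the wild type, keeps the per-gene features
deterministic and comparable. A deletion with no feasible steady state is
reported as infeasible with an all-zero flux map, so its subsystem deltas
equal $-v_{wt}$ — a lethal deletion carries no flux.

The dynamic features are, per subsystem, the mean of $v_{ko} - v_{wt}$ over
member reactions. The differences are **signed** by default so the
direction of rewiring is preserved; `absolute = TRUE` switches to
magnitudes. Subsystems with no member reactions get zero.

## Biochemical features and ternary labels

Turnover numbers span orders of magnitude, so the feature is
$\mathrm{median}(\log_2 k_{cat})$ per gene over its substrate-specific
records (even counts use the mean of the central pair). Genes without
records receive the median of the per-gene medians — per-gene rather than
per-record, so a heavily measured multi-substrate enzyme cannot dominate
the imputation value. Expression is used as provided, with an optional
log2 flag; the package does not re-normalise.

The label rules are implemented exactly as stated thresholds, all
boundaries inclusive where the wording says "or above"/"or less":

* survival: UPREG iff HR $\ge$ 1.33 and $p \le 0.05$; DOWNREG iff HR
  $\le$ 0.75 and $p \le 0.05$; otherwise NEUTRAL. Multiple cohorts
  reconcile by strict plurality, any tie for the top count giving NEUTRAL.
  The alternative published threshold pairs (0.5/2.0, 0.90/1.10) are plain
  arguments.
* copy number: per-sample GAIN iff (ploidy $\le$ 2.7 and CN $\ge$ 5) or
  (ploidy > 2.7 and CN $\ge$ 9); LOSS iff (ploidy $\le$ 2.7 and CN = 0) or
  (ploidy > 2.7 and CN < ploidy − 2.7). The high-ploidy LOSS cutoff is
  printed ambiguously in its source as "(average genome ploidy, 2.7)"; the
  only reading that yields a usable threshold is ploidy minus 2.7, which is
  what the package implements, with the offset configurable
  (`loss_offset`). GAIN is checked first, which only matters beyond ploidy
  11.7 where the clauses could overlap. Gene-level calls use the gain/loss
  ratio: NEUTRAL when fewer than 5 measurements exist (all records count,
  including NONE calls) or when the ratio lies in [0.5, 2.0] inclusive;
  GAIN above, LOSS below; gains with zero losses give ratio $+\infty$.
* differential expression: the per-gene median log2 fold change against
  $\pm 2$, both inclusive.

## The feature matrix and the classifier

Rows are (gene, cell line) pairs: static features (topology, kcat, pathway)
repeat across a gene's cell lines, expression varies, and the knockout-flux
block may come either from FBA on the model or from a supplied per-gene
table. Genes missing from any source are dropped with a message rather than
imputed. Categorical features get lexicographic integer codes with a stored
reversible map (an unseen category at prediction time is an error naming
the column); numeric features are robust-scaled, $x' = (x - \mathrm{median})
/ \mathrm{IQR}$ with linear-interpolation quartiles and a divisor of 1 when
the IQR is zero. Class imbalance is handled by random oversampling to the
majority count, originals always retained.

The classifier is a random forest: 500 trees, $\sqrt{p}$ features per
split, unlimited depth, a fixed seed for exact reproducibility, and an
optional cross-validated grid search (`tune_forest()`) that reports the
grid best-first. Importance is the Gini mean decrease in impurity,
normalised to sum to one.

**Where resampling and scaling happen is the load-bearing design choice.**
All evaluation schemes fit the scaler and the oversampler on the training
side of each split only, and — because a gene's static features repeat
across its cell-line rows — group every split by gene. With row-level
splits the forest can identify the gene from its repeated features and
recall its training-fold label, so even signal-free data scores near
perfectly; grouping restores the intended reading of accuracy as
generalisation to unseen genes. A `paper_mode` flag reproduces the
alternative workflow (scale, then oversample the pooled data, then split at
row level) for side-by-side comparison; it is not the default precisely
because duplicated and replicated rows then straddle the split and inflate
accuracy.

Validation schemes: stratified 10-fold cross-validation (pooled out-of-fold
confusion matrix), a stratified 70/30 holdout, leave-one-cell-line-out, and
leave-one-feature-set-out over the three feature categories. Metrics are
one-vs-rest per class (precision, recall, specificity, F1) macro-averaged;
accuracy; the multiclass covariance form of MCC (0 by convention when a
marginal is degenerate); and AUROC as one-vs-rest on class probabilities,
macro-averaged — the multiclass AUROC scheme is the package's choice, as is
the $-1/0/+1$ ordinal encoding used for the Pearson correlation-direction
calls at $|R| > 0.6$. Permutation significance refits the full pipeline on
shuffled labels and reports both the normal-fit upper-tail p (via the
Z-score) and the empirical $(1 + \#\{null \ge obs\}) / (n_{iter} + 1)$; the
empirical p is the one to trust when the null is skewed. Per-gene summaries
aggregate cell-line rows by plurality vote, a label tie falling back to the
class of the median ordinal encoding (an UP/DOWN conflict is NEUTRAL) and
numeric columns to their medians.

## The synthetic test bed

`fixture_spec()` + `generate_toy_model()` + `generate_omics_tables()`
emulate the pipeline's inputs with planted, recoverable structure. The toy
model is built to be feasible by construction: an exchange source per media
component, short single-gene chains routing media to every biomass
component, random extra reactions (20% reversible) for topological variety,
and a biomass reaction consuming all precursors. The omics tables are
generated by inverting the label rules — survival records drawn in the
UPREG regime (HR around 1.8, clamped $\ge$ 1.35, significant p) or DOWNREG
regime (around 0.55, clamped $\le$ 0.74), CNV sample sets whose gain/loss
counts land in the intended ratio band, fold changes whose median lands on
the intended side of $\pm 2$ — so with zero label noise the labelling stage
recovers the planted classes exactly, and with noise rate $q$ the error is
$q$ in expectation.

Class signal is planted by shifting designated feature columns by
`effect_size` times the class's ordinal sign on top of unit Gaussian noise.
The five default signal columns live in the knockout-flux table (one
feature category, so leave-one-feature-set-out has a well-defined expected
winner); expression and kcat can carry signal too. The defaults — 60 genes
observed in 5 cell lines (300 rows), effect size 2, label noise 0.05,
balanced classes — mirror a five-cell-line cancer panel at desk scale.

What passing tests show, and what they do not: the suite demonstrates that
every rule and algorithm does what its definition says (against independent
oracles: hand-rolled breadth-first search for distances, an external
HiGHS solver for the linear programs, formula-level recomputation for the
metrics), that the pipeline recovers planted signal and ranks the planted
features first, and that signal-free data scores at chance. It does not
show that real tumor omics carry such signal, that real metabolic networks
resemble the toy topology (they are far denser, with hubs, compartments and
isozymes), or that the specific published accuracy figures on patient data
are reproducible — those depend on external databases outside this
package's scope.

Problem sizes used by the checks (chosen to characterise behaviour, with
every seed explicit): 200 random models of up to 50 metabolites for the
topology oracle; 50 models of up to 15 reactions, wild type plus one
deletion each, for the flux oracle; a 300-gene, single-cell-line,
signal-free fixture for null calibration — one row per gene makes the 300
rows exchangeable so the binomial $\pm 3\sigma$ band around 1/3 is the
correct reference (with 60 genes × 5 lines the effective unit count is 60
and that band would not apply); ten seeded 300-row fixtures for signal
recovery, summarised by mean cross-validated accuracy and the count of
seeds whose top-10 Gini ranks contain all five planted features; and a
200-shuffle holdout permutation with a 100-tree forest for the null
significance check.

## Known limitations

* The simplex is dense and intended for toy-to-moderate models (hundreds of
  reactions), not genome-scale reconstructions; swapping in an external LP
  solver behind `wild_type_flux()` would be the natural extension.
* Exchange reactions are modelled as one-sided sources/sinks; uptake
  kinetics and medium composition beyond the declared component list are
  out of scope.
* The COSMIC-style LOSS clause reading (ploidy − 2.7) is an interpretation
  of an ambiguous printed rule, flagged and configurable.
* Correlation directions use Pearson R against an ordinal encoding; genes
  ranked highly by the forest can still show $|R| < 0.6$ (non-monotone or
  interaction effects), and the `~` call is not evidence of no association.
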