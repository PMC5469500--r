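---
title: "Quantifying alternative optima in context-specific metabolic predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternative optima in context-specific metabolic predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambiflux)
```

## The problem

Constraint-based analysis of a genome-scale metabolic model (GEM) restricts
flux predictions to the flux cone, the set of steady-state flux vectors

$$F = \{v : S v = 0,\; v_{\min} \le v \le v_{\max}\},$$

where $S$ is the stoichiometric matrix. Integrating context-specific gene
expression data — through gene-protein-reaction (GPR) rules — narrows the
predictions further, either to a context-specific flux distribution
(*flux-centered* methods) or a context-specific subnetwork
(*network-centered* methods). Both kinds of data integration are solved as
optimization problems, and while a convex (or mixed-integer) program has a
unique optimal *value*, it typically does not have a unique optimal
*solution*. Distinct flux distributions can be equally close to the data;
distinct subnetworks can be equally parsimonious. Downstream biology read
off a single arbitrary optimum is therefore ambiguous. This package
implements both kinds of data integration together with the machinery to
*sample* and *quantify* their alternative optima.

## The flux-centered program and its alternative optima

`regrex_lad()` fits a flux distribution to a non-negative per-reaction data
vector $d$ (obtained from expression data via `map_expression_to_reactions()`)
by least absolute deviations with an $\ell_1$ penalty:

$$\min_{v \in F} \; w^{\top}\left(\epsilon^{+}+\epsilon^{-}\right) +
\lambda \lVert v \rVert_1,$$

where $\epsilon^{+}-\epsilon^{-} = d_i - |v_i|$ on the *data-bounded* set
$R_D$ (reactions whose GPR maps to measured genes), and reactions without
mapped data (*data-orphan*) do not enter the error. Reversible reactions are
split into non-negative forward and backward components; a binary selector
per reversible reaction makes the two directions mutually exclusive, so the
program is a MILP. The split also linearizes $|v_i|$ in the error terms.

Two sources of degeneracy remain at the optimum: data-orphan fluxes may vary
freely within the cone as long as the total $\ell_1$ norm is unchanged, and
when $d$ lies outside the projection of $F$, several flux vectors are
equidistant from it. `regrex_aos()` samples this optimum face. Each draw

1. picks a random vector $v_{rand}$ coordinate-wise uniform within the
   bounds-only FVA ranges (`fva()`),
2. flips the sign of its negative reversible entries together with the
   matching columns of $S$, so every entry falls in a forward range,
3. solves a MILP minimizing the $\ell_1$ distance to $v_{rand}$ subject to
   the fitting constraints *plus* two norm-preserving constraints — the
   total weighted error and the total $\ell_1$ norm must equal those of the
   fitted optimum — and
4. flips the flipped entries back.

Distance to the random point is measured per reversible reaction either
against the forward or the backward component; the same binary direction
selector makes the two distance terms mutually exclusive, so the sampler
chooses whichever direction is closer to the draw.

Preserving *both* norms is a deliberately strict reading of membership in
the optimum set: it implies that a reaction pinned by mass balance to the
data-bounded part (for example every reaction of a linear chain) shows no
variation at all beyond solver tolerance, and that a lone data-orphan
reaction can change only its direction, not its magnitude — variation in
magnitude requires at least two orphan routes that can trade flux at
constant total. The norm equalities are enforced as two-sided inequalities
with slack $\texttt{feasibility\_tol}\cdot\max(1,|\mathrm{rhs}|)$, because
exact equalities on solver floating point are brittle; every reported
sample therefore satisfies both norms to that slack plus one solver
tolerance per summed variable.

The penalty weight $\lambda$ is chosen by `select_lambda()`: the program is
solved over a grid and the $\lambda$ maximizing the Pearson correlation
between $d$ and $|v|$ on $R_D$ wins; a grid point whose fitted fluxes are
constant (for max-scaled data this happens at $\lambda = 1$, where every
flux is shrunk to zero) has no defined correlation and is scored $-\infty$.
Ties resolve to the smaller $\lambda$, i.e. the milder regularization.

## Quantifying flux ambiguity

`flux_entropy()` summarises a sample by the per-reaction Shannon entropy

$$H_i = -\sum_{k=1}^{n} f_{i,k}\, \log f_{i,k},$$

with $f_{i,k}$ the relative frequency of bin $k$ among $n = 20$ equal-width
bins spanning the reaction's sampled range. The natural logarithm is used,
so $H_i \in [0, \ln 20 \approx 2.996]$. Binning on the *sampled* range is
the default; binning on the FVA range is available (`range = "fva"`) for
analyses that want entropies comparable across samplers. A constant column
has $H = 0$ by convention. Totals are reported over all reactions and over
the data-bounded/data-orphan partition; comparing the total entropy of a
`regrex_aos()` sample against an unconditioned `cone_sample()` (random
points projected onto $F$ by a Euclidean-distance QP) isolates what the
data integration, rather than the stoichiometry, pins down. Note that a
reaction pinned up to solver tolerance still shows a tiny sampled range and
hence a small non-zero entropy; we do not collapse such ranges, so entropy
ranks remain comparable with values computed by other implementations.

`fixed_direction()` reports the share of reversible reactions carrying flux
anywhere in the sample (max $|v| \ge$ `active_tol`, default $10^{-6}$)
whose above-threshold values all share one sign — reactions whose
*direction*, if not their magnitude, is decided by the data.

## The network-centered program and its alternative optima

`corex()` extracts a parsimonious context-specific subnetwork: given a core
set $C$ of reactions that must be active, it minimizes the number
$Z = \lVert x \rVert_1$ of non-core reactions (the set $P$) added, subject
to one common steady-state flux in which every core and every added
reaction carries flux of magnitude at least $\varepsilon$ and every
excluded reaction carries none. Activity of a reversible reaction is the
sum of its split components, with a second binary vector forcing one
direction to zero. An optional floor $\lVert x\rVert_1 \ge Z_{lb}$ relaxes
parsimony when larger, more functional networks are wanted.

`altnet_step()` asks the complementary question: among networks of the
*same* cardinality that keep the core consistent, which differs most from a
given one? Binary mismatch indicators $\delta^{+},\delta^{-}$ (at most one
set per reaction) link the new inclusion vector to the anchor, and their
count is maximized. A zero maximum certifies that the optimum at that
cardinality is unique. `altnet_enumerate()` iterates the step, feeding each
newly found network back as the anchor; when the step stagnates (duplicate
or zero mismatches) it flips the state of 1% of the non-core entries
(at least one, uniformly without replacement, seeded) of the last vector
and continues, using the perturbed vector only as an anchor — never storing
it as a network, since a perturbed vector need not be feasible. The
procedure is explicitly not an exhaustive enumerator, but on every fixture
family with brute-force ground truth in the test suite it recovers the
complete optimal set.

External reconstructions plug into the same machinery:
`audit_external_network()` converts any inclusion vector (e.g. a FastCORE
or CORDA output) into an anchor, after verifying by LP that all its
reactions can be simultaneously active at $\varepsilon$. For
classifications in the four-group style of CORDA — a high-confidence core
plus medium (MC), negative (NC) and other (OT) non-core groups —
`core_set(mode = "corda")` makes the cardinality constraint hold per group,
so alternative networks conserve the number of added MC, NC and OT
reactions separately.

Ensembles are summarized by pairwise Hamming distances between inclusion
vectors (`hamming_summary()`: maximum, mean, coefficient of variation,
normalized variants; `compare_ensembles()` runs the one-sided rank-sum test
between two distance distributions), by the three-way classification of
non-core reactions into *active* (in every network), *inactive* (in none)
and *variable* (`classify_noncore()`), and by pathway ambiguity scores
(`pathway_scores()`). For the scores, both normalizations are always
emitted: by the total non-core size $|P|$ (so scores of one class sum to
that class's share) and by the pathway's own non-core size (so a pathway
entirely in the active set scores 1); which of the two a study should quote
depends on whether cross-pathway or within-pathway enrichment is meant, and
the table carries both so the choice stays explicit.

`run_tasks()` closes every exchange reaction, opens a task's uptakes at
their stated bounds and maximizes the product exchange flux; a task passes
when the optimum reaches its required minimum. Exchanges are detected as
columns of $S$ with a single non-zero entry, and bounds in a task are plain
flux bounds in the model's own sign convention. `filter_ensemble()` keeps
the networks passing *all* tasks; since this adds a constraint, the
variable non-core set can only shrink — trading parsimony against
functionality is the practical lever for reducing reconstruction
ambiguity.

## Numerical choices

* **Solvers.** All LPs and MILPs are solved with HiGHS (via SciPy's
  `linprog`/`milp`, bridged by reticulate); the flux-cone projection QP is
  strictly convex and solved with `quadprog`. Single-threaded solving and
  model-column variable ordering keep MILP tie-breaking reproducible.
* **Tolerances.** The network MILPs run at a primal feasibility tolerance
  of $10^{-9}$; the sampling MILP runs at a 1% relative MIP gap — its
  objective (distance to the random draw) only steers the sample, while
  membership in the optimum face is enforced by hard constraints, so gap
  slack never leaks into the reported norms.
* **$\varepsilon$ and big-M.** The minimum active flux defaults to
  $\varepsilon = 10^{-4}$: large enough to dominate the feasibility
  tolerance by five orders of magnitude, small relative to default bounds.
  Big-M constants default to each split column's own upper bound rather
  than a global constant, for tighter LP relaxations; a global `vmax` can
  be supplied.
* **Bounds and reversibility.** Missing or infinite bounds become
  $\pm 1000$ (the conventional COBRA default, configurable); a reaction is
  reversible iff $lb < 0$, and when an input file's reversible flag
  disagrees with its bounds, the bounds win, since they define the cone.
* **GPR semantics.** The mapping of expression to reactions evaluates AND
  as `min` (enzyme complexes limited by the scarcest subunit) and OR as
  `max` (isoenzymes), both configurable; unmeasured genes drop out at each
  operator, and a rule with no measured gene leaves the reaction
  data-orphan. Expression is scaled to the per-replicate maximum before
  mapping, and replicate means are taken afterwards, so the maximum mapped
  reaction value can be below 1. One value per gene is required — probe
  sets mapping to several genes are assumed resolved upstream.
* **Degenerate inputs.** Zero-width sampling ranges give $H = 0$; an
  empty task suite passes vacuously with a warning; a sample in which no
  reversible reaction is active makes the fixed-direction fraction
  undefined (`NA`), not zero.

## What the synthetic fixtures emulate — and what they do not

`make_fixture()` builds small consistent models: linear chains, parallel
alternative routes (a minimal setting with a known number of equally
parsimonious networks), a three-reaction toy with one data-orphan
inter-pool transport, and random backbone-plus-shortcut networks with a
configurable reversible fraction, uniform data on a configurable share of
reactions, and a planted core taken as the top quantile of the data values
— mirroring how expression thresholds define cores in practice. Every
topology can carry flux through every reaction by construction, so
`reduce_model()` is the identity on them.

Two brute-force oracles, deliberately independent of the MILP constraint
builders, provide ground truth at small size: exhaustive subset search with
per-direction LP feasibility for the minimal-subnetwork problem
(`brute_force_min_subnetwork()`, refused above $|P| = 14$), and
sign-enumerated LPs over the optimum face for the sampling problem
(`brute_force_aos_extrema()`). The test suite checks the MILPs against
these oracles on dozens of seeded fixtures; the study sizes there (7–10
reactions, $|P| \le 10$, 25–200 samples per fit) were chosen so a full run
of the suite stays in the minutes range on a single CPU.

Passing on these fixtures shows that the programs are implemented
correctly, not that genome-scale behaviour is reproduced: real GEMs have
thousands of reactions, highly non-uniform expression, thermodynamically
curated bounds, and MILPs whose solve times — not correctness — become the
limiting factor. Nothing in the fixtures emulates expression noise,
probe-to-gene ambiguity or compartmentalization.

## A worked miniature

```{r example, eval = FALSE}
fx <- make_fixture("random", n_reactions = 12, n_metabolites = 6,
                   data_coverage = 0.6, seed = 1)
sol <- regrex_lad(fx$model, fx$data, lambda = 0)
aos <- regrex_aos(fx$model, fx$data, sol, n = 100, seed = 2)
flux_entropy(aos, data = fx$data)

net <- corex(fx$model, fx$core)
ens <- altnet_enumerate(fx$model, core_set(fx$model, fx$core), net,
                        max_iter = 50, seed = 3)
classify_noncore(ens)
```

The same pipeline, at these exact sizes, is what `scripts/acceptance.R`
runs end to end; the README shows its printed output.

## Known limitations

* Exhaustiveness of `altnet_enumerate()` is not guaranteed (by design); the
  1% perturbation restart is a heuristic whose coverage degrades as $|P|$
  grows.
* The backend bridge requires a Python with SciPy on the PATH; there is no
  pure-R MILP fallback.
* Genome-scale models are structurally supported (sparse stoichiometry
  throughout) but constraint matrices are densified at the solver boundary,
  which is wasteful at the scale of published human reconstructions.
* SBML support covers Level 3 + FBC bounds, gene-product associations and
  boundary species; kinetic laws, groups-extension subsystems and SBML
  writing are not implemented (the JSON dialect is the round-trip format).
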