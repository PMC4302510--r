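---
title: "Lattice-based knockout coupling analysis: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-based knockout coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxlattice)
```

## The qualitative model

A metabolic network $(\mathcal M, \mathcal R, S, \mathrm{Irr})$ induces
the steady-state flux cone
$C = \{v \in \mathbb R^{\mathcal R} \mid Sv = 0,\ v_r \ge 0 \ \forall r
\in \mathrm{Irr}\}$.  All analyses in this package depend only on *which*
reactions can be active together, never on flux magnitudes, so we work
with the support family
$L = \{\operatorname{supp} v \mid v \in C\}$.  Two facts make $L$
tractable:

1. $L$ is a **lattice**: $\emptyset \in L$, and the sum of two feasible
   flux vectors (after scaling the summands so that no cancellation
   occurs on a shared reversible reaction — generic scalings avoid exact
   cancellation) shows that the union of two supports is again a
   support.
2. Every finite lattice has a unique maximal element, the union of all
   its elements.  $1_L$ is precisely the set of unblocked reactions, and
   for any knockout set $\mathcal K$, the sub-family
   $L_{\perp\mathcal K} = \{a \in L \mid a \cap \mathcal K = \emptyset\}$
   is again a lattice whose maximal element $1_{L_{\perp\mathcal K}}$ is
   the set of reactions still unblocked after removing $\mathcal K$.

Blocked reactions, directional coupling
($r \to t \iff t \notin 1_{L_{\perp\{r\}}}$), partial-coupling classes
and knockout effects of arbitrary order are all questions about maximal
elements, and the whole package reduces to computing them efficiently.

The qualitative model deliberately cannot express *flux ratios*; "fully
coupled" reactions (fixed ratio) are reported as partially coupled, and
no attempt is made to distinguish them.  Hypotheses beyond steady state
(e.g. thermodynamic loop-law constraints) would change only the
feasibility oracle below, not the lattice algorithms — the oracle is the
single point where model semantics enter.

## The feasibility oracle

`find_path(net, t, K)` asks: is there $v \in C$ with $v_k = 0$ for all
$k \in \mathcal K$ and $v_t \neq 0$?  It solves
$\max\{v_t \mid Sv = 0,\ v_{\mathrm{Irr}} \ge 0,\ v_{\mathcal K} = 0,\
|v| \le M\}$ and, for a reversible target whose maximum is zero, the
corresponding minimum.  Design notes:

* **Box bound** $M$ (default 1000): the cone is scale-invariant, so
  truncating it changes no support; it only keeps the LPs bounded.
* **Two tolerances**: the decision "is $v_t$ nonzero" uses
  $\varepsilon = 10^{-6}$, support extraction uses $10^{-9}$.  The
  asymmetry is deliberate: a spurious support member is harmless — any
  feasible support is a lattice element and only ever *adds* true
  information to the lower bound — while wrongly declaring a target
  blocked would corrupt the upper bound.
* **Vertex solutions**: reversible reactions are split into forward and
  backward parts.  The two columns are negatives of each other, hence
  linearly dependent, so a simplex vertex never carries both
  simultaneously and supports read off the solution are not inflated by
  cancelling pairs.  This is why the backend must be a simplex-type
  (vertex) solver rather than an interior-point method.
* **Solver**: these LPs are tiny but maximally degenerate — the origin
  is always feasible and optimal bases at $v = 0$ abound.  The installed
  general-purpose routines proved fragile exactly there (NaN pivots from
  $0/0$ ratio tests, cycling), so the package carries a ~70-line dense
  primal simplex with Bland's anti-cycling rule, which terminates
  provably and deterministically.  `pracma::linprog` remains available
  as `lp_config(solver = "pracma")` and the test suite cross-checks the
  two backends.  For desk-scale networks (tens of reactions) performance
  is ample (~1 ms per LP); genome-scale models would want an external
  simplex and are not a target of this implementation.

## Maximal elements and witness reuse

`max_element` refines a lower bound `lb` (union of known pathway
supports avoiding $\mathcal K$) and an upper bound `ub` (reactions not
yet proven blocked).  Each oracle call either merges a whole new support
into `lb` or removes one reaction from `ub`; termination at
`lb == ub` is immediate.  Targets are taken from `ub \ lb` in sorted
order, so results *and* LP counts are reproducible run to run.

Supports found anywhere are stored in a **witness pool** (FIFO, default
capacity 10000) shared across knockout computations: under a new
knockout set, every stored support disjoint from it seeds the lower
bound for free.  Witnesses can only change LP counts, never results —
an invariant the test suite asserts — because any valid support is a
lattice element regardless of how it was found.

## Single, double and multiple knockouts

`fca()` computes $1_{L_{\perp\{r\}}}$ for every unblocked $r$ and
derives directional couplings and the partial-coupling equivalence
classes.  Mutual coupling cannot be certified from one direction alone,
so FCA itself computes all single knockouts; the payoff of the class
structure comes next.  The table stores knockout results per class
representative (lexicographically smallest member — any member is
mathematically equivalent) and answers classmate queries through the
class map.

`double_knockout_analysis()` iterates over candidate pairs
$\mathcal K_{2,1}$: unordered representative pairs with no directional
coupling either way (a coupled pair is redundant — it acts like the
dominating single knockout).  For each pair it computes
$1_{L_{\perp\{r,s\}}}$ with the shared pool and reports the jointly
coupled targets
$(1_{L_{\perp\{r\}}} \cap 1_{L_{\perp\{s\}}}) \setminus
1_{L_{\perp\{r,s\}}}$.  Empty-target pairs are kept and flagged so that
ratio statistics have their denominator without re-running.  Results are
reported at representative level; expansion to reaction level
($|[r]|\cdot|[s]|$ pairs, $|[t]|$ targets) happens only in the summary
statistics, never in the core loop.

Two degraded variants exist for benchmarking the algorithmic devices:
variant A iterates over all uncoupled unblocked *reaction* pairs instead
of representatives; variant B additionally runs without witnesses.  Both
must (and in the tests do) give identical class-level joint couplings.

`multi_knockout()` handles one fixed set $\mathcal K$ of any size using
the general characterization
$\bigl(\bigcap_{k \in \mathcal K} 1_{L_{\perp(\mathcal K \setminus
\{k\})}}\bigr) \setminus 1_{L_{\perp\mathcal K}}$, whose equivalence
with the recursive minimal-subset definition is exercised against the
brute-force oracle in the tests.  The degenerate case
$|\mathcal K| = 1$ returns the directional couplings rather than
erroring, keeping the recursion uniform.  `candidate_sets(d, m)`
generates $d$-subsets of representatives filtered by couplings of order
$\le m$ ($m \le 2$; higher orders would need triple-knockout data).
Exhaustive $d \ge 3$ analysis is deliberately not run wholesale — the
candidate sets are the product, and single sets can be evaluated with
`multi_knockout`.

## Gene knockouts

Gene–protein–reaction rules are boolean expressions over genes with
`and`/`or`/`not` and precedence `not` > `and` > `or`.  Negation is part
of the grammar even though curated models rarely use it, because it is
exactly what makes the association map non-monotone: with
$r \equiv g_1 \vee \neg g_2$, reaction $r$ is associated to the knockout
of $\{g_1\}$ but *not* of $\{g_1, g_2\}$.  For this reason gene coupling
judges every gene set on its own associated reactions and does not
subtract the effects of smaller gene sets.

Genes admit no representative compression — distinct genes are distinct
experiments.  Instead `all_gene_knockouts()` memoizes on the associated
reaction set $K_\Gamma$: gene sets inducing identical reaction knockouts
(common, e.g. all genes outside any rule) are solved once.  Rules are
parsed once into expression trees and evaluated by tree walking, not
re-parsed per query.  A reaction without a rule is never removable by
gene knockout; a blocked associated reaction is dropped before the
lattice call since it is absent from every lattice element anyway.

## The brute-force oracle

For networks of up to 12 reactions, `enumerate_lattice()` computes $L$
exactly: for each of the $2^{|\mathcal R|}$ reaction subsets $a$, the
maximal support achievable inside $\{v \mid v_i = 0\ \forall i \notin
a\}$ is a lattice element, and every element arises this way.  A shared
witness pool keeps the total LP effort near-linear in the number of
subsets.  `oracle_analysis()` then derives every coupling notion by
exhaustive iteration over lattice elements with *no further LP calls* —
couplings, classes and joint couplings straight from their definitions.
This is the reference the algorithmic path is tested against; the only
primitive the two routes share is the feasibility oracle itself, which
is in turn cross-checked between two independent simplex
implementations.

`enumerated_lattice()` also accepts hand-specified element families
(validated for union closure), which is how abstract qualitative models
— e.g. the two-gene bookkeeping example in the gene-knockout tests — are
encoded without constructing a stoichiometry for them.

## Synthetic test networks

`random_network()` draws sparse stoichiometries with coefficients
$\pm 1$ (matching the small worked example; real models mostly use small
integer coefficients, so nothing in the LP path depends on this
simplification), a configurable reversible fraction, and appends
single-metabolite exchange reactions so mass can enter and leave.  The
test battery uses 30 fixed seeds with 3–6 metabolites, 4–6 internal
reactions plus 2 exchanges (≤ 8 reactions total, within the oracle's
comfortable range) and reversible fractions 0, 0.3 and 0.6.  These
networks exhibit blocked reactions, nontrivial classes and joint
couplings, which is what the equivalence tests need.  They do *not*
emulate biological realism in degree distribution, compartments, cofactor
ubiquity or GPR structure — passing the battery demonstrates algorithmic
correctness against the definitions, not predictive validity on any
particular organism.  Statistics on real reconstructions should be read
with that distinction in mind.

Problem sizes were chosen so the whole suite (including 30 brute-force
enumerations and all double-knockout analyses) runs in well under a
minute on one CPU.

## Numerical and degenerate-input choices

* Identifiers are opaque strings; all deterministic orderings are
  radix-sorted (locale-independent).  Representative = smallest id.
* SBML finite bounds are used for orientation only ("cone semantics"):
  the cone has no finite bounds, and honoring magnitudes would change
  blocked-reaction calls for bound-limited models.  Reactions with upper
  bound $\le 0$ are re-oriented (column negated) rather than rejected.
  `honor_bounds = TRUE` keeps the magnitudes available as an attribute
  without changing the analyses.
* A knockout set containing a blocked reaction is rejected in
  `multi_knockout` (the joint-coupling definition requires unblocked
  members) but silently reduced in `gene_coupling` (a gene association
  may legitimately include blocked reactions).
* Empty gene sets, rule-less genes, empty candidate-pair lists and
  all-blocked networks all produce well-defined empty results rather
  than errors; the statistics functions error only when a mean would be
  over an empty set (no unblocked reactions).

## Summary statistics

`impact_stats`, `option_stats` and `biomass_blockers` reproduce the
three table families usual in knockout screens.  One definitional
choice deserves a note: the double-knockout impact mean is taken
*conditional* on pairs that have a joint effect at all, with the
effective-pair fraction reported separately as the ratio.  The
unconditional mean over all candidate pairs is recoverable as the
product of the two reported numbers (divided by 100).  Single-knockout
impact excludes the knocked-out reaction's own class; biomass single
counts exclude the biomass's own class, and biomass double counts
consider only pairs whose joint targets contain the biomass — by the
definition of joint coupling such pairs are never directionally coupled
to it.

## Known limitations

* Genome-scale models install and load, but the in-package simplex makes
  full FCA on thousands of reactions impractical; the intended scale is
  tens to a few hundred reactions.
* No "fully coupled" (flux-ratio) detection, no compartments/annotation
  semantics, no FBA objective evaluation, no minimal cut sets.
* Floating-point LP answers at tolerance $10^{-6}$; adversarial
  stoichiometries with coefficients spanning many orders of magnitude
  could in principle misclassify — the coefficient range of curated
  models is far from that regime.
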