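# fluxlattice

Lattice-based flux coupling analysis of metabolic networks, extended to
double and multiple reaction knockouts and to gene knockouts.

## The problem

A genome-scale metabolic model is a stoichiometric matrix
*S* ∈ ℝ^(M×R) together with a set Irr ⊆ R of irreversible reactions.
Its steady-state behaviour is the flux cone

    C = { v | S v = 0,  v_r ≥ 0 for r ∈ Irr }.

Which reactions shut down when one — or several — reactions or genes are
removed?  Classical flux coupling analysis (FCA) answers this for single
knockouts; `fluxlattice` answers it for knockout *sets*, which is what a
genetic-engineering or lethality screen actually needs.

The package works with the *qualitative* model behind the cone: the
family L = { supp v | v ∈ C } of supports ("pathways") of feasible flux
vectors.  L contains ∅ and is closed under union, i.e. it is a lattice,
and its maximal element 1_L (the union of all supports) is exactly the
set of unblocked reactions.  Everything else follows from maximal
elements of sub-lattices: for a knockout set K, the reactions that stay
unblocked are

    1_{L⊥K} = ∪ { a ∈ L | a ∩ K = ∅ },

computed by an LP feasibility oracle (FindPath) inside a lower/upper
bound refinement loop, with previously found pathways reused as
witnesses.  Key notions:

* **blocked**: r ∉ 1_L;
* **directional coupling** r → t: t ∉ 1_{L⊥{r}} (knocking out r blocks t);
* **partial coupling** r ⇔ t: coupled both ways; the equivalence classes
  ("reaction classes") are knocked out wholesale, so one representative
  per class suffices;
* **joint coupling** {r,s} → t: t ∈ (1_{L⊥{r}} ∩ 1_{L⊥{s}}) \ 1_{L⊥{r,s}} —
  a synergistic effect of the pair that neither single knockout shows;
* **gene coupling** Γ → r: r ∉ 1_{L⊥K_Γ}, where K_Γ is the set of
  reactions whose gene–protein–reaction rule evaluates to false with the
  genes in Γ switched off.

## Worked example

The built-in six-reaction network (`example_network()`) has four
metabolites A–D and reactions r1: ∅ ↔ A, r2: A → B+C, r3: B+C → D,
r4: D → ∅, r5: ∅ → C, r6: C → A+D, all irreversible except r1.

```r
library(fluxlattice)
net <- example_network()

dko <- double_knockout_analysis(net)
dko
#> <dko_analysis> 3 candidate pairs, 3 with joint effects
#> LP calls: blocked=2, couplings=11, dko=13, total=26

for (rec in dko$records) print(rec)
#> {r1, r2} -> {r4, r5, r6}
#> {r1, r5} -> {r2, r3, r4}
#> {r2, r5} -> {r1, r4}

impact_stats(dko)
#> <impact_summary>
#>   unblocked reactions: 6
#>   coupling classes:    4
#>   single KO impact:    0.75 classes (1.25 reactions)
#>   double KO impact:    2 classes (2.67 reactions), ratio 100% (3 / 3 pairs)
```

Reading: no reaction is blocked; the six reactions fall into four
partial-coupling classes ({r1}, {r2,r3}, {r4}, {r5,r6}); of the
C(4,2) = 6 representative pairs only three are uncoupled candidates, and
each has a joint effect, e.g. removing r2 *and* r5 additionally blocks
r1 and r4 although neither single knockout blocks anything beyond its
own class.  A single knockout blocks on average 0.75 foreign classes
(the r4 knockout blocks all three others; the rest block none).

Gene knockouts ride on the same machinery:

```r
net <- example_network(gpr = list(r2 = "gA", r3 = "gA or gB",
                                  r5 = "gC", r6 = "gC"))
gene_coupling(net, c("gA", "gC"))
#> {gA, gC}: 3 associated, 6 coupled reactions
```

A brute-force reference (`enumerate_lattice()` / `oracle_analysis()`)
recomputes all of the above by exhaustive enumeration on networks of up
to 12 reactions and backs every algorithmic result in the test suite.

For shell use, `inst/cli/flca.R` wraps the same functions:

```sh
Rscript inst/cli/flca.R stats --model model.json --biomass r1 --out out/run
```

## Model input

SBML Level 3 with the FBC extension (`load_network("model.xml")`) or a
small JSON dialect documented in `inst/extdata/model-schema.md`.  Flux
bounds are used for orientation only (the analyses are defined on the
cone); reactions that can only run backward are re-oriented.
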