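---
title: "Molecular Process Diagrams: model, semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular Process Diagrams: model, semantics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(mpdiagram)
```

## The problem

A rule-based model specifies biochemistry as reaction rules over
molecular patterns. Molecules are typed objects with named components
(sites) that can hold internal states (`Y1~U~P`) and bonds; a pattern
constrains only what matters to the rule, and everything unconstrained
is a wildcard. One rule therefore represents a family of concrete
reactions, which is what defeats the combinatorial explosion of
enumerated networks — and also what makes rule sets hard to draw as a
pathway: reactant and product patterns rarely chain syntactically, so a
naive rule graph is disconnected, while the generated network is
typically too large to draw at all.

A Molecular Process Diagram resolves this with a bipartite graph:
process nodes are the rules themselves, and molecular-complex nodes
group every pattern by its *molecular composition* — the multiset of
molecule types, ignoring states and bonds. The number of process nodes
equals the number of rules exactly, and complex nodes are bounded by the
number of patterns per rule times the number of rules, so the diagram
scales with the model text, not with the generated network.

## The BNGL dialect

`parse_model()` reads `molecule types`, `parameters`, `compartments`,
`seed species`/`species`, `observables`, `functions` and
`reaction rules` blocks (optionally wrapped in `begin model`/
`end model`), with `#` comments and backslash continuation. In
patterns:

* a listed component without a bond suffix is required **unbound**;
* `!n` is an explicit bond, `!+` requires a bond to an unspecified
  partner, `!?` leaves bonding unconstrained;
* `~s` fixes a state; `~?` or omitting the component entirely leaves it
  unconstrained (omission is remembered only for round-trip writing);
* `<->` with two comma-separated rates makes one reversible rule.

`observables` and `functions` are retained as opaque text: they do not
affect the diagram. Constructs whose semantics we do not implement —
`DeleteMolecules`, `include_reactants`/`exclude_reactants`, fixed
species `$` — raise an `unsupported construct` error naming the
construct rather than parsing to something subtly wrong. Compartment
prefixes (`@ec:`) are parsed, carried through round-trips and included
in composition keys (identical composition in different compartments is
a different pool), but no compartment topology is checked; that logic
is simulator-specific.

When a molecule type declares duplicate component names (two identical
binding arms), pattern components bind to type components positionally,
leftmost unused occurrence first. The source material does not fix a
convention for this; positional binding is deterministic and matches
common tooling, and the same convention is used during matching.

## Site classification

For each rule, reactant and product molecules are paired by type name in
order of appearance (leftmost reactant occurrence of a type with the
leftmost product occurrence); surplus molecules are created or
destroyed. Pairing by position rather than by graph matching is a
deliberate choice: it is deterministic, cheap, matches how modelers
write rules, and ambiguous cases are recorded in a provenance note on
the correspondence. Every reactant-side site then receives exactly one
label:

* **modified (state)** — the state constraint differs between sides;
* **modified (bond)** — the bond *class* changes, where the classes are
  unconstrained / unbound / bound and both `!n` and `!+` count as
  bound; a change of explicit partner at equal class also counts;
* **modified (both)** — both, and every site of a created or destroyed
  molecule;
* **context** — unchanged but carrying at least one non-wildcard
  constraint: the molecular context the rule requires;
* **unconstrained** — wildcard on state and bond; irrelevant to the
  rule.

Two edge conventions are worth stating. `!?` on both sides is never a
modification — wildcards carry no commitment, even if written with
different indices. And `!+` versus `!n` at equal (bound) class is *not*
treated as a partner change, because `!+` names no partner to compare;
only two explicit, different partners trigger the bond-modified label.
A site unconstrained on the reactant side but concretely constrained on
the product side is inconsistent rule-writing; it is labeled modified
and a warning is recorded — never silently dropped. Note that a listed
product site such as `x~P` also constrains its bond (unbound), so
against a wildcard reactant it counts as modified in both aspects.

## Diagram construction

One process node per rule — reversible rules deliberately stay a single
node with a `reversible` flag and forward-oriented arcs, preserving the
process-count identity; whether the original implementation merges the
two directions is not documented, so the choice is recorded in the
graph's provenance. One complex node per distinct composition key,
shared across rules and sides. Reactant patterns of one rule with equal
keys merge into a single consumption arc whose stoichiometry is their
count: a homodimerization shows one arc labeled 2, never two parallel
arcs.

Levels only grow annotations; node and arc sets are identical across
levels 1–3. State changes are written `before→after@site` on
consumption arcs and in the resulting-state form (`P@Y1`) on production
arcs; bond changes (`bond@ecd–site`, `unbind@...`) appear on
consumption arcs only, since a formed bond has no meaningful
product-side "before". Context labels (`unbound@tmd`, `bound@ecd`,
`P@Y1`) attach to consumption arcs at level 3. Site names are prefixed
with their molecule type (`EGFR.Y1`) only when another type in the same
pattern carries a site of the same name.

The grouping-by-composition rule has a known consequence: the diagram
depends on how rules are *written*, not just on what they mean. A
ligand-receptor complex written as `EGFR(ecd!+)` contributes to the
`EGFR` node, while the equivalent `EGF(site!1).EGFR(ecd!1)` contributes
to `EGF·EGFR`. The bundled fixture pins the formulation that yields the
documented four-node diagram; rewriting its dimerization rule with
explicit ligands would change the picture without changing the model.

## Matching and expansion

`match_pattern()` enumerates every injective embedding of a pattern
into a concrete species by exhaustive search — correctness over speed,
at pattern sizes where this is trivial. `expand_rule()` applies a rule
to every combination of embeddings over a species pool (species chosen
with multiplicity, as dimerization requires), builds products by
applying exactly the modified-site changes, splits disconnected
products into separate species, and deduplicates reactions by canonical
reactant/product multisets — so embeddings differing only by an
automorphism of the reactant side collapse into one reaction, and no
rate bookkeeping is attempted (counts are over distinct reactions;
kinetics is out of scope). Iterative expansion feeds new species back
into the pool until a fixed point, an iteration cap, or a hard species
cap (default 10,000) that errors explicitly rather than truncating,
since rule sets can generate unbounded networks. Products that cannot
be concretized (`!+` bonds on modified sites, created molecules missing
state specifications) are unsupported-rule errors, not guesses.

Canonical species identity uses exhaustive permutation canonicalization:
molecules are pre-sorted by an index-free signature, permutations
within equal-signature groups are tried, bond indices relabeled in
first-use order, and the smallest serialization wins. Hash-based
canonical labeling was rejected: patterns in rules are small (≤ ~10
molecules), and the exhaustive form is obviously correct and testable
against a brute-force isomorphism oracle.

## Exporters and layout

The layered layout ranks nodes by longest path over the arc flow,
dropping arcs that would close a cycle (self-loops of modification
rules) in deterministic arc order; within a rank, complexes precede
processes, stacked with fixed 80×40 boxes and 40-unit gutters. The
units are arbitrary but fixed so output is byte-reproducible; no
aesthetic optimization is attempted.

GraphML carries the entire graph in typed keys and round-trips to an
equal object. SBGN-ML 0.2 Process Description maps choose glyphs from
the composition key alone: single type → macromolecule, homo-n-mer →
multimer with a cardinality unit of information `N:n`, hetero-complex →
complex container with one macromolecule per distinct type; sites
render as state-variable glyphs once per molecule. Everything
rule-specific lives in `extension` elements on arcs — never in
non-standard attributes on core elements — so stripping extensions from
a level-3 document reproduces the level-1 export byte-for-byte, and any
standard SBGN consumer can read the map. The official XML schema cannot
be fetched in the offline test environment, so the test suite checks
structural validity (namespace, map language, unique glyph ids, bboxes
everywhere, arcs referencing existing glyphs) instead of schema
validation; glyph geometry is not normative in any case.

## The random-model generator

Property tests run on seeded random models, built from archetypes —
state change, binding, unbinding, synthesis, degradation, with optional
reversibility — in which the product side is a copy of the reactant
side with exactly the intended sites changed. This guarantees validity
and coherent context by construction while exercising every constraint
kind (concrete states, explicit `~?`, omission, unbound, `!?`, `!+`,
explicit bonds) at the default configuration: 3 molecule types of 1–4
components with 0–3 states, 6 rules, context probability 0.5, bond
wildcard probability 0.25 — sizes chosen to mirror small published
models while keeping exhaustive oracles instant. The generator restores
the caller's RNG state.

What a green corpus run does establish: the structural invariants
(bipartiteness, process-count identity, complex-node bound, label
partition, round-trips, expansion/classification agreement) hold across
varied well-formed models. What it does not: behavior on adversarial or
semantically inconsistent rule sets beyond the explicitly tested
warning paths, models exploiting duplicate component names at scale, or
real published models' idioms outside this dialect.

## Limitations

* Molecule pairing is positional; rules where the "same" molecule
  should be tracked through a type-preserving rearrangement may be
  classified differently than the author intended.
* Expansion is exhaustive and intended as an oracle on small pools, not
  a network generator; no symmetry-corrected rate factors are computed.
* Compartments are labels, not geometry.
* The SBGN export encodes annotation boxes as extension content with
  plain labels; renderers that ignore extensions will show a valid but
  unannotated PD map.
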