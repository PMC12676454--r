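# mpdiagram

Rule-based models describe site-specific biochemistry as reaction rules
over molecular patterns: one rule stands for many concrete reactions, so
a receptor with nine independently phosphorylated tyrosines (2^9 = 512
states) stays tractable. The price is visualization — a rule set has no
obvious pathway diagram, and the generated network is usually far too
large to draw.

`mpdiagram` builds **Molecular Process Diagrams (MPDs)** for models
written in a BNGL (BioNetGen language) dialect. An MPD is a bipartite
graph with

* one **process node** per reaction rule (reversible rules included), and
* one **molecular-complex node** per distinct *molecular composition*
  (the multiset of molecule types in a reactant or product pattern) —
  states and bond topology never split a node,

joined by consumption (complex → process) and production (process →
complex) arcs carrying stoichiometry. The diagram therefore scales
linearly with the number of rules, not with the generated network.
Three resolution levels add the rule-specific detail back in:

| level | content |
|---|---|
| 1 | complexes, processes, arcs with stoichiometry |
| 2 | + sites **modified** by each rule (`U→P@Y1`, `bond@ecd–site`) |
| 3 | + **molecular context** — sites required but unchanged (`unbound@tmd`) |

Diagrams export to GraphML (round-trippable), SBGN-ML 0.2 Process
Description (annotations in strippable `extension` elements, so removing
them leaves a conventional SBGN-PD map) and DOT. A brute-force pattern
matcher and single-rule expander serve as the semantic oracle, and a
seeded random-model generator drives the property tests.

## Worked example

The bundled six-rule model of early EGFR signaling (ligand binding,
dimerization, transphosphorylation, dephosphorylation):

```r
library(mpdiagram)
m <- egfr_model()
g <- build_mpd(m, level = 3)
g
#> <mpd_graph level 3: 6 processes, 4 complexes, 13 arcs>
```

Six rules collapse onto four complex nodes — `EGF`, `EGFR`, `EGF·EGFR`
and `EGFR·EGFR` — because composition, not state, defines a node. The
arcs tell the pathway story, with modification and context labels:

```r
for (a in g$arcs[c(1, 2, 8, 10)])
  cat(a$kind, a$complex_key, a$rule_id, a$stoichiometry, "|",
      paste(a$site_labels, collapse = " "), "|",
      paste(a$context_labels, collapse = " "), "\n")
#> CONSUMPTION EGF R1 1 | bond@site–ecd |
#> CONSUMPTION EGFR R1 1 | bond@ecd–site | unbound@tmd
#> CONSUMPTION EGFR R4 2 | bond@tmd–tmd | bound@ecd
#> CONSUMPTION EGFR|EGFR R5 1 | U→P@Y1 | bound@tmd
```

Reading these: ligand binding forms the `site–ecd` bond and requires the
transmembrane site unbound; dimerization consumes two receptors
(stoichiometry 2) and requires their extracellular domains bound;
transphosphorylation flips `Y1` from `U` to `P` inside the dimer.

One rule, many reactions — the binding rule expanded over free EGF and
the four receptor phosphoforms:

```r
res <- expand_rule(m$rules[[1]], lapply(m$seed_species, `[[`, "species"), m)
length(res$reactions)
#> [1] 4
enumerate_states(m$molecule_types[["EGFR"]])
#> [1] 4
```

Export:

```r
to_graphml(g, mpd_layout(g), file = "egfr.graphml")
to_sbgnml(g, level = 3, file = "egfr.sbgn")
writeLines(to_dot(g), "egfr.dot")
```

or from the shell:

```sh
Rscript -e 'mpdiagram::mpd_cli()' build egfr_mpd.bngl --level 3 \
    --format sbgnml -o egfr.sbgn
Rscript -e 'mpdiagram::mpd_cli()' stats egfr_mpd.bngl --sites
```

Exit codes: 0 success, 2 parse error, 3 unsupported BNGL construct.

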