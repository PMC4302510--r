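# JSON model dialect

A metabolic network is a single JSON object:

```json
{
  "metabolites": ["A", "B"],
  "reactions": [
    {
      "id": "r1",
      "stoich": {"A": -1.0, "B": 1.0},
      "reversible": false,
      "gpr": "g1 or (g2 and g3)"
    }
  ],
  "genes": ["g1", "g2", "g3"]
}
```

Fields:

* `metabolites` — array of unique metabolite id strings; defines the row
  order of the stoichiometric matrix.
* `reactions` — array of reaction objects in column order:
  * `id` — unique reaction id string.
  * `stoich` — object mapping metabolite id to a (nonzero) real
    coefficient; negative = consumed, positive = produced.  Metabolite
    ids must be declared in `metabolites`.
  * `reversible` — boolean; `false` (or absent) constrains the flux to be
    non-negative.
  * `gpr` — optional gene-protein-reaction rule: a boolean expression
    over gene ids with `and`, `or`, `not` (case-insensitive) and
    parentheses; precedence `not` > `and` > `or`.
* `genes` — array of gene id strings; genes used in `gpr` rules but
  missing here are declared on the fly with a warning.

Identifiers are opaque strings.  There are no compartments, units,
annotations or flux bounds: the model is the steady-state flux cone
`{v | S v = 0, v_r >= 0 for irreversible r}`.
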