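# phylotable

Phylogenetic comparative analyses need two objects that agree taxon for
taxon: a phylogeny whose tips are the sampled taxa, and a character matrix
with one row per taxon.  In real projects the two are curated separately and
drift apart — extra tips, extra rows, duplicated species — and scripts that
prune one object but forget the other are a classic source of silently wrong
results.  `phylotable` is for comparative biologists who want that agreement
enforced by the data structure instead of by discipline: one exact
name-matching step couples one or more trees to a trait table, and every
subsequent operation keeps the two consistent.

The object maintains a single invariant throughout its life:

> the set of values in the taxon-label column equals the tip set of **every**
> tree in the object, with exactly one row per tip, rows stored in the first
> tree's tip order.

Around that invariant the package provides:

- **Matching** (`as_phylotable`): picks the label column by maximum exact
  matches against the tip labels (leftmost on ties, with a warning), prunes
  every tree to the intersection of all tip sets with the table (tree sets
  are forced to one common sampling), drops unmatched and duplicate rows,
  and reports every count in a match report.
- **Queries** (`td[i, j, by]`): full `data.table` syntax on the character
  matrix.  Row filters, per-row derived columns, per-group
  `head(.SD, n)` selections and `:=` updates stay coupled — the label
  column is implicitly retained and the trees are pruned to the surviving
  taxa.  Grouped aggregations that collapse rows detach the table (a plain
  `data.table` is returned with a warning), since the result no longer
  describes tips.
- **Pruning** (`prune_tree`): drop-tip with unifurcation suppression that
  sums merged branch lengths; lengths of suppressed root chains are kept as
  `root.edge`, so every retained tip's root-to-tip path length
  (`tip_depth`) is conserved exactly.
- **Extraction** (`extract_vector`, `[[`, `pull_phylotable`): named trait
  vectors in tip order — the input format of most comparative-method
  functions — and independent copies of the table or trees.
- **External functions** (`apply_treedata`): run `fn(tree, data)` once per
  tree (a list of results for tree sets), e.g. a Brownian-motion fit from
  another package.
- **Character tools** (`detect_character_type`, `detect_all_characters`,
  `filter_matrix`, `has_names`, `force_names`): discrete/continuous
  classification by the distinct-value-ratio rule (non-numeric ⇒ discrete;
  numeric ⇒ discrete iff distinct/non-missing < cutoff, default 0.1) and
  name repair.
- **Newick IO** (`parse_newick`, `read_newick`, `write_newick`): a literal
  dialect — no underscore/space translation, quoted labels stored without
  quotes, metacharacter labels quoted on write, parse errors with character
  offsets, multi-tree files supported.
- **Fixtures and timing** (`generate_benchmark_data`, `run_benchmark`):
  random trees plus trait matrices (50 discrete + 50 continuous columns
  matching 90% of tips, by default) and a median/quartile timing harness.
- A command-line interface (`exec/phylotable`, or `phylotable_cli()` in R)
  with `match`, `filter`, `extract`, `summary`, `simulate` and `benchmark`
  subcommands; exit codes 0 / 2 (validation) / 3 (parse).

## Worked example

```r
library(phylotable)

tree <- parse_newick("(((sp1:1,sp2:1):1,(sp3:1,sp4:1):1):1,(sp5:1,sp6:1):2);")
traits <- data.frame(
  species   = paste0("sp", 1:6),
  ecomorph  = c("trunk", "trunk", "crown", "crown", "twig", "twig"),
  island    = c("Cuba", "Cuba", "Hispaniola", "Hispaniola", "Cuba", "Jamaica"),
  SVL       = c(50, 60, 40, 45, 55, 35),
  hostility = 1:6)

td <- as_phylotable(tree, traits)
td
#> A coupled tree/data object: 6 taxa, 1 tree (6 tips, 5 internal nodes each)
#> Label column: 'species'
#>    species ecomorph     island   SVL hostility
#>     <char>   <char>     <char> <num>     <int>
#> 1:     sp1    trunk       Cuba    50         1
#> 2:     sp2    trunk       Cuba    60         2
#> 3:     sp3    crown Hispaniola    40         3
#> 4:     sp4    crown Hispaniola    45         4
#> 5:     sp5     twig       Cuba    55         5
#> 6:     sp6     twig    Jamaica    35         6
```

A filter plus a derived column stays coupled: the three Cuban taxa keep
their rows (`Index` is the per-row sum `SVL + hostility`) and the tree is
pruned to the same three tips, with merged branch lengths preserving each
tip's root-to-tip depth:

```r
cuba <- td[island == "Cuba", .(Index = SVL + hostility)]
cuba
#> A coupled tree/data object: 3 taxa, 1 tree (3 tips, 2 internal nodes each)
#> Label column: 'species'
#>    species Index
#>     <char> <num>
#> 1:     sp1    51
#> 2:     sp2    62
#> 3:     sp5    60
write_newick(cuba$phy)
#> [1] "((sp1:1,sp2:1):2,sp5:3);"
```

Named vectors come out in tip order, ready for downstream model fits, and
`summary()` reports the character census and everything dropped so far:

```r
extract_vector(td, "SVL")
#> sp1 sp2 sp3 sp4 sp5 sp6
#>  50  60  40  45  55  35
summary(td)
#> Coupled tree/data summary
#>   taxa: 6   trees: 1
#>   characters: 2 discrete, 2 continuous
#>   missing values: 0
#>   dropped since construction: 0 tips, 0 rows
#> Match report: label column 'species'; 6 taxa matched; 0 tips, 0 rows, 0 duplicate rows dropped
```

A grouped aggregation (e.g. `td[, .(mean(SVL)), by = ecomorph]`) returns a
plain `data.table` with a warning: collapsed rows no longer map to tips.

See `vignette("coupled-tree-data")` for the full account of the matching
rules, the query result contract, the pruning conservation law, and the
design decisions behind them.

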