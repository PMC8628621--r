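---
title: "Coupled trees and trait tables: model, invariants and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled trees and trait tables: model, invariants and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotable)
```

## The problem

Phylogenetic comparative analyses work with two objects that must agree
taxon for taxon: a phylogeny whose tips are sampled taxa, and a character
matrix with one row per taxon and one column per measured trait (body size,
ecomorph class, host range, ...).  In practice the two are curated
separately, so names drift apart: the tree carries tips with no data, the
table carries rows with no tip, and a species gets duplicated.  Analyses
that silently recycle or reorder mismatched vectors produce wrong answers
without warning, and scripts that prune the tree but forget the table (or
vice versa) are a classic source of irreproducible results.

`phylotable` makes the agreement a maintained invariant rather than a
one-off cleaning step.  A single matching step builds a coupled object; from
then on every operation — explicit taxon dropping, row filtering, grouped
selection, derived columns — acts on both sides at once, and the package
guarantees at all times:

> **Coupling invariant.** The set of values in the table's taxon-label
> column equals the tip set of *every* tree in the object, with exactly one
> row per tip, and rows are stored in the first tree's tip order.

When an operation destroys the row-to-taxon bijection (a grouped
aggregation, say), the result cannot remain coupled; it is returned as a
plain table with a warning rather than an error, because summary tables are
a legitimate end product — they just no longer describe tips.

## Matching

`as_phylotable(tree, data, label_column = NULL)` performs the match.

* **Label column selection.** If no column is named, each column is scored
  by the number of its values occurring among the first tree's tip labels
  (exact, case-sensitive string comparison), and the best-scoring column
  wins; ties go to the leftmost column with a warning naming the tied
  candidates, so the choice is deterministic and order-stable.
* **Literal names.** Comparison does no trimming, case folding, or
  underscore/space translation, and the Newick reader (below) is equally
  literal.  Silent normalisation is how mismatches hide; if two spellings
  should match, the data should say so.
* **Tree sets.** For multiple trees the matched taxon set is the
  intersection of the label column with the tip sets of *all* trees: a
  coupled object shares one character matrix, so all its trees are forced
  to one common tip sampling.  Each tree is pruned to that set.
* **Duplicates.** Duplicated taxon rows keep the first occurrence; the
  count of discarded duplicates is reported, never silently absorbed.
* **Row order.** Rows are canonicalised to the first tree's tip order at
  match time and after every coupled operation.  This makes
  `extract_vector()` output deterministic and lets downstream functions
  rely on positional agreement between table and tree.

The match report (`td$report`) records the chosen column, the matched-taxon
count, tips dropped per tree, and unmatched/duplicate rows dropped.  The
cumulative counters on the object itself (`dropped_tips`, `dropped_rows`)
start at zero at construction and track changes made *after* it, so
`summary()` separates "what matching cost" from "what you have done since".

## Queries and the result contract

`td[i, j, by]` forwards to `data.table` on a copy of the matrix and then
decides, from the result, whether coupling survived:

1. if the result still contains the label column with unique, known values,
   it is coupled (this covers pure filters, `head(.SD, n)` per group, and
   `:=` updates);
2. otherwise, if re-running the same `i`/`by` with the label column as the
   only `j` yields the same number of rows, `j` was a per-row derivation:
   the label column is re-attached implicitly and the result is coupled;
3. otherwise rows were collapsed by aggregation: the result is returned
   detached, with a warning.

Coupled results prune every tree to the surviving taxa and re-canonicalise
row order; a query that would leave fewer than two taxa is an error, because
a one-tip phylogeny is not a meaningful object.  The two-row-count probe in
step 2 is the weakest test that is still sound: any `j` producing one output
row per input row passes, and any row-collapsing `j` fails it.

```{r query-example}
td <- as_phylotable(
  parse_newick("(((sp1:1,sp2:1):1,(sp3:1,sp4:1):1):1,(sp5:1,sp6:1):2);"),
  data.frame(species = paste0("sp", 1:6),
             ecomorph = c("trunk", "trunk", "crown", "crown", "twig", "twig"),
             island = c("Cuba", "Cuba", "Hispaniola", "Hispaniola",
                        "Cuba", "Jamaica"),
             SVL = c(50, 60, 40, 45, 55, 35),
             hostility = 1:6)
)
td[island == "Cuba", .(Index = SVL + hostility)]   # coupled, 3 taxa
td[, head(.SD, 1), by = "ecomorph"]                # coupled, 1 per ecomorph
td[island == "Cuba", .(mean_svl = mean(SVL)), by = ecomorph]  # detached
```

## Newick dialect

The reader and writer implement a deliberately conservative dialect:

* bare and single-quoted labels are both accepted; quoted labels are stored
  without their quotes, with `''` as the embedded-quote escape;
* **no underscore-to-space translation** in either direction — labels are
  literal, avoiding silent mismatches at matching time;
* on writing, labels containing `( ) , : ;`, quotes, or whitespace are
  single-quoted, so every representable label round-trips;
* branch lengths are optional per edge; trees without lengths are legal;
* internal node labels and a root edge are parsed and preserved, but play
  no role in coupling logic;
* multi-tree input is semicolon-separated, with newlines optional;
* malformed input fails with the character offset of the offending token;
  duplicate tip labels, empty labels, negative lengths, and single-tip trees
  are validation errors.

NEXUS, PhyloXML, and extended-Newick annotations are out of scope.

## Pruning and path-length conservation

Dropping tips creates unifurcating internal nodes; these are suppressed and
the branch lengths of merged edges are summed.  When the suppressed chain
includes the old root, the accumulated length has no single surviving edge
to merge into (the new root may have several children, and adding the
length to each would distort tip-to-tip distances), so it is stored as the
standard `root.edge` attribute, and `tip_depth()` includes `root.edge` in
the root-to-tip sum.  The conservation law the package maintains — and that
the test suite checks against an independent delete-one-tip-at-a-time
oracle on a thousand random trees — is:

> for every retained tip, the root-to-tip path length after pruning equals
> its value before pruning (relative tolerance 1e-9).

Pruning below two tips is an error: single-tip trees are undefined in most
phylogenetic conventions and would make downstream semantics ambiguous.
Pruning composes: `prune(prune(t, S1), S2)` equals `prune(t, S1 ∩ S2)`
whenever the intersection keeps two taxa.

## Character types

The discrete/continuous classifier uses a distinct-value-ratio heuristic:
non-numeric columns are discrete; numeric columns are discrete when
`(distinct non-missing values) / (non-missing values) < cutoff`, continuous
otherwise.  The default `cutoff = 0.1` suits matrices with tens of taxa or
more, where a trait with fewer than one distinct value per ten observations
is far more plausibly a coded state than a measurement; the parameter is
exposed because short tables or heavily rounded measurements can defeat any
fixed threshold.  A character column is only treated as numeric when every
non-missing value parses strictly as a number — `"1.5"` next to `"three"`
stays discrete, avoiding silent coercion.  Ordinal/meristic modelling and
polymorphic state strings (`"A/B"`) are out of scope.

## Synthetic data generator

`generate_benchmark_data(n_tips, cfg, seed)` emulates the standard
benchmark protocol for this kind of tool: a random tree (recursive uniform
bipartition topology, uniform(0,1) branch lengths, tips `t1..tn`) and a
trait matrix covering a uniform random 90% of tips, with 50 discrete
columns (states drawn uniformly from `"A".."E"`) and 50 continuous columns
(standard normal draws).  The state space and trait distributions are
documented stand-ins — realistic in shape (categorical states of moderate
cardinality; centred, unit-scale measurements) but not fitted to any
empirical dataset.

What the generator does *not* emulate matters for interpreting green tests:
real matrices have missing cells, heterogeneous scales, correlated traits,
and phylogenetically structured (non-i.i.d.) trait values, and real trees
are rarely uniform-split random.  Passing tests therefore demonstrate the
*bookkeeping* contracts — matching, pruning, coupling, detection of
column types by their value structure — not statistical performance on
empirical data.

The timing harness (`run_benchmark()`) reports median and quartile
wall-clock times, in milliseconds, for the match step, the coupled
filter-plus-grouped-aggregation query, and the same query on the bare
table.  Absolute timings are hardware-dependent and carry no acceptance
value; the harness exists for inspection and regression watching.

## Numerical and design choices

* Branch lengths are written with 10 significant digits by default
  (`digits` parameter); round-trips are exact to that precision.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state, so simulations are reproducible without global
  side effects.
* Problem sizes in the shipped checks — 1000 random trees (≤ 50 tips) for
  the pruning oracle, 500 for round-trips, 200 randomized operation chains,
  and a 10,000-tip coupling smoke test — were chosen to exercise the
  combinatorics thoroughly while keeping a full check run in well under a
  minute on one core.
* Aggregation detaches with a *warning*, not an error: the weakest reading
  consistent with "row changes affect the matching taxa" that still lets
  users compute summary tables in one expression.
* `pull_phylotable()` and `$dat` return defensive copies; mutating a pulled
  table never corrupts the coupled object.  The price is a copy per query,
  which is the right trade for an object whose selling point is an
  invariant.  By-reference, in-place update semantics are deliberately out
  of scope.

## Known limitations

* One shared character matrix per object; partial tree/data matching
  (trees with deliberately different tip sampling over a common matrix) is
  not supported — the intersection rule is applied instead.
* The `i`-expression grammar of the command-line `filter` subcommand is
  restricted to column/literal comparisons with `& | !` and parentheses;
  arbitrary R in `--where` is rejected (by validation, exit code 2) to keep
  the CLI safe to expose.
* Very deep parsed trees are bounded by the iterative parser/writer, but
  `as_phylotable` on hundreds of thousands of tips is memory-bound by the
  underlying tree structure, not by the table engine.
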