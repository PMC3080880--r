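# anchorlign

Alignment strategies and phylogenetic placement for divergent fungal ITS
data — with a 5.8S "anchored" alignment procedure, iterative
alignment↔tree co-estimation, bootstrap bipartition support, and a
synthetic ITS simulator with known truth.

## The problem

The fungal barcode, the nuclear ribosomal internal transcribed spacer region
(ITS1–5.8S–ITS2), pairs two hypervariable, indel-rich spacers with a short
(~160 nt), highly conserved 5.8S gene. Across divergent lineages —
between-genus whole-ITS similarity routinely falls below 70% — automated
aligners let the conserved 5.8S core dominate and drag ITS1/ITS2 out of
register, which propagates into the phylogeny as spurious long branches and
misplaced environmental sequences. That matters because placing
insufficiently identified environmental ITS records into labeled reference
clades is often the only way to say what an "uncultured fungus" is.

anchorlign implements four strategies on one input set and compares them:

| strategy | what it does |
|---|---|
| `baseline_whole` | single-pass progressive alignment of the whole ITS |
| `coest_whole` | iterative co-estimation: align on a guide tree → re-estimate tree (JC + NJ) → score (JC log-likelihood via Felsenstein pruning) → repeat; best-scored pair kept over independent runs |
| `coest_anchored` | 5.8S excised and replaced by a 16-character constant anchor, then co-estimation — the anchor keeps ITS1 and ITS2 separate and registered while removing 5.8S's pull on the optimization |
| `coest_58s_reincluded` | the excised 5.8S block aligned among itself and spliced back into the best anchored alignment; tree and support on the combined alignment |

Each strategy is evaluated by parsimony-informative column classification,
fraction of bootstrap-supported branches (support > 0.94 by convention),
long-branch counts, Robinson–Foulds distance to the true tree and
sum-of-pairs/column accuracy against the true alignment (on simulated data),
and by support-aware assignment of unlabeled queries to reference clades.

## Worked example

Simulate a 16-taxon ITS dataset (4 leaves masked as environmental queries)
and run all four strategies:

```r
library(anchorlign)
out <- simulate_and_run(sim_config(n_taxa = 16, n_queries = 4, seed = 42),
                        pipeline_config(runs = 2, iterations = 5,
                                        bootstrap_replicates = 100, seed = 42))
out$result$comparison[, c("strategy", "ncol", "pct_informative",
                          "supported_fraction", "rf", "n_assigned")]
#>               strategy ncol pct_informative supported_fraction rf n_assigned
#> 1       baseline_whole  761              41          0.7692308  0          3
#> 2          coest_whole  755              42          0.6923077  0          4
#> 3       coest_anchored  608              50          0.6923077  0          4
#> 4 coest_58s_reincluded  752              42          0.6923077  0          4
```

`ncol` is the alignment width, `pct_informative` the percentage of
parsimony-informative columns, `supported_fraction` the share of internal
edges with bootstrap support above 0.94, `rf` the Robinson–Foulds distance
to the true tree (0 here: at 16 taxa all four strategies recover the true
topology; they separate on harder inputs), and `n_assigned` how many of the
four queries were placed into a reference group — the single-pass baseline
places only 3, the co-estimated strategies all 4. The placements carry the
defining clade's support:

```r
out$result$reports$coest_58s_reincluded$assignments[
  , c("query", "group", "support", "clade_size")]
#>   query group support clade_size
#> 1 t0003    g3    1.00          3
#> 2 t0011    g3    0.99          2
#> 3 t0016    g1    1.00          4
#> 4 t0001    g1    0.96          3
```

Checked against the simulator's truth (`out$assignment_scores`), every
assigned query is placed in its true group in this example.

Every stage is also available on its own: `global_similarity()`, `orient()`,
`filter_records()` (data preparation), `make_anchored()` / `reinsert_58s()`
(anchoring), `coestimate()`, `bootstrap_support()`, `majority_consensus()`,
`classify_columns()`, `rf_distance()`, `monophyly()`, `long_branches()`,
`alignment_accuracy()`, `assign_queries()`. A thin command-line wrapper
lives at `inst/scripts/anchorlign.R` (`simulate`, `run-all`).

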