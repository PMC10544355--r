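# targetrank

Weighted drug-target prioritization and repurposing candidates from pathway
enrichment results.

`targetrank` is for computational biologists who have finished a
differential-expression → pathway-enrichment analysis (SPIA or enrichr) and
want a ranked, reproducible answer to "which proteins in my significant
pathways should we drug, and which existing therapeutics could be
repurposed?" The package resolves every member of every significant pathway
against an offline snapshot of Open Targets-style annotations, scores each
target with a configurable linear weighting of ten attributes, derives a
prioritized-therapeutics table, and tests whether a curated gold target set
is over-represented among the top-ranked candidates.

## The model

Each target's score is a weighted linear combination of ten annotation
attributes:

```
score = w_pw * n_pathways            + w_tract * tractability_count
      + w_appr * n_approved          + w_safe  * n_safety_liabilities
      + w_uniq * n_unique_drugs      + w_dis   * n_associated_diseases
      + w_ph1 * n_phase1 + w_ph2 * n_phase2 + w_ph3 * n_phase3 + w_ph4 * n_phase4
```

where `n_pathways` counts the *significant input pathways* containing the
target (computed per run) and `n_phaseP` counts therapeutics whose maximum
clinical phase is P. Two presets ship with the package — `default`
`(1, 1, 1, -2, 1, 1, 0.5, 1, 1.5, 2)` for repurposing (rewards late-stage
evidence, penalizes safety liabilities) and `novel`
`(0.5, 0.5, 0.5, -2, 0.5, 0.01, 10, 4, 0.5, 0.01)` for early-stage target
discovery — and any custom scheme can be supplied. Targets are ranked by
score (deterministic tie-breaks); each drug inherits the maximum score among
its linked targets. Gold-set enrichment in the top *k* targets is assessed
with the hypergeometric upper tail `P(X >= hits)` over the run's own
prediction universe.

See `vignette("targetrank-methods")` for the full account of the model,
the snapshot backend, and the synthetic-data generator.

## Worked example

Generate a synthetic annotation snapshot with five planted gold targets
(their approved/phase-4/unique-drug counts are inflated 10x over background),
write the matching pathway table and gold set, and run the pipeline:

```r
library(targetrank)

fx <- generate_snapshot(fixture_params(seed = 42))
write_snapshot(fx$snapshot, "demo/snapshot.json")
write_pathway_table(fx$snapshot, "demo/pathways.tsv", "spia")
write_gold_set(fx$gold_symbols, "demo/gold.txt")

run_pipeline("demo/pathways.tsv", "demo/snapshot.json", "demo/results",
             gold = "demo/gold.txt")
#> Parsed 10 pathway record(s) from demo/pathways.tsv
#> 10 pathway(s) significant at alpha = 0.05
#> 43 target(s) resolved; 0 skipped
#> Top-15 enrichment p = 0.00312

ranked <- read_output_tsv("demo/results/targets.tsv")
dplyr::select(ranked, rank, symbol, score, n_pathways, n_approved, n_unique_drugs)
#> # A tibble: 43 × 6
#>    rank symbol   score n_pathways n_approved n_unique_drugs
#>   <dbl> <chr>    <dbl>      <dbl>      <dbl>          <dbl>
#> 1     1 GENE0010 3114.          4        120            250
#> 2     2 GENE0049 3062.          2         60            370
#> 3     3 GENE0037 3030           2         20            450
#> 4     4 GENE0025 2932.          2         80            190
#> 5     5 GENE0001 2720           3         10            170
#> # ℹ 38 more rows
```

The five planted gold targets (`GENE0001`, `GENE0010`, `GENE0025`,
`GENE0037`, `GENE0049`) occupy the top five ranks, and the hypergeometric
test reports p = 0.00312 for their over-representation in the top 15 of a
43-target universe — the pipeline recovers the planted signal. The run also
writes `drugs.tsv` (one row per unique drug with its inherited score and
best target), a `manifest.json` echoing the configuration and per-stage
counts, and `enrichment.json`.

The scoring arithmetic itself is pinned to published worked values: a target
with attribute vector (pathways = 2, tractability = 5, approved = 4,
safety = 0, unique drugs = 11, diseases = 2188, phase3 = 1, phase4 = 4)
scores exactly **2219.5** under the default preset:

```r
score_target(tibble::tibble(
  tractability_count = 5L, n_approved = 4L, n_safety_liabilities = 0L,
  n_unique_drugs = 11L, n_associated_diseases = 2188L,
  n_phase1 = 0L, n_phase2 = 0L, n_phase3 = 1L, n_phase4 = 4L
), n_pathways = 2)
#> [1] 2219.5
```

A thin command-line wrapper ships in `inst/cli/targetrank`:

```sh
inst/cli/targetrank run --input spia.tsv --dialect spia \
    --snapshot snapshot.json --preset default --top-k 15 \
    --gold gold.txt --out results/
inst/cli/targetrank fixtures --out fixtures/ --seed 7
```

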