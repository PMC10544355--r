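---
title: "Weighted target prioritization from pathway enrichment results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted target prioritization from pathway enrichment results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetrank)
```

## The problem

Differential-expression studies routinely end with a list of significantly
perturbed signaling pathways — from SPIA, enrichr, or a similar tool — and
the question "which proteins in these pathways are worth pursuing as drug
targets, and which existing drugs might be repurposed against them?"
`targetrank` answers that question mechanically and reproducibly: it resolves
every member of every significant pathway, attaches the annotations a drug
hunter would look up by hand (disease associations, tractability, safety
liabilities, clinical-phase drug counts, drug links), scores each target with
an explicit linear weighting of those annotations, and reports ranked target
and therapeutic tables plus a statistical check of how strongly a curated
"gold" target set concentrates at the top of the ranking.

## The scoring model

Each target receives

$$
s \;=\; w_{\mathrm{pw}}\,x_{\mathrm{pw}}
 + w_{\mathrm{tract}}\,x_{\mathrm{tract}}
 + w_{\mathrm{appr}}\,x_{\mathrm{appr}}
 + w_{\mathrm{safe}}\,x_{\mathrm{safe}}
 + w_{\mathrm{uniq}}\,x_{\mathrm{uniq}}
 + w_{\mathrm{dis}}\,x_{\mathrm{dis}}
 + \textstyle\sum_{p=1}^{4} w_{\mathrm{ph}p}\,x_{\mathrm{ph}p},
$$

where the ten attributes $x$ are, in order: the number of *significant input
pathways* containing the target (computed per run, not a global database
count), the tractability bucket count, the number of approved therapeutics,
the number of curated safety liabilities, the number of unique drugs ever
developed against the target, the number of associated diseases, and the
number of therapeutics whose *maximum* clinical phase is 1, 2, 3 or 4
(phases are exclusive, not cumulative — a drug is counted once, at its
highest phase).

Two presets are built in:

```{r}
weight_scheme("default")
weight_scheme("novel")
```

The `default` preset rewards late-stage, heavily validated biology — the
configuration used for drug repurposing, where one wants targets with
approved or phase-3/4 therapeutics. The `novel` preset down-weights the
attributes that merely reflect an existing franchise (disease associations,
approved and phase-4 drugs) and strongly up-weights phase-1/2 trial
activity, surfacing targets whose pipeline is young. Weights are arbitrary
finite reals, applied raw: no normalization or capping is performed, so the
associated-disease count (hundreds to thousands for well-studied genes)
dominates the default-weight score. That is a deliberate property of the
method as designed, not an accident; users who want a more balanced score
can pass any custom scheme via `weight_scheme()` or a YAML file.

Both the approved count and the phase-4 count enter the sum even though they
are often numerically equal (an approved drug's maximum phase is 4, so a
target's approved therapeutics usually *are* its phase-4 therapeutics).
Keeping both terms — at weights 1 and 2 — is what reproduces the published
worked scores exactly (see the regression points below), and effectively
gives post-approval evidence a combined weight of 3.

Ties on the score are broken by approved-drug count (descending), then
unique-drug count (descending), then gene symbol (ascending). The tie-break
is a package choice, made so that ranking is a deterministic function of the
*set* of inputs: permuting input rows cannot change the output order.

Drugs inherit the **maximum** score among their linked targets ("a drug is
as promising as its best target"), and the therapeutics table carries one
row per unique drug, sorted by inherited score. Max-inheritance is again a
package choice; mean- or sum-inheritance would double-reward promiscuous
compounds linked to many mediocre targets.

### Regression points

Three published attribute vectors with hand-checkable scores serve as exact
regression tests of the scoring arithmetic (integer/half-unit, so the
comparison is exact):

```{r}
vegfa <- tibble::tibble(
  tractability_count = 5L, n_approved = 4L, n_safety_liabilities = 0L,
  n_unique_drugs = 11L, n_associated_diseases = 2188L,
  n_phase1 = 0L, n_phase2 = 0L, n_phase3 = 1L, n_phase4 = 4L
)
score_target(vegfa, n_pathways = 2)          # 2219.5
```

The corresponding EGFR-like and PTGS2-like vectors score 1960 and 1651, and
the three rank in that order under the default preset. Under the `novel`
preset the EGFR-like vector recomputes to 62.53 deterministically; published
novel-preset scores drawn from a *different* annotation retrieval are not
treated as regression targets, because the attributes themselves differ
between retrievals.

## Inputs

**Pathway tables.** Two dialects are parsed into one record type. The SPIA
dialect maps `Name`/`ID`/`pSize`/`NDE`/`Status` and takes the most
conservative adjusted-p column present (`pGFWER`, then `pGFdr`, then `pG`);
a source-database column is honored when the upstream run merged several
pathway databases. The enrichr dialect maps the term to the pathway name,
splits the `Overlap` fraction into DEG count and pathway size, and infers
the source database from a trailing accession (`R-HSA-…`, `hsa…`).
Significance filtering is a strict `p < alpha` on whatever adjusted column
the dialect supplied — multiple-testing correction belongs to the upstream
tool and is never re-applied here.

**The snapshot.** All annotation lookups go through an offline JSON snapshot
(pathway membership, gene identifier maps, target attributes, drug links)
whose schema ships in `inst/extdata/snapshot-schema.json`. Serialization is
canonical — sorted keys, accession-ordered collections — so snapshots
round-trip byte-identically and pipeline runs are bit-reproducible. In
production the snapshot is populated from an Open Targets-style GraphQL API:
`build_live_query()` constructs the query document and pagination plan, and
`snapshot_from_response()` converts a recorded response into a snapshot. No
HTTP client is shipped; query construction and response conversion are
testable offline, and executing the query is left to the user's transport of
choice. One subtlety carried over from the source data model: the
tractability *count* is the number of tractability buckets reported true
across all bucket types, while the 12 stored boolean *flags* cover only the
approved/advanced-trial/phase-1 buckets of the four modalities — so the
count can legitimately exceed the number of true flags, and the flags are
reported but never scored.

**Missing data.** Pathways absent from the snapshot contribute no members
and are logged, not fatal (enrichment inputs routinely cover more pathways
than any annotation source). Targets in a significant pathway but absent
from the target table are skipped with a logged count. Numeric attributes
absent at conversion default to 0 and a missing subcellular location is
reported as `"No data"`. A run in which no pathway passes the threshold
succeeds with empty outputs and a prominent warning, so pipelines composed
around the tool do not die on a quiet dataset.

## The enrichment test

Given a gold set of externally validated targets (one symbol per line,
case-insensitive matching), `evaluate_topk()` counts the overlap between the
gold set and the top-$k$ ranked targets and reports the hypergeometric
upper tail

$$P(X \ge k_{\mathrm{hits}}),\qquad X \sim
\mathrm{Hypergeom}(N,\,K,\,n),$$

with the universe $N$ equal to the run's own prediction list (all scored
targets), $K$ the gold targets present in that universe, and $n = k$ the
top-list size (default 15). The universe choice matters: the test asks
whether gold targets concentrate near the top of *this* ranking, not whether
they are enriched among all human genes. Only over-representation is tested.
The tail is computed with `stats::phyper()` (log-space, numerically stable);
the test suite validates it against exhaustive enumeration of all
$\binom{N}{n}$ draws for every $N \le 12$ to $10^{-12}$.

## The synthetic-data generator

`generate_snapshot()` builds complete, schema-valid snapshots so every stage
is testable without network access, and plants a recoverable signal for
benchmarking. Defaults: 50 targets, 10 pathways of 5–15 members, 5 gold
targets, inflation 10.

Attributes are **not** drawn independently, because real target annotations
are internally consistent and the scoring behavior depends on that
structure. Per target the generator draws per-phase therapeutic counts and a
shelved-compound count from right-skewed distributions (scaled Beta(1, 3)
over documented integer ranges — most targets sit far below the observed
maxima); sets the approved count equal to the phase-4 count (an approved
drug's maximum phase is post-approval, an equality visible in published
per-target tables); forms the unique-drug count as the sum of per-phase
counts plus shelved compounds; and derives the associated-disease count as a
skewed baseline plus 15 diseases per unique drug, saturating at 2500 —
heavily drugged targets are heavily studied, and the saturation point
matches the magnitude seen for flagship oncology targets. Gold targets
receive the planted signal exactly as specified for the benchmark: their
approved, phase-4 and unique-drug counts are the background draws times the
inflation factor, rounded, with the disease count derived from the final
(inflated) unique count.

Had the attributes been drawn independently and uniformly at the observed
magnitudes, the disease count (range ~2500 at weight 1) would swamp a 10x
inflation of the drug counts and the planted signal would be statistically
unrecoverable at $k = 15$; the consistency structure above is both the more
realistic model and the one under which the benchmark is informative.

What the generator does **not** emulate: correlated pathway membership
(real pathways share genes non-uniformly), heavy-tailed "superstar" targets
beyond the saturation cap, identifier ambiguity (one-to-many symbol maps),
and annotation errors. Passing the planted-signal benchmark therefore shows
the ranking machinery recovers a known signal under honest noise — not that
the default weights are optimal for any particular disease.

Each generation call consumes a private RNG stream seeded from
`params$seed` and restores the caller's RNG state, so fixtures are
reproducible without global side effects; identical parameters give
byte-identical canonical JSON.

## Numerical and design notes

- Scores are computed in double precision as a matrix-vector product; the
  published regression points are exact because their arithmetic is in
  half-units.
- `P(X \ge 0)` is returned as exactly 1, bypassing floating-point summation.
- Pathway matching tries `pathway_id` first, then exact name; fuzzy matching
  was rejected to keep runs deterministic.
- The weight scheme hash stamped into output tables is a 12-hex-digit prefix
  of a stable hash of the (name, value) pairs, for provenance only.
- Problem sizes used by the test suite (50-target snapshots, 20 seeds,
  enumeration up to $N = 12$) were chosen as the smallest sizes at which the
  statistical properties under test are non-trivial; all suites run in well
  under two minutes on one CPU.

## Known limitations

- The score is a hand-weighted linear combination; no calibration, learning
  or multi-objective optimization is attempted, matching the method's
  design.
- The raw associated-disease count dominates default-weight scores; no
  log-scaling or capping is applied (a faithful reproduction of the method;
  revisit via custom weights if this bothers you).
- Drug-score inheritance ignores mechanism: an antagonist and an agonist of
  the same target inherit the same score.
- The gold-set test conditions on the run's own universe; with very small
  universes ($N$ close to $k$) the test has little power by construction.
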