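---
title: "ogxpand: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ogxpand: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogxpand)
```

`ogxpand` integrates four standard upstream outputs — an Orthofinder-style
hierarchical orthogroup table, per-species differential-expression (DE)
tables, an all-vs-all protein hit table, and GO annotations over an OBO
ontology — into per-hypothesis tables of expanded, expression-responsive
gene families. This vignette explains the statistical model and procedure
behind each stage, every tunable parameter that matters, and the design
choices made where the design was genuinely open.

## The expansion model

A *hypothesis* is a declared comparison: species sets `expanded_in` and
`compared_to` (disjoint, both non-empty) plus three cutoffs. For one
orthogroup (OG) with per-species gene counts, a focal species $a$
qualifies against a comparison species $b$ iff

$$ c_a \ge 1 \quad\wedge\quad c_a \ge f\,c_b \quad\wedge\quad c_a - c_b \ge d $$

where $f$ = `min_expansion_factor` (real, $\ge 1$, default 2) and
$d$ = `min_expansion_difference` (integer, $\ge 0$, default 0). The OG is
called **expanded** when at least `Nmin_expanded_in` focal species qualify.

Three decisions here were open and are worth making explicit:

* **Aggregation over `compared_to`.** A focal species must beat *every*
  comparison species (`comparison = "all"`, the default) — the reading
  that the comparison set as a whole "should not show expansion" — with
  `"any"` available as a switch. "All" is the conservative choice: it can
  only shrink the expanded set relative to "any".
* **The $c_a \ge 1$ guard.** With $c_b = 0$ the factor condition is
  vacuously true; without a guard, an absent family would be "expanded by
  a factor of infinity" on the strength of zero genes. The guard plus the
  difference condition gate these calls; equality at $c_a = f\,c_b$
  counts as expanded (the cutoff is a $\ge$).
* **Ploidy.** Species ploidy is recorded but its role in expansion calling
  is not standardized, so normalization is **off by default**; when
  enabled, counts are rescaled to diploid equivalents,
  $c \times 2/\mathrm{ploidy}$, before the predicate is applied. With all
  ploidies equal the calls are provably unchanged (a tested invariant).

## DEG integration

A gene is a significant DEG iff its adjusted p-value is present and
$p_\mathrm{adj} \le \alpha$. The cutoff is deliberately a mandatory,
visible parameter (`alpha`, default 0.05; inclusive comparison): published
analyses in this area use anything from 0.05 to 0.1. Missing adjusted
p-values — produced by the DE tool's independent filtering — are preserved
as missing and never count as significant, matching the semantics of the
tool that produced them. Direction is ignored for DEG counting; an
optional `min_abs_log2fc` filter exists for users who want effect-size
gating. Duplicated DE rows collapse to their first occurrence with a
warning, making DEG counts invariant to row order.

## Neighborhoods from reciprocal best hits

Reciprocal best hits (RBH) are computed across species pairs from the
12-column tabular hit format: per (query, target species) the hit with the
highest bitscore wins, ties broken by smaller e-value then lexicographic
subject id — every choice is deterministic and row-order independent.
Self-hits are removed; within-species hits never form RBH pairs but are
retained for the extended hit tables.

The "most similar additional OGs" of a focal OG are ranked by the number
of RBH links between focal genes and candidate-OG genes (descending), then
maximum linking bitscore, then OG id. Link count was chosen as the primary
metric because it is robust to family size; a bitscore-sum metric would
let one strong pair outvote consistent multi-gene support. Genes assigned
to no OG act as one-gene pseudo-OGs (`singleton:<gene>`), so a strong
unassigned homolog — often a mis-annotation signal — can surface as a
neighbor. `n = 0` is valid and restricts the extended hits to focal-
internal pairs.

## Set over-representation

OG sets are defined by conjunction predicates over the summary table
(`expanded`, `conserved`, `deg[Species] >= m`, `count[Species] > c`,
`any_deg >= m`). The test builds the classical urn: background size $N$,
successes in background $K$, sample $n$ (always intersected with the
background first — the urn model requires nesting), observed $k$, and

$$ p = P[X \ge k], \qquad X \sim \mathrm{Hypergeom}(N, K, n). $$

`hypergeom_sf` sums the tail from exact binomial coefficients with
Kahan-compensated accumulation for $N \le 1000$ and switches to
log-gamma/log-sum-exp above, so small-problem p-values are reproducible to
near machine precision and large problems remain stable.
`fisher_one_sided` computes the same tail through R's hypergeometric CDF —
an intentionally independent formulation used to cross-check the
hand-rolled path; the two agree to $10^{-12}$ relative over every urn with
$N \le 60$ (a tested sweep). A two-sided Fisher variant exists behind a
flag; the one-sided (greater) test is the default because
over-representation is a directional question. No multiple-testing
correction is applied at this layer — it answers a single user-posed
question.

One numerical note: the identity $P[X \ge k] = 1 - P[X \le k-1]$ is only
meaningful to about $10^{-12}$ in *absolute* terms; for tails below
$10^{-13}$ the complement subtraction cancels catastrophically regardless
of implementation, which is why the direct summation is the primary route.

## GO enrichment

Annotations are closed under the true-path rule (`is_a` always; `part_of`
off by default, consistent with common slim practice) with memoized DFS;
cycles are a hard error, unknown terms are dropped with a message, and
obsolete terms are removed. The enrichment universe is **OGs, not genes**:
an OG's term set is the union over member genes, and unannotated OGs stay
in the background. This matches the level at which expansion hypotheses
are formulated; a gene-universe analysis can be performed by passing
per-gene sets directly.

Per term with at least `min_annotated` annotated background OGs (default
3, the conventional minimum node size), the same hypergeometric tail is
tested; BH-adjusted p-values are reported alongside raw ones, and results
sort by raw p then term id. The optional `elim` mode processes terms by
decreasing DAG depth and, whenever a term's raw p falls below `elim_alpha`
(default 0.01), removes its annotated OGs from all ancestors before they
are tested — decorrelating the DAG bottom-up. With `elim_alpha = 0` the
procedure reduces exactly to the classic test (a tested identity).
Classic Fisher is the default algorithm; weight-style algorithms are out
of scope.

## The synthetic world

The generator emulates the *post-upstream* view of a small comparative
RNA-seq experiment; it simulates result tables, not reads or sequences,
because the upstream tools are explicitly out of scope and their output
distributions are what downstream code sees.

Defaults (the stated world, chosen once):

| parameter | default | rationale |
|---|---|---|
| species | 3 grass-like species, ploidy 2 | mirrors a typical three-species test setup |
| `n_ogs` | 500 | large enough for stable set statistics, small enough for seconds-scale tests |
| family size | geometric, mean 3/species; 15% absence | right-skewed family sizes and patchy membership patterns as in real orthogroup tables |
| planted expansions | 6% of OGs, factor 3, margin 1, in species 1 | a clear margin above the calling factor 2 |
| DEG rates | 5% background, 50% in expanded families | background false-positive-ish rate vs a strong stress response |
| adjusted p | Uniform(0,1) null / Beta(0.5, 20) signal mixture; 2% set missing | matches the empirical shape of DE adjusted-p columns incl. independent filtering |
| hit scores | within-OG ~ N(300, 20), cross-OG ~ N(150, 20) | bitscore separation that makes RBH recoverable but not trivial |
| GO | 50-term single-root BP DAG; planted term at study rate 0.6 vs background 0.1, base rate 0.08 | effect size large enough to rank first in ≥ 95% of replicates at n = 30 vs N = 300 |

Two constructions deserve emphasis because they define what a green test
does and does not establish:

* **Background pinning.** After planting, any background OG that would
  qualify at the *written* hypothesis cutoffs has its focal count pinned
  to the smallest comparison count. The planted truth table is therefore
  exact by construction, and `precision = recall = 1` on fixtures
  validates the *calling machinery*, not the biological discriminability
  of real expansion signals — real orthogroup tables contain borderline
  families by the hundreds.
* **Engineered RBH structure.** Each planted OG donates one extra
  duplicate gene whose only hits go to a partner OG lacking the focal
  species, guaranteeing one recoverable cross-OG RBH neighbor; additional
  cross-OG links arise from complementary-coverage sibling pairs. Real
  similarity graphs are denser and noisier; the fixtures validate ranking
  determinism and link counting, not neighbor biology.

The generator is byte-reproducible from (config, seed); truth tables for
expansions, DEG signal indicators and the planted term are written next to
the data.

## Results bundle

The output is an open directory of TSV tables plus `manifest.json` (tool
and schema version, seed, config hash, md5 per member file) rather than a
serialized in-memory object: language-neutral, diffable and
checksummable. Subsetting to a bookmark list keeps the rows of the
selected OGs (and only the DE/annotation rows of their genes), leaves
global metadata untouched, and yields a bundle that validates and reloads
exactly like a full one. The stored run configuration omits the output
directory itself so that identical runs into different locations produce
byte-identical members — the property the determinism tests check.
Pattern-count tables are global summaries and are deliberately *not*
recomputed on subset.

## Numerical and degenerate-input choices

* Longest-isoform filtering: ties broken by lexicographically smallest
  isoform id (platform-independent); the default gene-id rule strips one
  trailing `.N` / `_TN` / `-TN` suffix and is a user-configurable regex.
* Empty cells in the orthogroup table become empty gene lists, never
  missing keys; duplicate OG ids, ragged rows (reported with line number)
  and globally duplicated gene ids are hard errors, with a
  `species:gene` prefixing option for genuinely colliding annotations.
* `k = 0` (or any `k` at or below the urn's lower support bound) returns
  p = 1 exactly; urn invariant violations are errors, not NAs.
* Empty study sets in GO tests warn and return an empty, well-typed table;
  an empty over-representation background is an error while an empty
  sample returns p = 1 with missing fold enrichment.

## Known limitations

* No phylogenetically corrected model of family-size change; the cutoffs
  are descriptive, not a significance statement about evolutionary rates.
* RBH neighborhoods depend on the completeness of the supplied all-vs-all
  table; missing search directions silently reduce link counts.
* The GO machinery handles `is_a`/`part_of` only, and tests within a
  single namespace at a time.
* Gene ids are assumed globally unique across species unless prefixing is
  enabled.
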