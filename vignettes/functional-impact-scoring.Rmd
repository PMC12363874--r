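---
title: "Subfamily conservation patterns and variant functional impact scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subfamily conservation patterns and variant functional impact scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceofis)
```

## The model

A protein family's multiple sequence alignment (MSA) records, column by
column, which residues evolution has tolerated at each position. `ceofis`
evaluates an amino-acid substitution by two complementary count log-ratios
and decides, in addition, whether the substitution looks like a *switch* of
functional specificity rather than a plain loss of function.

The combinatorial entropy of the residues at column $i$ is the log number of
distinguishable permutations of that residue multiset,

$$S_i = \ln \frac{(\sum_a n_i(a))!}{\prod_a n_i(a)!},$$

where $n_i(a)$ counts residue $a$ at the column. An $\alpha \to \beta$
substitution adds one $\alpha$ and removes one $\beta$ from the multiset, so
its entropy change reduces to a count log-ratio. Evaluated on the whole
family it is the **conservation score**

$$\chi_c = \ln \frac{n_i(\alpha)}{n_i(\beta) + 1},$$

and evaluated on the subfamily containing the query protein (counts
$n_i^s$) it is the **specificity score** $\chi_s$. The **functional impact
score** is their mean, $\mathrm{FIS} = (\chi_c + \chi_s)/2$; positive values
mean the variant moves against the observed conservation pattern. Equal
weighting of the two components is fixed: it is also what maximizes
benign/pathogenic discrimination on curated clinical labels.

The **conjugate specificity score** asks the reverse question: is there a
subfamily built around the *variant* residue? Among subfamilies whose
plurality residue at the column is $\beta$, it is the maximum of
$\ln(n^s_i(\beta) / (n^s_i(\alpha) + 1))$; if $\beta$ is nowhere the
plurality, the subfamily with the largest $\beta$ count is used, and if
$\beta$ is absent from every subfamily the score is $-\infty$. A high
specificity score together with a high conjugate specificity score and a
low-to-moderate conservation score is the switch-of-function signature:
wildtype and variant residues conserved in distinct subfamilies. The
converse pattern — very high conservation with negative or $-\infty$
conjugate specificity — marks variants toward residues evolution has never
tolerated anywhere in the family.

## Subfamily decomposition by combinatorial entropy optimization

Subfamilies are found by **CEO**: a joint optimization over a partition of
the aligned sequences and a set of *specificity columns* that are variable
across the family but conserved within subfamilies. For a partition $P$
with blocks $k$ and a column $j$, the raw entropy difference

$$\Delta S_j(P) = S_j(\text{family}) - \sum_k S_j(\text{block } k) \ge 0$$

is maximized by the all-singletons partition, so it cannot be optimized
directly. The objective therefore measures the *excess* of $\Delta S_j$
over its expectation when the column's symbols are randomly permuted across
rows with the block sizes held fixed. Because a block of a random
permutation is marginally a uniform random subset, that null expectation is
$S_j - \sum_k E_j(m_k)$, with $E_j(m)$ the expected entropy of a uniform
$m$-subset of the column. The objective of a partition is

$$\mathrm{obj}(P) = \sum_{j \in \text{selected}} \sum_k
  \left[ E_j(m_k) - S_j(\text{block } k) \right],$$

summed over the top $\lceil a \cdot C \rceil$ of the $C$ candidate columns
ranked by this excess. The excess is exactly zero at both trivial
partitions (singletons: every block has $S = E = 0$; one cluster:
$E_j(N) = S_j$), so the optimum along a merge path is interior whenever the
alignment has real subfamily structure.

$E_j(m)$ is estimated once per column from `n_perm` seeded random
permutations of the column's symbol vector (gaps included), accumulating the
running entropy of every permutation prefix — one pass yields the estimate
for all $m$ simultaneously. Permutations are drawn from the *sorted* symbol
vector, so the estimate depends only on the column's symbol multiset; the
objective is therefore exactly invariant under row reordering. The
standalone estimator `null_entropy_difference()` implements the direct
permute-and-average definition and agrees with the shared-permutation table
within Monte-Carlo error (this is tested). The null model itself is this
package's reconstruction of the classical "compare against random
groupings" idea; original descriptions of CEO leave the ranking statistic
open, and the permutation null is documented here as our concrete choice.

### The agglomerative search

`ceo_cluster()` starts from singletons and greedily merges the pair of
clusters with the best objective, walking the full path to a single cluster
and returning the level with the maximal objective (no early-stop
threshold). Two deliberate approximations/tie-breaks:

* Candidate merges at a level are scored on that level's selected column
  set; columns are re-selected immediately after the merge and the recorded
  level objective is the exact top-$\lceil aC \rceil$ objective of the new
  partition. Re-selecting inside every candidate evaluation would add a
  per-candidate sort with no observed effect on planted-structure recovery
  at the scales we test.
* Ties are deterministic: equal-scoring merges resolve to the pair with the
  lexicographically smallest (older, older) cluster ids, and equal
  objectives along the path resolve to the later level — an alignment of
  identical rows therefore returns one subfamily rather than singletons.

Per-cluster count matrices, per-cluster excess vectors and merged-pair
excess rows are memoized, so a run is dominated by $O(N^2)$ vectorized
pair updates; memory is $O(N^2 C)$ doubles for the pair table, which is the
practical depth limit (use `subsample_alignment()` first, as the pipeline
does).

The granularity parameter $a \in (0, 1]$ — the fraction of candidate
columns admitted to the specificity set — is scanned by `scan_a()` over
0.5 to 0.975 in steps of 0.025, keeping the partition with the maximal
objective (ties to the smallest $a$). `ceo_objective()` recomputes any
partition's objective from scratch with the same seeded null, which makes
the reported objective independently checkable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `coverage` | 0.70 | rows aligning to `< 70%` of query residues are removed (boundary retained); the query row is exempt from every filter |
| `occupancy` | 0.70 | columns need `>= 70%` non-gap characters (boundary included) and a query residue to be scored or clustered |
| `max_sequences` | 20000 | depth cap; deeper alignments are uniformly subsampled (query always kept, seeded) |
| `a_grid` | 0.5–0.975 by 0.025 | granularity scan for the specificity-column fraction |
| `n_perm` | 100 | permutations per column for the null table (units: draws; precision of $E_j(m)$ scales as $1/\sqrt{n_\mathrm{perm}}$) |
| cutoffs | 2.6 / 5.25 / 7 | FIS category boundaries (nats): neutral `< 2.6 <=` low `< 5.25 <=` medium `< 7 <=` high; a value exactly at a cutoff takes the higher-impact category |
| switch thresholds | 4.5 / 4.5 / 5.25 | specificity `>= 4.5`, conjugate specificity `>= 4.5`, conservation `< 5.25` (nats) |

The category cutoffs come from calibration of released scores against
curated benign/pathogenic labels and are shipped as configurable constants;
this package does not re-derive them (that would require the external
clinical databases). The switch-of-function thresholds are this package's
own defaults, chosen so that the bundled reference scores of experimentally
characterized RAC1/CDC42 specificity swaps and of putative recurrent
switch-of-function cancer mutations all pass while the IDH1 active-site
substitutions (very high conservation, negative or $-\infty$ conjugate
specificity) all fail; both margins are several tenths of a nat, and the
thresholds are exposed as configuration.

Counting conventions: residues are the 20 standard letters; `-` and `.` are
gaps; ambiguity codes (B, J, Z, X, U, O) stay in the alignment but count as
nothing, since including them would corrupt the 20-letter count vectors.
Occupancy counts all non-gap characters. The query row is always counted,
which guarantees $n_i(\alpha) \ge 1$ for the true wildtype at any query
position, keeping the forward log-ratio finite. Variant positions are
1-based in the ungapped query; a variant whose claimed wildtype disagrees
with the query residue is still scored against the claimed letters but
flagged `wt_mismatch` and categorized `not_scorable` — isoform mismatches
are common in real variant lists and a silent wrong answer is worse than a
flagged one.

## What the synthetic generator emulates

`generate_planted_msa()` draws one ancestor per subfamily: at planted
specificity columns the ancestors carry distinct residues, elsewhere they
share one residue; rows are ancestor copies with i.i.d. substitutions
(default rate 0.03, uniform over the other 19 letters) and i.i.d. gaps
(default 0.02 — shallow, so that near all columns clear the occupancy
filter and column selection is exercised but not dominant). The default
shape — 3 subfamilies, 30 rows each, 60 columns, 30% specificity columns —
is the standard desk-scale test condition used throughout the test suite.
The background residue distribution is uniform because the scores depend on
counts, not biochemistry, and uniformity gives closed-form expectations
(e.g. a mutation at a conserved column to an absent residue scores
$\chi_c \approx \ln(\text{family residue count})$).

What it does *not* emulate: phylogenetic correlation between rows, rate
heterogeneity across sites, realistic residue frequencies or gap blocks.
Passing the planted-recovery suite therefore shows the optimizer finds
block structure under i.i.d. noise at realistic signal levels; it does not
certify performance on real families, where rows are correlated and
subfamily boundaries are soft. `rows_per_subfamily` accepts a vector so
unequal subfamily sizes can be planted; the "mutation toward the plurality
residue" panel case has a deterministic negative conservation score only
when the plurality subfamily outnumbers the query's, so tests of that case
use unequal sizes. Switch-of-function flag tests use 150 rows per subfamily
at substitution rate 0.01: the maximal attainable specificity score is
$\ln(\text{subfamily depth})$, so depth must comfortably exceed
$e^{4.5} \approx 90$ for the default thresholds to be reachable at all.

## Numerical choices and degenerate inputs

* Entropies are in natural log throughout; `lgamma` (or an exact
  log-factorial lookup inside the clustering loop) avoids factorial
  overflow.
* `log(0)` is allowed to produce $-\infty$ deliberately: an absent wildtype
  (only possible with a mismatched claim) gives $\chi_c = -\infty$, an
  absent mutant everywhere gives conjugate specificity $-\infty$; TSV
  output serializes these as `-inf`.
* A single seed governs subsampling, the permutation null and hence the
  clustering; two runs with the same configuration and seed produce
  byte-identical output files.
* Degenerate inputs: single-row alignments and empty column sets are
  rejected by the clustering; an all-gap query row is rejected at
  construction; an alignment of identical rows returns one subfamily with
  objective exactly 0.
* Noise floor: on a structureless (single-ancestor) alignment the
  *optimized* objective is positive — greedy maximization harvests
  Monte-Carlo and noise co-occurrence signal — but several-fold below that
  of an equally sized alignment with planted structure. Comparisons between
  alignments should use the objective only qualitatively.

## Desk-scale test sizes

The planted-recovery property is run at 2–4 subfamilies × 30 rows × 60
columns with 10 seeded replicates per family size, requiring adjusted Rand
index ≥ 0.9 against the planted labels in at least 9 of 10; these sizes
keep a full granularity scan to a few seconds per replicate while leaving
the per-column signal (counts of ~30 per diagnostic residue) in the regime
where the null correction matters. Full-scale validations of the published
scores (clinical-label AUROC, population-frequency trends, recurrence
analyses) need external databases and UniRef-depth alignments and are out
of scope here; the bundled reference component scores and the planted
suite are what this package's tests actually establish.

## Limitations

* Only substitutions are scored; indels and truncations are out of scope.
* Scores are only as good as the input MSA; positions with poor occupancy
  are reported `not_scorable` rather than guessed.
* The agglomerative search is greedy and single-threaded; the $O(N^2 C)$
  pair table bounds practical depth, which is why the pipeline subsamples
  to at most 20,000 sequences.
* The permutation-null objective is a reconstruction (see above); its
  fidelity to earlier CEO formulations cannot be established from the
  materials this package is built on, and it is validated here by its
  properties (interior optimum, planted-structure recovery) instead.
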