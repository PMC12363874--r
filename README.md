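# ceofis

Evolution-based functional impact scores for amino-acid substitution
variants, from the conservation patterns of a protein-family multiple
sequence alignment (MSA).

Missense variants of unknown significance are the daily bread of cancer
genomics and clinical variant curation. `ceofis` is for researchers who
have (or can build) an MSA of a protein family with a designated query —
typically the canonical human protein — and want, for any substitution or
for all 19 × L of them, an interpretable score of likely functional impact
plus a flag for variants that look like a *switch* of functional
specificity rather than a plain loss of function.

## The method

Aligned homologs are first clustered into **subfamilies** by combinatorial
entropy optimization (**CEO**): a joint selection of a sequence partition
and a set of *specificity columns* — columns variable across the family but
conserved within subfamilies — maximizing the summed excess of the
partition's per-column entropy difference over a permutation null. The
granularity parameter *A* (the fraction of columns admitted to the
specificity set) is scanned over 0.5–0.975 in steps of 0.025 and the value
maximizing the entropy difference is kept. Clustering uses MSA columns with
≥ 70% residue occupancy; sequences covering < 70% of the query are removed
first, and alignments deeper than 20,000 sequences are seeded-subsampled.

For an α→β substitution at query position *i*, with `n(a)` the residue
counts at the column,

    conservation  χc = ln( n(α) / (n(β) + 1) )        (whole family)
    specificity   χs = ln( nₛ(α) / (nₛ(β) + 1) )      (query's subfamily)
    FIS           = (χc + χs) / 2

FIS is categorized neutral < 2.6 ≤ low < 5.25 ≤ medium < 7 ≤ high (nats).
A **conjugate specificity score** — the reverse β→α ratio in a subfamily
where β is conserved, `-Inf` if β is absent everywhere — completes the
switch-of-function rule: specificity ≥ 4.5, conjugate specificity ≥ 4.5,
conservation < 5.25 (all configurable).

See `vignettes/functional-impact-scoring.Rmd` for the model, the
permutation-null construction, parameter semantics and limitations.

## Worked example

Everything is testable without external data via the planted-subfamily
generator:

```r
library(ceofis)

gen  <- generate_planted_msa(n_subfamilies = 3, rows_per_subfamily = 30,
                             seed = 7)            # 90 x 60 synthetic MSA
aln  <- gen$alignment
part <- scan_a(aln, select_scoring_columns(aln), seed = 7)
part
#> subfamily_partition: 90 sequences in 3 subfamilies (query in #1)
#>   a = 0.575, objective = 1459.2899 nats, 35 specificity columns
adjusted_rand_index(part$labels, gen$truth$true_labels)
#> [1] 1
```

The scan recovered the three planted subfamilies exactly (adjusted Rand
index 1) with 1459 nats of above-null entropy difference across 35
specificity columns. Scoring the generator's variant panel:

```r
panel <- generate_variant_panel(gen$truth)
score_variant(aln, part, mutation(panel$position[2], panel$wt_aa[2], panel$mut_aa[2]))
#>   position wt mut conservation specificity conjugate_specificity  fis category
#> 1        2  V   R      -0.0328        3.40                  3.40 1.68  neutral
```

This is the switch-of-function pattern at desk scale: V and R are each
conserved in a different subfamily, so the family-wide conservation score
is near zero while the specificity and conjugate specificity scores are
both at their maximum (ln of the 30-row subfamily depth). The
loss-of-function anti-signature — mutating a family-wide conserved residue
to one never observed — scores conservation 4.47 with conjugate
specificity `-Inf` on the same fixture.

For real alignments, the same pipeline runs from the shell via the
installed `exec/ceofis` script:

```sh
ceofis cluster --input family.fasta --query-id MYPROT_HUMAN --seed 1 --out run1
ceofis score   --input family.fasta --query-id MYPROT_HUMAN --variants G12D,G13D --out run1
ceofis score   --input family.fasta --query-id MYPROT_HUMAN --all --out run1
```

`cluster` writes `partition.tsv` and `partition_meta.json` (parameters,
seed, chosen granularity, objective, specificity columns); `score` writes
`scores.tsv` with one row per substitution (`-Inf` serialized as `-inf`).
Identical configuration and seed reproduce byte-identical files.

The package also ships reference conservation/specificity component pairs
for well-known recurrent cancer mutations; `check_reference_fis()` (or
`ceofis demo-reference`) recombines them through `fis()`:

```r
check_reference_fis()
#>    gene mutation conservation specificity fis_2dp fis_reported category agrees
#>    KRAS     G12D         5.05        1.98    3.52         3.52      low   TRUE
#>    BRAF    V600K         8.35        6.97    7.66         7.66     high   TRUE
#>  PIK3CA   H1047L        -1.16        5.24    2.04         2.04  neutral   TRUE
#>    TP53    R175H         6.99        4.43    5.71         5.71   medium   TRUE
#>  ...
#> 13/13 reference FIS values reproduced
```

Note the instructive outliers: PIK3CA H1047L is a well-known oncogenic
mutation, yet its *negative* conservation score (the leucine is the
majority residue in the family) pulls its FIS into the neutral band — high
recurrence in tumors does not always mean moving against family
conservation.

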