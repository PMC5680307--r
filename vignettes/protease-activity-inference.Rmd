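---
title: "Inferring protease activity from urinary peptide profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protease activity from urinary peptide profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteact)
```

## The model

Naturally occurring urinary peptides are endogenous fragments of larger
proteins. Because no experimental digestion is involved, each detected
peptide's termini are footprints of in vivo proteolysis: a peptide spanning
positions `start..stop` of its parent implies a cleavage after residue
`start - 1` (unless the peptide begins at the parent's first residue) and a
cleavage after residue `stop` (unless it ends at the last). `proteact`
treats these two positions as cleavage events and asks which proteases in a
curated cleavage-site table could have produced them; the balance of
up- versus down-regulated products per protease is then summarized into an
activity score.

The chain has four stages.

**Differential testing.** Peptide abundances are compared between the two
groups with the Mann–Whitney rank-sum test. We use the exact null
distribution of U when the pooled sample size is at most 12 and the values
are tie-free, and the normal approximation with midrank tie correction
otherwise; no continuity correction is applied in the approximate branch.
P-values are adjusted by the Benjamini–Hochberg step-up procedure, and the
regulation call combines the adjusted p-value with a fold-change gate on
raw-abundance group means: `up` when adjusted p < 0.05 and FC > 1.5,
`down` when adjusted p < 0.05 and FC < 0.66. The asymmetric gate pair is
kept verbatim (0.66, not 1/1.5); both gates and alpha are arguments. Fold
change uses group means rather than medians — with an undetected peptide
encoded as abundance 0, medians of sparsely detected peptides collapse to
0/0 far more often, and means match the "change in mean signal" reading of
CE-MS intensities. An all-zero peptide has undefined fold change and is
never called regulated.

**Protease prediction.** A cleavage event matches a cleavage-site entry on
the *same substrate* when accession and P1 position coincide, or on a
*different substrate* when the two sites share an identical sequence
context. We represent the context by the standard P4..P1|P1′..P4′ octamer
(padded with `-` at protein ends) and require exact octamer equality — the
strictest reading of "observed in different substrate"; the window
half-width is an argument. Only entries with experimentally observed
evidence are used; probability-matrix predictions are out of scope by
design. Multiple matches of one protease to one peptide (e.g. both
termini) are deduplicated to a single association, with the same-substrate
mode preferred as the recorded one, so downstream occurrence counts are
counts of peptides, not of events. N- and C-terminal events are pooled
against a single site table rather than matched against terminus-specific
records; site tables do not record which product side was observed, so
pooling is the only choice that uses all the evidence.

**Activity scoring.** For protease *j*, let `occ_up(j)` and `occ_down(j)`
be the numbers of its unique up-/down-regulated associated peptides, and
`n_up`, `n_down` the sums of these occurrences over *all* predicted
proteases before any reporting threshold (associations counted with
multiplicity: a peptide linked to three proteases contributes three). With
`n_total = n_up + n_down`:

\[
weight_j = \frac{occ_{down}(j)}{n_{down}} + \frac{occ_{up}(j)}{n_{up}},
\qquad
\%freq_j = \frac{occ_{up}(j) - occ_{down}(j)}{occ_{up}(j) + occ_{down}(j)}
           \cdot 100,
\qquad
Score_j = \%freq_j \cdot weight_j .
\]

`%freq` is the normalized imbalance of the protease's own products
(bounded in [−100, 100]); `weight` scales it by how much of the overall
regulated degradome the protease explains. The sign of the score equals
the sign of `occ_up − occ_down`; swapping the up/down roles everywhere
negates it. The packaged reference fixture reproduces all 17 published
protease scores at 2-decimal display rounding from exactly these formulas
with `(n_up, n_down) = (93, 42)`:

```{r table3}
head(recompute_table3()[, c("protease", "pct_freq", "score",
                            "printed_pct_freq", "printed_score")], 5)
```

The denominators are deliberately the association totals over all
predicted proteases, pre-threshold: those totals reproduce every printed
score and sum to the printed number of regulated associations (135),
whereas cohort-level regulated-peptide counts do not. When one direction
has no associations anywhere (`n_up = 0` or `n_down = 0`, possible in
small or one-sided datasets), the corresponding weight term is defined as
zero rather than 0/0; the published configuration never hits this case.
Proteases with fewer than `min_peptides = 3` regulated associated peptides
are dropped, and the report lists activated proteases (score > 0) in
descending score order followed by inhibited ones in ascending order, ties
broken alphabetically for determinism.

**Cross-omics concordance.** Predicted direction (activated iff score > 0)
is compared per protease with external direction labels — tissue
transcript trends and protease protein-expression trends supplied as a
table. `increase` meeting a predicted activation (or `decrease` meeting
inhibition) is `agree`; crossed directions `oppose`; `no_change` and
`inconclusive` labels pass through untouched and are tallied separately.
How conflicting external datasets were collapsed into one label is not
algorithmic here: the label is an input.

## The synthetic cohort generator

Real urinary CE-MS cohorts are not redistributable, so validation runs on
synthetic cohorts that emulate their structure: two groups of samples,
log-normal peptide abundances (positive, right-skewed, multiplicative
noise — `exp(mu + N(0, sigma))` with per-peptide baseline `mu` drawn
uniformly on `log(500)..log(5000)` signal units), peptides that are true
substrings of randomly drawn parent proteins, and a cleavage-site table in
which each planted protease owns a set of sites. Every peptide spawned
from a site abuts it with exactly one terminus (the free terminus is kept
clear of all sites), so the planted association structure is unambiguous
and the matcher can be checked for exact recovery. Peptides of an
"activated" protease get their case-group abundances multiplied by the
effect size, "deactivated" ones divided by it; background peptides with no
site association are added in equal parts up-/down-/un-regulated.

Defaults: 30 case and 30 control samples; 6 activated, 6 inhibited and 5
null proteases with 5 sites × 2 peptides each (10 peptides per protease);
effect size 4; log-scale noise sigma 0.5 (≈ 53% coefficient of variation,
a realistic figure for untargeted peptide signal); 60 background peptides;
20 parent proteins of 200–400 residues. These sizes keep a full pipeline
run under a second while leaving the rank tests non-trivial; the direction
recovery checks aggregate 20 seeds.

What passing these tests shows — and does not. The generator plants clean,
site-anchored peptides with homogeneous effects and no missingness, PTMs,
migration-time artifacts or correlated peptides from shared parents. Tests
against it validate the statistical machinery, the matcher and the score
bookkeeping; they do not certify performance on real cohorts, where
cleavage-site annotation is incomplete and effects are heterogeneous.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; readers never renumber.
* Undetected peptide in a sample = abundance 0; no imputation. Modified
  sequences are carried as annotation only; coordinates refer to the plain
  residue string.
* The exact/approximate Mann–Whitney switch is at pooled n = 12; at n = 3/3
  the smallest achievable two-sided exact p is 2/20 = 0.1, so no peptide
  can pass alpha = 0.05 — tiny cohorts yield an empty, clean report rather
  than spurious calls.
* All randomness in the generator is a pure function of the config seed;
  the analysis path itself has no randomness, and repeated pipeline runs
  are byte-identical.
* Scores are kept at full precision internally; display rounding (score to
  2 decimals, %freq to the nearest integer) is applied only when
  formatting.

## Limitations

* The score has no attached uncertainty; it is a descriptive imbalance
  measure, not a test statistic.
* Cross-substrate matching by exact octamer identity is conservative;
  near-identical sites are not matched.
* Evidence adjudication (e.g. between conflicting transcriptomic datasets)
  happens upstream of this package.
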