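# proteact

Protease activity inference from urinary peptidomics.

Urine carries thousands of naturally occurring peptides — endogenous protein
fragments whose N- and C-termini record in vivo proteolytic cleavage events.
When the abundance of a protease's cleavage products shifts between two
clinical groups (for example diabetic patients with nephropathy versus
diabetic patients without), that shift is indirect evidence that the
protease's activity itself has changed. `proteact` implements this inference
chain for anyone working with CE-MS–style peptide profiles:

1. **Differential peptides** — per-peptide two-group comparison with the
   Mann–Whitney rank-sum test, Benjamini–Hochberg FDR control, and
   fold-change gates (up: FC > 1.5, down: FC < 0.66, on adjusted p < 0.05).
2. **Protease prediction** — each regulated peptide's termini define
   cleavage events (N-terminal event at P1 = start − 1, C-terminal event at
   P1 = stop) which are matched against a curated cleavage-site table
   (protease, substrate accession, P1 position), either on the same
   substrate or through an identical P4..P4′ octamer context on a different
   substrate. Only experimentally observed cleavage-site associations are
   used; probability-based predictions are excluded.
3. **Activity scoring** — per protease, with occ(up)/occ(down) the number of
   its up-/down-regulated associated peptides and n(up)/n(down) the totals
   of regulated associations over all predicted proteases:

   ```
   weight   = occ(down)/n(down) + occ(up)/n(up)
   freq%(up)   = occ(up)/n(total) * 100
   freq%(down) = occ(down)/n(total) * 100
   %freq    = (freq%(up) - freq%(down)) / (freq%(up) + freq%(down)) * 100
   Score    = %freq * weight
   ```

   A positive score predicts increased proteolytic activity, a negative
   score predicts inhibition. Proteases with fewer than 3 regulated
   associated peptides are dropped from the report.
4. **Cross-omics concordance** — each scored protease is annotated against
   external direction evidence (kidney transcript levels, protease protein
   expression): `agree`, `oppose`, `inconclusive`, `no_change` or `missing`.

A seeded synthetic-cohort generator emits peptide tables, parent-protein
FASTA, cleavage-site and evidence tables with planted activated/inhibited
proteases, so the whole pipeline can be validated end to end without any
clinical data.

## Worked example

Generate a synthetic cohort (30 vs 30 samples; 6 activated, 6 inhibited and
5 null proteases with 10 peptides each; 4-fold planted effect) and run the
full pipeline:

```r
library(proteact)

cohort <- generate_cohort(simulation_config(seed = 4))
paths  <- write_cohort(cohort, "demo_cohort")
report <- run_pipeline(paths$peptides, paths$fasta, paths$cleavage_db,
                       groups = paths$groups, evidence = paths$evidence,
                       out_dir = "demo_run")
report$counts
```

```
$peptides_detected   230
$regulated_up         80
$regulated_down       80
$associations        120
$n_up                 60
$n_down               60
$proteases_predicted  12
$proteases_reported   12
```

All 12 non-null planted proteases are recovered with the correct sign
(`demo_run/scores.tsv`):

```
protease  occ_down  occ_up  pct_freq  score
ACTP1     0         10      100       16.67
ACTP2     0         10      100       16.67
...
INHP1     10        0       -100      -16.67
```

The packaged reference fixture reproduces the published diabetic-nephropathy
protease table from its occurrence counts (n_up = 93, n_down = 42):

```r
recompute_table3()
#  protease occ_down occ_up pct_freq  score printed_pct_freq printed_score ...
#  CTSD            1      9       80   9.65               80          9.65
#  KLK4            0      7      100   7.53              100          7.53
#  ...
#  MMP-13         10      4      -43 -12.05              -43        -12.05
# all 17 rows match at 2-decimal display rounding
```

The same stages are scriptable from a shell via `exec/proteact`
(subcommands `simulate`, `diff`, `predict`, `score`, `concord`, `run-all`,
`table3`).

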