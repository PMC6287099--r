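# caprisweep

Selection scans for multi-breed resequencing cohorts: SNP deserts, pooled
heterozygosity and Fst sweep scans with Z-score thresholds, cross-population
extended haplotype homozygosity (XP-EHH), and the derived gene
classifications — SNP-desert-associated genes (**SAGs**),
domestication-associated genes (**DAGs**) and trait-associated genes
(**TAGs**) — with QTL cross-referencing. The package targets the classic
livestock design: several domesticated breeds resequenced alongside a small
wild outgroup (the motivating system is goat breeds selected for dairy,
cashmere and meat production). It ships a forward-time Wright–Fisher cohort
simulator that generates every input the scans consume (phased VCF,
callable-mask BED, GFF3 gene models, QTL BED, group table, FASTA) with known
ground truth, so every rule in the pipeline is testable against planted
signals.

## The statistics

* **SNP deserts** — SNP rates in 10-kb windows, normalized by the callable
  (≥8-fold-covered) length rather than the window span; windows with under
  1 kb callable are rejected. Windows in the lowest decile of rates seed
  deserts; seeds separated by ≤10 kb are joined. A gene covered by deserts
  over strictly more than 30% of its span is a SAG.
* **Pooled heterozygosity** — per 100-kb window, from pooled read counts of
  the major and minor allele at each SNP:
  `Hp = 2 ΣnMAJ ΣnMIN / (ΣnMAJ + ΣnMIN)²`.
* **Fst** — windowed ratio-of-averages, Hudson-style plug-in estimator by
  default (Weir–Cockerham optional), domestic pool vs wild outgroup for the
  domestication scan, one breed vs the pooled other breeds for the breed
  scans.
* **Z-scores and calls** — Hp and Fst are standardized across windows;
  a window with `ZHp ≤ −3` OR `ZFst ≥ 3` is a domestication-sweep
  candidate (genes overlapping it are DAGs); a window with breed-wise
  `ZFst ≥ 4` AND a windowed XP-EHH score in the top 1% is a breed-sweep
  candidate (genes overlapping it are TAGs).
* **XP-EHH** — from-scratch EHH / iHH on phased haplotype panels:
  `raw = ln(iHH_focal / iHH_reference)` per core site, normalized
  genome-wide, aggregated per window.

See the methods vignette (`vignettes/caprisweep-methods.Rmd`) for the model
details, parameter defaults, simulator calibration and known limitations.

## Worked example

Simulate the default cohort (3 breeds × 5 diploids + 4 wild, 29× depth,
1-Mb chromosome), filter it, and run the domestication scan:

```r
library(caprisweep)

sim <- simulate_cohort(sim_config(seed = 1))
glance(sim)
#> # A tibble: 1 × 8
#>   n_samples n_sites n_snps n_indels n_genes       L     s sel_final_freq
#>       <int>   <int>  <int>    <int>   <int>   <int> <dbl>          <dbl>
#> 1        19    1905   1705      200      50 1000000     0             NA

vt <- filter_snps_by_depth(sim$variants)
qc_report(vt)
#> # A tibble: 4 × 2
#>   criterion                              count
#> 1 snp_low_depth_removed                      0
#> 2 het_calls_demoted                          3
#> 3 snp_monomorphic_after_demotion_removed     0
#> 4 snp_retained                            1705

st <- scan_domestication(vt, sim$groups, chrom_lengths = sim$chrom_lengths)
head(st, 4)
#> # A tibble: 4 × 8
#>   chrom  start    end n_snps    hp   fst    zhp   zfst
#> 1 chr1       0 100000    179 0.172 0.470 -0.316  0.600
#> 2 chr1  100000 200000    157 0.198 0.356  0.965 -0.805
#> 3 chr1  200000 300000    173 0.148 0.308 -1.50  -1.39
#> 4 chr1  300000 400000    167 0.188 0.489  0.503  0.832
```

Each row is one 100-kb window: `hp` is the pooled heterozygosity of the 15
domestic samples (read-count based, bounded by 0.5), `fst` the
domestic-vs-wild differentiation, and `zhp`/`zfst` their genome-standardized
scores. At this neutral 1-Mb scale no window reaches the sweep thresholds:

```r
glance(classify_dags(st, sim$genes))
#> # A tibble: 1 × 5
#>   kind  n_windows n_genes zhp_cut zfst_cut
#> 1 DAG           0       0      -3        3
```

Per-breed deserts come from the breed's own polymorphic SNPs:

```r
w <- snp_rate_windows(subset_polymorphic(vt, group_samples(sim$groups, "dairy")),
                      sim$mask, chrom_lengths = sim$chrom_lengths)
head(call_deserts(w), 3)
#> # A tibble: 3 × 6
#>   chrom  start    end length n_windows mean_rate
#> 1 chr1       0  10000  10000         1    0.0002
#> 2 chr1   90000 100000  10000         1    0.0002
#> 3 chr1  230000 240000  10000         1    0.0001
```

`run_pipeline(run_config(...), "run_dir")` chains all stages — simulate (or
load files), QC, effect annotation, desert scan per breed, domestication
scan, breed Fst + XP-EHH scans, gene classification, QTL cross-reference —
writing every table plus a manifest of config hash and file checksums;
reruns with the same config are byte-identical. A thin command-line wrapper
lives at `inst/scripts/caprisweep.R` (subcommands `simulate`, `run-all`,
`report`).

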