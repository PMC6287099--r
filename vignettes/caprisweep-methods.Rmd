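---
title: "Selection scans for multi-breed cohorts: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans for multi-breed cohorts: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprisweep)
```

## The scientific problem

Intensive trait-driven breeding leaves three kinds of footprints in a
resequenced cohort of domestic breeds and their wild relatives:

1. **SNP deserts** — runs of windows with exceptionally low SNP rate,
   interpreted as long-standing purifying selection or old sweeps;
2. **domestication sweeps** — windows where the pooled domestic samples
   have unusually low heterozygosity (Hp) or unusually high differentiation
   (Fst) from the wild outgroup;
3. **breed-specific sweeps** — windows where one breed is both strongly
   differentiated from the other breeds (Fst) and carries unusually long
   haplotypes relative to them (XP-EHH).

caprisweep implements these three scans and the derived gene
classifications — SAG (SNP-desert-associated gene), DAG
(domestication-associated gene) and TAG (trait-associated gene) — together
with a forward-time Wright–Fisher cohort simulator that produces every
input the scans consume (phased VCF, callable-mask BED, GFF3 gene models,
QTL BED, group table, FASTA reference) with known ground truth.

All genomic intervals are 0-based and half-open internally; VCF positions
are shifted on read and restored on write, so a single coordinate
convention crosses BED, GFF3 and VCF without off-by-one drift.

## Variant-level rules

**Depth filter.** A SNP site is removed when any individual's summed
allelic depth is below 8. The phrase "minimum depth below the cutoff in
all individuals" admits two readings; the strict one (any individual below
8 removes the site) matches a cohort analysed at a uniform ~29x depth,
where the two readings rarely differ, and is the default
(`mode = "any_below"`); the permissive reading is available as
`mode = "all_below"`. A heterozygous genotype call is demoted to missing
unless both alleles are supported by at least 4 reads; a site that loses
its polymorphism this way is dropped, and every decision is tallied in a
filter report.

**Indel filter.** Indel records are removed when caller quality is below
20, the reference homopolymer context exceeds 10 bp, or the indel is
longer than 5 bp — boundaries read inclusively ("longer than 10" keeps
10). The per-strand support rule (two reads per strand) applies only when
per-strand depths exist; otherwise it is skipped with a warning, since the
order of that rule relative to the other three is not fixed anywhere and
strand counts are frequently unavailable downstream of calling.

**Effect annotation.** Biallelic SNPs are placed against gene models:
outside any span → intergenic; inside a span but not in CDS → intronic (a
UTR class is deliberately not split out, keeping the three-way partition
reproducible); inside CDS → the alternate base is substituted into the
reference codon (reverse-complemented for minus-strand genes) and
translated with the standard genetic code. Stop gains/losses count as
nonsynonymous and carry a flag. Genes whose CDS length is not a multiple
of three (truncated models) yield `other_coding` rather than a guess. The
test suite checks every coding call against an independent oracle that
translates the entire mutated CDS with Biostrings, and checks that
reverse-complementing the whole genome (sequence, gene models and alleles)
leaves every call unchanged.

## The desert scan

SNP rates are computed in 10-kb windows and normalized by the *callable*
length — the window's intersection with the ≥8-fold-coverage mask — rather
than the window span; windows with under 1 kb callable are rejected. Seeds
are the windows whose rate falls at or below the empirical lowest-decile
cutoff, defined by ceiling-rank selection on the sorted rates with all
ties included: rank interpolation schemes differ between libraries, and
rank selection is exactly reproducible. Seeds on a chromosome are joined
into one desert when the gap between them is at most 10 kb, and a desert's
length is measured end-to-start of the joined region — gaps included — so
total desert length can exceed the summed seed spans. A gene is a SAG when
strictly more than 30% of its genomic span (introns included — "harboured
by" a desert is read as genomic residence, and desert windows are not
exon-aware) is covered by deserts. Deserts longer than 100 kb and the
top-10 largest deserts are available as separate reports.

Two choices were genuinely open. The scan windows are non-overlapping
tiles by default: a step size for the "sliding" windows is not printed
anywhere, tiles make window counts and the decile denominator unambiguous,
and `step` is exposed for users who want overlap. And each breed's decile
is computed within that breed's own genome-wide window set, because desert
landscapes are reported per breed.

## The sweep scans

**Pooled heterozygosity.** For each 100-kb window, summing over its
biallelic SNPs the pooled read counts of the most and least abundant
allele (nMAJ, nMIN) across the chosen samples:

$$Hp = \frac{2\,\sum n_{MAJ} \sum n_{MIN}}{(\sum n_{MAJ}+\sum n_{MIN})^2}$$

Hp lies in [0, 0.5] and is invariant to allele relabeling. The statistic
is defined on read counts; when a site carries no depth information the
pooled genotype allele counts stand in (announced once per call).

**Fst.** Windowed as a ratio of averages of per-site components. The
default estimator is the Hudson-style plug-in

$$N_s = (p_1-p_2)^2,\qquad D_s = p_1(1-p_2)+p_2(1-p_1),\qquad
F_{st} = \textstyle\sum_s N_s \big/ \sum_s D_s,$$

which is exactly 1 for fixed differences and exactly 0 for equal allele
frequencies — the two anchor cases the test suite pins at machine
precision. The Weir–Cockerham two-population estimator (sample-size
corrected; can go slightly negative) is available via
`estimator = "wc"`. Sites monomorphic across both groups, or with fewer
than two called diploids in either group, are skipped.

**Z-scores and calls.** Hp and Fst are standardized over the windows that
carry SNPs, using the sample (n−1) standard deviation — at genome window
counts the convention is immaterial, but one must be fixed. A window is a
domestication-sweep candidate when ZHp ≤ −3 **or** ZFst ≥ 3 (inclusive
thresholds: a window "passes the threshold" when it reaches it); a DAG is
a gene overlapping any flagged window. The per-window OR rule is applied
window by window, not region by region. Breed scans test one breed
against the pooled other breeds; a window is a breed-sweep candidate when
its ZFst ≥ 4 **and** its windowed XP-EHH is in the top 1% of scored
windows; a TAG is a gene overlapping such a window.

The top-1% set is the `ceiling(0.01 * n)` highest-scoring windows with
ties broken by genomic order. With the floor convention, any scan of
fewer than 100 windows would have an empty top set and the rule could
never fire; with ceiling, the flagged count is still bounded by
`ceiling(0.01 * n)` on any input, which is the form the test suite
asserts.

## EHH, iHH and XP-EHH

A haplotype panel is a binary haplotype-by-site matrix on strictly
increasing physical positions, phased, with no missing alleles and at
least four haplotypes. EHH at a flanking site x is the probability that
two randomly drawn haplotypes are identical at every panel site strictly
between the core and x, inclusive of x:

$$EHH(x) = \sum_h \binom{n_h}{2} \Big/ \binom{n}{2}$$

over haplotype-identity groups h. The core site itself does not split
haplotypes, so EHH(core) = 1 and the profile is non-increasing outward —
an invariant asserted per profile. This "combined-core" variant (groups
over all haplotypes rather than per core allele) is the one appropriate to
a cross-population comparison, where the contrast is between populations,
not between alleles.

iHH is the trapezoidal integral of EHH against physical distance (no
genetic map is assumed), left plus right. Profiles truncate when EHH
drops below 0.05 or the extension exceeds 1 Mb; cores whose EHH has not
decayed when a chromosome end is reached are skipped by the scan (edge
bias), with a tally. XP-EHH at a core is ln(iHH_focal / iHH_reference) —
antisymmetric under population swap by construction — normalized to mean
0, sd 1 over all scored cores jointly (frequency-binned normalization is
deliberately not applied; at the sample sizes involved the bins would be
tiny). Cores with zero iHH in either panel are skipped and counted.
Per-window values are the maximum normalized score over cores in the
window by default (`aggregate = "mean"` is available). The scan thins
cores to at most 2000 evenly spaced sites per chromosome by default —
about 40 cores per 100-kb window at the simulated scales, ample for a
window-level maximum.

## The cohort simulator

`simulate_cohort()` is a discrete-generation diploid Wright–Fisher
simulator: each offspring draws two parents (fitness-weighted when a
selected site segregates), each gamete recombines with Poisson(rL)
crossovers at uniform breakpoints and mutates with Poisson(μL) new
infinite-sites mutations on integer positions (collisions redrawn,
positions never reused). Selection is additive with fitnesses 1, 1+s/2,
1+s. The demography is: ancestral burn-in; split into a wild population
and a domestic lineage; the domestic lineage later splits into three
breeds; terminal samples (5 per breed, 4 wild by default) are drawn
without replacement. A hard sweep introduces a new mutation into one
haplotype of the focal breed at the breed split and can be conditioned on
fixation: lost attempts terminate early and the epoch is resimulated from
the saved pre-sweep state, up to a retry cap. Everything is
byte-deterministic under the master seed, which the test suite checks
file-by-file. The generation loop is compiled code, as is the EHH walk —
both are the hot paths of the package.

Sequencing is emulated per sample per site: total depth ~ Poisson(λ = 29,
the cohort's published mean depth), reads split between the two haplotype
alleles binomially, and each read miscalled to a uniformly random other
base with probability ε = 0.001, so a read crosses to the other listed
allele with probability ε/3 and is otherwise dropped. The callable mask
punches exponentially sized low-depth holes (mean 2 kb, ~10% of the
genome) so callable-length normalization is actually exercised. Gene
models are non-overlapping one-to-three-exon genes with stop-free CDS and
a terminal stop codon, written into the reference on either strand; when
a sweep is configured the first gene is centred on the selected site so
the sweep region always contains a gene. Synthetic short indels (1–8 bp,
with quality and homopolymer metadata) give the indel filters real work.

**Rate calibration.** Desk-scale simulation rescales the population:
N = 100–200 stands in for a much larger effective size. Mutation is set
to μ = 5 × 10⁻⁷/bp/generation so that θ = 4Nμ ≈ 2–4 × 10⁻⁴/bp, giving
realistic SNP densities for the window statistics. Recombination is *not*
scaled by the same factor: r = 4 × 10⁻⁸/bp/generation is chosen so that a
conditioned s = 0.1 sweep (fixation time ≈ 250 generations at N = 200)
drags a footprint of roughly 1/(r·T) ≈ 100 kb — the same
footprint-to-window ratio a real livestock sweep shows at 100-kb windows.
Scaling r consistently with μ would shrink footprints to a few kb and
make every window-level scan vacuous. The default selected site is
centred in its 100-kb window so the footprint is not split across a
window boundary. These were fixed a priori from the arithmetic above, not
fitted to test outcomes.

**What the simulator does not emulate.** A single chromosome (the Z
statistics therefore standardize over one chromosome's windows); no gene
conversion, no mutation-rate or recombination-rate heterogeneity, no
background selection, no migration between breeds, no mapping or calling
artefacts beyond Poisson depth and uniform base error, and no reference
bias. Passing tests show the *rules* are implemented correctly and that
the statistics respond to planted signals in the expected direction; they
do not certify performance on real resequencing data.

## Power at desk scale: a known limitation

The strict TAG rule (ZFst ≥ 4 AND top-1% XP-EHH) has essentially no power
at the 5-Mb, 50-window scale the simulations use, and this is a property
of the scale, not of the implementation. Two effects compound. First,
with n = 50 windows the largest achievable |z| for a single outlier is
(n−1)/√n ≈ 6.9 in the degenerate limit, but background windows are not
tight: at the linkage scale that makes a sweep footprint fill a window,
each window is essentially one genealogy, so window-level Fst has
genealogical variance comparable to the sweep effect itself. Second, an
s = 0.1 additive sweep needs ~250 generations to fix at N = 200 — about
0.6 coalescent units — so the focal breed is strongly drifted genome-wide
(background Fst ≈ 0.35–0.5, long haplotypes everywhere), which compresses
both the ZFst and the XP-EHH contrast. Across a 3 × 3 grid of (μ, r)
calibrations the swept window's ZFst never exceeded ~3. A 2.5-Gb genome
scanned in ~25,000 windows is what makes z ≥ 4 outliers observable; a
5-Mb replicate cannot reproduce that tail. The acceptance suite therefore
measures recovery power honestly at the stated conditions and reports the
companion effect-direction checks (sweep-window diversity depression,
elevated XP-EHH near the selected site), which do hold.

## Problem sizes used by the tests

Unit tests run on hand-built tables and small cohorts (N = 30–100,
L = 0.1–1 Mb). The sweep-recovery study uses 20 replicates at N = 200,
L = 5 Mb plus 3 neutral replicates; the desert-rule check uses one
neutral N = 100, L = 5 Mb genome and 1,000 randomized joining instances;
the equilibrium-diversity check uses 20 seeds at N = 100, L = 1 Mb with a
6N-generation burn-in (bringing expected diversity to within 5% of 4Nμ).
These sizes are the package's chosen trade-off between stochastic
stability and a test suite that runs in minutes.

## Known limitations

* The variant table stores per-site genotype and depth matrices in list
  columns — transparent and convenient at 10⁴–10⁵ sites, not engineered
  for 2 × 10⁷-site cohorts.
* Multi-allelic sites are carried through IO and QC intact but are
  excluded from MAF, Hp, Fst and EHH, which are defined on biallelic
  sites; they are never split into pseudo-biallelic records because that
  would distort the read-count semantics of Hp.
* XP-EHH uses physical distance; supplying a genetic map is not
  implemented.
* The CNV merge operates on externally called CNV intervals; calling CNVs
  from depth is out of scope.
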