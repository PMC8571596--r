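---
title: "sweepscan: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweepscan: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

`sweepscan` targets a common comparative-resequencing design: a small case
population with a distinctive phenotype (here labelled `HG`) against a
larger control panel of related animals (`CG`), scanned genome-wide for
regions where the case group shows the signature of a recent selective
sweep — locally reduced nucleotide diversity together with elevated
between-group differentiation — and for copy-number variants whose dosage
distribution separates the groups.

## SNP window statistics

All coordinates are 0-based half-open internally; conversion to/from the
1-based conventions of VCF and GFF3 happens only at the I/O boundary.

**Windows.** The tiling is `window_bp` = 40 kb stepped by `step_bp` = 20 kb,
the classic sliding-chromosome-window configuration for livestock scans.
Windows extending past the chromosome end are dropped unless a truncated
terminal window is requested. Statistics are ranked genome-wide (pooled
over chromosomes), matching how published cutoffs are quoted.

**Nucleotide diversity.** Per site, with `n` non-missing chromosomes in the
group and `c` alt alleles, the unbiased pairwise estimator
$\pi_s = 2c(n-c)/(n(n-1))$; the window value is $\sum_s \pi_s / L$ with $L$
the window length in bp. Sites with $n < 2$ contribute nothing. Dividing by
the full window length (rather than the number of genotyped sites) is the
convention of window-based sweep scans; per-informative-site normalization
is available via `denominator = "sites"` because the two conventions differ
exactly by SNP density and either may be wanted for comparison with other
tools.

**Hudson F~ST~.** Per informative site (both groups with $n \ge 2$),
$N_s = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$,
$D_s = p_1(1-p_2) + p_2(1-p_1)$, and the window estimate is
$\sum N_s / \sum D_s$ over sites with $D_s > 0$ — the ratio-of-averages
form, which is the low-bias choice for windowed Hudson estimates. The
average-of-ratios variant sits behind `mode = "average_of_ratios"` for
comparison only. Windows with no informative site are `NA` and never enter
percentile ranking. Negative window estimates are reported as-is so that
empirical ranks are unbiased; clamping at zero is purely cosmetic and left
to display code.

**π ratio.** $\pi_{CG}/\pi_{HG}$; a monomorphic case group with a variable
control group gives $+\infty$, which deliberately ranks above every finite
value (it is the strongest possible diversity-loss signal); $0/0$ is
undefined and excluded.

**Outlier selection.** The cutoff is the type-7 (linear-interpolation)
quantile of the defined finite values and selection is *strictly* beyond
the cutoff, mirroring how scans report "top 1 % (F~ST~ > c)". The choice of
quantile rule matters at the margin — published window counts for three
statistics over one window set are generally not consistent with any single
exact rule, so the convention here is fixed and documented rather than
inferred. Candidates are windows surviving all three selections (exact
coordinate identity). Windows with fewer than `min_snps` (default 1)
informative SNPs are excluded from ranking: an empty window has π = 0 for
trivial reasons and would otherwise flood the lower diversity tail.

## CNV statistics

**Reliability filter.** A region passes when the variant-state frequency
(share of individuals whose *rounded* copy number differs from the
reference state 2, folded at 0.5) exceeds `maf_min` = 0.05 strictly, and
the mean silhouette of the rounded-CN classes (absolute-difference distance
on the raw values, averaged over members of classes of size ≥ 2) is at
least `silhouette_min`. No published threshold exists for the silhouette;
the default 0.7 is the conventional "reasonable structure" line for
silhouette scores and is deliberately config-only. Rounding uses R's
round-half-to-even; raw values are used for variances and t-tests.

**V~ST~.**
$$V_{ST} = \frac{V_{total} - (V_{pop1} N_{pop1} + V_{pop2} N_{pop2})/N_{total}}{V_{total}}$$
with *population* variances (denominator $N$). This is a deliberate design
decision: with denominator-$N$ variances the weighted within-group term is
exactly the within component of the law of total variance, so
$0 \le V_{ST} \le 1$ holds unconditionally — the analytic claim the
acceptance sweep checks. With sample ($N-1$) variances the statistic can
leave $[0,1]$. A region with zero total variance scores 0.

**CNV-level F~ST~.** Copy numbers carry no allele phase, so no canonical
allele frequency exists for Hudson's estimator. The implementation
dichotomizes each region into variant carriers (rounded CN ≠ 2) versus
reference individuals and applies the Hudson form to carrier frequencies
with individual-level sample sizes. This is one defensible reading among
several; it is isolated in `cnv_fst()` so an alternative definition is a
one-function change.

**t-test.** Welch's two-sided unequal-variance test on raw copy numbers,
with explicit degenerate conventions: both groups constant and equal means
→ p = 1; both constant with different means → p = 0 and a `degenerate`
flag (the data are then two distinct point masses and no finite t exists).

**Selection.** Upper-tail percentile selection is applied independently to
V~ST~ and F~ST~ and intersected. The default fraction is 0.01 ("top 1 %");
the stricter per-mille reading used in some reports is just
`fraction = 0.001`.

## Annotation and enrichment

Overlap assigns a gene to an interval when their half-open spans share at
least one base; flank assigns non-overlapping genes whose nearest-edge gap
is at most `flank_bp` per side (default 2 Mb, the usual reach quoted for
regulatory effects of CNVs; read as ±2 Mb from the interval's edges, not a
2-Mb total span). Both queries run on GenomicRanges interval trees and are
checked against a brute-force all-pairs oracle in the tests. Strand is
ignored.

Enrichment is a generic gene-set over-representation analysis: one-sided
hypergeometric p-value per term with at least one candidate hit, BH
adjustment across tested terms, significance at p < 0.05 and q ≤ 0.05. The
universe defaults to all genes in the annotation file (not the union of the
gene sets), because the annotation defines what could have been a
candidate. Pathway-database content is data, not method: collections are
supplied as GMT. Note that BH adjustment is *not* idempotent on arbitrary
monotone inputs (re-adjusting a strictly increasing q vector inflates it);
only flat or saturated q vectors are fixed points, and the tests assert
exactly that.

## The simulator: what it emulates and what it does not

`sim_config()` states the simulated world once:

| parameter | default | why |
|---|---|---|
| `n_hg`, `n_cg` | 20, 52 | the case/control cohort shape being emulated |
| `chrom_length` | 10 Mb | ~500 windows: enough for stable 1 % tails, minutes of CPU |
| `snp_density` | 1/kb | realistic post-calling density; ~40 SNPs per window |
| `f_bg` | 0.02 | between-breed background F_ST typical of livestock panels |
| `sweep_windows` | 5 spans of 40 kb on the 20-kb grid | one window each, spaced 2 Mb apart |
| `sweep_strength` | 0.95 | a strong, near-complete sweep |
| `n_cnv`, `n_diff_cnv` | 200, 5 | desk-scale analogue of a genome-wide CNV set |
| `neutral_cn_states` | {1,2,3} at (.15,.70,.15) | common biallelic del/dup polymorphism around CN 2 |
| `diff_hg_states` / `diff_cg_states` | {0,1} vs {2,3} | strongly differentiated deletion |
| `cn_noise_sd` | 0.1 | read-depth estimation noise around integer states |

Neutral SNPs follow the Balding–Nichols model: ancestral frequency
$p \sim U(0.05, 0.95)$, group frequencies Beta-distributed with mean $p$
and variance $p(1-p)F$, dosages Binomial(2, ·). Inside a sweep span the
case-group frequency is pulled toward its nearest fixation point,
$p' = (1-s)\,p_{draw} + s\,\mathrm{round}(p_{draw})$, so strength 1 makes
the case group monomorphic. Sites with no alt allele anywhere are dropped,
as a variant caller would.

This design is desk-scale and dependency-free, and it induces exactly the
rank structure the scan detects (reduced π(HG), elevated ratio and F~ST~ in
swept windows; high V~ST~/F~ST~ in differentiated CNV regions). It does
**not** model linkage within windows (sites are independent), recombination,
demographic history, linked selection, or read-depth profiles of real CNV
callers. A green recovery test therefore establishes that the statistics
and the selection logic are implemented correctly — not that the pipeline's
power on real, linked, demographically structured data matches the
simulation.

## Numerical choices and degenerate inputs

- Quantile cutoffs: type 7, fixed so cutoffs are reproducible across runs.
- `+Inf` π ratios are always selected in the upper tail; `NA` statistics
  never rank.
- V~ST~ with $V_{total} = 0$ is 0; the CNV F~ST~ with zero denominator is
  `NA` (excluded).
- All result tables are written at 6 significant digits with a fixed
  column order; two runs on identical inputs are byte-identical (the run
  manifest records config, input MD5 checksums, cutoffs and the package
  version).
- Genotypes are strictly diploid; other ploidies are rejected rather than
  coerced, and half-missing genotypes are treated as missing.

## Known limitations

- Two populations only; the V~ST~ decomposition and the CLI assume the
  `HG`/`CG` design.
- The CNV F~ST~ definition is one defensible dichotomization (see above).
- Haplotype statistics (iHS, XP-EHH), Tajima's D and per-site F~ST~ output
  are out of scope.
- Chromosome lengths are taken from config when given, otherwise inferred
  from the last SNP position rounded up to the step grid — terminal
  windows beyond the last SNP are then absent by construction.
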