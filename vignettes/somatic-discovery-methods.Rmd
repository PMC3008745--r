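---
title: "Methods: somatic variant discovery in tumor/normal exome pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic variant discovery in tumor/normal exome pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticExome)
```

This vignette is the package's own account of the statistical procedure it
implements and of the design choices that were genuinely open: what each
stage assumes, which parameters matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical conventions that make results reproducible to the byte.

## The discovery procedure

### High-confidence calling

The caller works on per-site pileups: read counts for the reference and one
alternative base, split by strand, with the best variant-supporting quality
and the local homopolymer length. A site is called when its coverage
strictly exceeds `min_coverage = 10` reads and at least one of two evidence
branches holds:

* **strand-count branch** — at least `min_variant_reads = 3`
  variant-supporting reads including at least one forward and one reverse
  read. Strand balance guards against the strand-biased artifacts typical
  of single-read library chemistry.
* **quality branch** — the best variant-supporting quality strictly above
  20 (phred-like), raised to 30 when a homopolymer of 5 or more bases is at
  or immediately adjacent to the site, homopolymer runs being the dominant
  error mode of flow-cycle sequencing.

The two branches are combined with OR; the strand requirement belongs to
the count branch only. Both quality comparisons are strict (`>`), as is the
coverage comparison, and the boundaries are exercised in the tests. Whether
the quality branch also needs a minimum number of variant reads is not
fixed by the rule text; the package requires at least one
(`quality_min_variant_reads = 1`, configurable), since a quality value must
be attached to an observed read.

### Bimodal somatic/germline classification

Somatic status is decided by a two-stringency design. Tumor calls must
reach a variant allele fraction of at least `tumor_min_vaf = 0.15` — a
fraction low enough to tolerate normal-cell admixture at the targeted
dissection purity of above 80%, where a clonal heterozygous somatic variant
is expected at fraction $0.5 \times 0.8 = 0.4$. The matched normal is then
read permissively:

| normal evidence | status |
|---|---|
| coverage $< 5$ | undetermined (no conclusion drawn) |
| coverage $\ge 5$, $\ge 1$ variant read | germline |
| coverage $\ge 5$, $0$ variant reads | somatic |

The 5-fold cutoff is what bounds the germline false-negative rate: a
heterozygous variant escapes detection entirely with probability
$(1-f)^{c}$, which at $f = 0.5$, $c = 5$ is `r benign_false_negative_rate(5, 0.5)`,
inside a 10% budget. `benign_false_negative_rate()` exposes that closed
form. One sentence of the original rule text ("for coverages above 30-fold
one variant read was accepted") is redundant under the plain reading —
one read already suffices from 5-fold upward — so the single rule is
implemented and the alternative (a proportional threshold between 5- and
30-fold) is left as a documented hook rather than guessed at. Sites absent
from the normal pileup are treated as coverage zero, hence undetermined,
never somatic. The classifier is deliberately asymmetric: it minimizes
false somatic calls and does not attempt zygosity determination.

### Consequence annotation

Variants are mapped to *all* overlapping transcript models; a locus under
two transcripts yields two annotations (for example an amino-acid change in
one transcript that lies in the UTR of another). Codons are extracted
strand-aware from the spliced CDS, translated with the standard genetic
code, and classified as synonymous, missense, nonsense, start/stop loss;
non-coding exonic positions become 5'/3' UTR, intronic positions within
`splice_window = 2` bases of an exon boundary become splice sites
(window unstated in the field description; two bases is the canonical
donor/acceptor dinucleotide and is configurable), and positions under no
transcript are intergenic, or miRNA when inside a miRNA interval.

Interchange files are 1-based and inclusive; internal arithmetic uses
transcript-ordered base indices with the conversion confined to the
reader/writer layer. When one consequence per variant is needed the fixed
severity order is: nonsense > start_lost > stop_lost > missense >
splice_site > utr5 > utr3 > synonymous > mirna > intronic > intergenic.
Protein position is `ceiling(CDS offset / 3)`.

### Prioritization cascade

Stages apply in a fixed order, each a pure set operation recorded with its
surviving count: the consequence-severity gate (protein-affecting classes
listed above), the population-frequency filter (kept when unreported or
frequency $< 0.01$), and the functional filter (damaging by at least one of
two predictors, `mode = "any"`; requiring both is available since the rule
text does not fix it). Conservation ($\ge 2.0$, inclusive per "greater or
equal"; 2.0 is the 0.975 quantile of the score background), expression
(genewise mean across samples at or above the first quartile, inclusive —
the inclusive boundary is a package decision, configurable), and
category/catalogue flags are attached for reporting by default and become
additional filters with `extended = TRUE`, so both readings of the workflow
(annotation versus successive narrowing) are reproducible. Missing
annotations fail closed — the variant is dropped by that stage with a
warning — consistent with the design goal of minimizing false positives.
Quantiles use the linear-interpolation definition (`stats::quantile`
type 7), so `conservation_threshold(1:1000)` is exactly 975.025.

### Read-depth copy number

Counts in fixed genomic bins (50 kb by default) are scaled to equal totals
(read frequencies), converted to $\log_2$ tumor/normal ratios, masked where
either count is zero, and median-centered so the profile median is exactly
zero. Segmentation is recursive binary splitting with a circular-style
candidate set: within a window of length $n$ the statistic for a candidate
segment $(i..j)$ of length $k$ is

$$ T = \frac{|\bar x_{in} - \bar x_{out}|}{\sqrt{1/k + 1/(n-k)}}, $$

maximized over all pairs with `min_len = 3` $\le k \le n -$ `min_len`
(pairs touching the window edge reduce to plain two-way splits). The
maximum is referred to its own permutation distribution (`B = 1000`
permutations, accepted when $p < \alpha = 0.01$); the pairwise candidate
set matters because a segment in the interior of a window cannot be
separated by any single split, and comparing a single-split statistic to a
permutation distribution dominated by short extreme runs loses the true
changepoint. The permutation loop stops early as soon as the exceedance
count rules out $p < \alpha$ — a pure speed-up; the accept/reject decision
is identical to the full loop. Gain/loss states use the two-standard-
deviation rule with the SD estimated robustly from bin-level residuals
around segment means (MAD $\times$ 1.4826); which spread the original rule
meant is unstated, and the MAD of residuals is the choice least influenced
by the aberrations being called (`sd_method = "sd"` is available).
Permutations draw from R's global RNG; callers seed for reproducibility,
and the pipeline derives a dedicated substream from its master seed.

### Concordance evaluation

Array-style genotypes act as the standard. Positions qualify when the array
quality p-value is strictly below 0.1 and sequencing coverage strictly
exceeds 3. Sequencing genotypes come from allele-fraction thresholds
(ref-hom below 0.15, alt-hom above 0.85, het between — the original
diploid caller is undescribed, so these mirror the tumor VAF convention and
are configurable). The report carries the full confusion matrix, false
positive rate (array-reference positions called variant), false negative
rate (array-variant positions called reference), diploid accuracy, haploid
concordance (het recoded to hom-alt on both sides, hence never below
diploid accuracy), and a coverage-stratified breakdown.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every pipeline property is demonstrated.

Per site, coverage is Poisson around the configured mean (mean coverages
are all the study design fixes; Poisson is the simplest overdispersion-free
choice and is isolated in one function). Germline heterozygous variants
occur at `heterozygosity_rate`, homozygous alternative genotypes at
`hom_alt_rate`, somatic variants at `somatic_rate` — planted only on a
germline-reference background, so no site is both. Variant-supporting reads
are binomial with allele fraction 0.5 (het) or 1 (hom), scaled by
`tumor_purity = 0.8` for somatic sites (the >80% tumor-cell dissection
target); strands are fair coin flips; reference reads flip to the site's
alternative base with probability `error_rate` (the original error model is
unstated — this binomial stand-in is a package choice, and flips to the two
other bases or back-flips of variant reads are not modelled since records
are biallelic by design). Per-read qualities come from a two-point mixture
(15/35, P(high) = 0.9) so both quality thresholds are exercised;
homopolymer lengths are geometric-tailed with P(length $\ge 5$) $\approx$
0.05. The MSI-like preset plants somatic variants at $8 \times 10^{-4}$
per site and the MSS-like preset at $10^{-4}$ — an 8:1 contrast matching
the observed fold difference in non-synonymous somatic burden between the
phenotypes.

Gene models are built constructively so their contract cannot fail by
sampling: every CDS starts with ATG, ends with a stop, has length divisible
by 3 and no internal stop; introns carry GT..AG; strands alternate; one
locus carries a second transcript whose CDS is a small ORF inside the first
transcript's 3' UTR, giving the CDS-in-one/UTR-in-the-other case. The
generator keeps a per-base bookkeeping map from which truth consequences
are computed by direct codon arithmetic — a second, independent path that
the sequence-extraction annotator is tested against.

Annotation side-tables are drawn consistently with the truth flags:
common-polymorphism entries above 0.01 exactly for truth-frequent sites
(plus sub-0.01 entries for a fifth of the rest), at least one damaging flag
for truth-damaging sites, conservation scores from a normal background
whose 0.975 quantile sits at 2.0 with truth-conserved sites at or above
2.0, and per-gene expression means separated around a nominal threshold
with `expressed_fraction = 0.75` so the truth flag coincides with the
pipeline's first-quartile rule. CNV bins are Poisson (normal around
`cnv_base_rate = 500` reads per bin; tumor rate multiplied by
$2^{\text{effect}}$ inside planted segments). Array genotypes copy the
truth with Beta(1, 19) quality p-values, so most but not all positions pass
the 0.1 filter.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: alignment and mapping artifacts, indels,
GC-content and capture-efficiency bias, overdispersed coverage, subclonal
tumor populations, strand-biased errors, and correlated errors at
homopolymers (homopolymer length only gates the quality threshold). The
generator demonstrates that the decision rules are implemented correctly
and behave as designed under their own assumptions, not that those
assumptions hold for any particular instrument.

## Reproducibility and problem sizes

Every generator accepts a seed and restores the caller's RNG state; each
operation derives its own substream so results do not depend on call order.
`run_all()` threads one master seed through simulation, segmentation
permutations and array generation, and writes no timestamps, so rerunning a
configuration reproduces the artifact directory byte for byte (asserted in
the tests by hashing every artifact).

The shipped test suite demonstrates the properties at desk scale, chosen
so the full suite stays under a minute: binomial sampling checks at
$10^5$ sites, the 8:1 contrast at $1.5 \times 10^5$ sites per patient,
concordance at $2$–$3 \times 10^4$ sites, segment recovery and type-I
control on 150-bin profiles with 100 replicates at 200 permutations per
test (the package default stays at 1000), and the end-to-end pipeline on a
3,000-site genome of 12 genes. The acceptance script uses $10^5$ sites.

## Known limitations

* One alternative allele per site; multi-allelic sites and indels are out
  of scope by design.
* The quality branch sees only the per-site maximum variant quality, not
  read-level qualities.
* Copy-number states are relative (gain/loss versus the profile's own
  residual spread); no purity/ploidy correction, GC correction or
  allele-specific copy number.
* The severity ranking of miRNA variants (between synonymous and intronic)
  is a package convention; the field ranks regulatory consequences
  inconsistently.
* `expressed_fraction` away from 0.75 decouples the generator's truth flag
  from the pipeline's fixed first-quartile rule; the default keeps them
  aligned and the divergence is intentional parameter space, not a bug.
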