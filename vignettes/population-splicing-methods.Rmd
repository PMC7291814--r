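---
title: "Methods: population-scale alternative splicing with PopSplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale alternative splicing with PopSplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PopSplice)
```

# The analysis

PopSplice analyses alternative splicing (AS) in a replicated population
expression study: many unrelated genotypes, each grown as clonal
replicates in a row--column field or greenhouse layout, with per-sample
isoform FPKM quantifications against a shared merged transcriptome, a SNP
panel for the same individuals, and per-isoform protein-domain and miRNA
target-site annotations. The pipeline covers five analysis layers:

1. **Event classification.** All isoform pairs of a gene are compared and
   five event types are called: retained intron (RI), skipped exon (SE),
   alternative 3' acceptor (A3), alternative 5' donor (A5) and alternative
   terminal exon (AE). Donor and acceptor are strand-aware labels: the
   donor is the intron boundary nearer the transcript 5' end. Events are
   deduplicated by (type, interval, junction set), so an event supported
   by several isoform pairs is counted once.
2. **Support filters.** A junction must be spanned by at least 2 reads in
   some sample; a retained intron must have a median per-base depth of at
   least 2 in some sample. RI events are exempt from the junction rule
   because the retaining isoform has no junction at the retained intron --
   the coverage rule is their support criterion.
3. **Expression filtering and population statistics.** An isoform is
   present in an individual when its FPKM is at least 3 in at least 2
   replicates; isoforms present in fewer than 3 individuals are removed.
   Major-isoform frequency counts, per gene, the individuals in which each
   isoform is the most expressed (replicate-mean FPKM, ties to the
   lexicographically smallest transcript id).
4. **Heritability.** Per trait (isoform FPKM), the mixed model
   `y = intercept + experiment + genotype + row + column + error` is
   fitted by REML, with row and column nested in experiment and the
   genotype, row and column terms random. Broad-sense heritability is
   `H2 = s2_g / (s2_g + s2_r + s2_c + s2_e)`. Significance comes from a
   permutation null: genotype labels are shuffled and the model refitted;
   a trait is heritable when its H2 strictly exceeds the 99th percentile
   of the null.
5. **QTL mapping and functional consequences.** SNPs pass five filters
   (HWE chi-square p >= 0.01, MAF >= 0.05, mean depth >= 8, mean GQ >= 20,
   missingness <= 75%). Isoform expression (iso-eQTL) and splice-junction
   usage (sQTL; junction reads over gene reads, replicate-averaged) are
   scanned against all SNPs with per-pair simple linear regression at a 5%
   empirical FDR, and associations are cis when the SNP lies within 1 Mb
   of the trait's span. Protein domains and miRNA sites are compared
   between each alternative isoform and a reference isoform (longest CDS,
   or most expressed), and gains/losses are attributed to the AS events
   that overlap them and distinguish the two isoforms.

# Modelling decisions

Several points are under-determined by the analysis conventions of this
field; the package fixes them as follows.

**Permutation unit.** The genotype-label permutation shuffles labels at
the *sample* level while trait values and row/column/experiment
assignments stay with the physical samples. In a clonally replicated
design each individual is one genotype; moving replicate groups intact
would permute nothing (the grouping would be preserved, only renamed), so
the sample-level shuffle is the only null-generating reading. Under the
null hypothesis of zero genotypic variance, samples are exchangeable
across genotype labels, which is exactly what the test requires.

**REML engines.** The full model is fitted with `lme4::lmer` (REML).
When the design reduces to genotype-only (no varying row, column or
experiment), an exact profiled one-way REML is used instead: the
likelihood is profiled down to a single variance ratio and optimized by
Brent search. On balanced one-way data this optimum coincides with the
ANOVA method-of-moments estimator truncated at zero, which the tests use
as an independent oracle. Negative variance estimates cannot occur (both
optimizers constrain variances to be non-negative); a constant trait or a
single genotype yields all-zero components with a degeneracy flag, and
zero total variance gives H2 = 0 by convention.

**Permutation nulls: per-trait vs pooled.** Refitting thousands of
permutations per trait is the statistically cleanest null but expensive;
`estimateHeritability()` therefore also offers a pooled mode that spreads
the permutation budget across traits and shares one threshold. The
pipeline default is the pooled mode with a budget of 1000 fits; 10000
per-trait permutations give the most stable 99th percentiles and are the
recommended reporting configuration when runtime allows. Empirical
p-values use the `(1 + #null >= observed) / (1 + #null)` convention.

**Empirical FDR.** The scan permutes the individuals of the whole
phenotype matrix jointly (preserving trait-trait correlation), and
estimates FDR at each candidate p-value threshold as the mean null
exceedance count -- plus a one-count pseudo-observation, the same
convention as permutation p-values -- over the observed count, monotonized
in the threshold. The pseudo-count matters: with few permutations the raw
ratio occasionally dips to zero by chance and an uncorrected estimator
systematically over-reports. The smallest reportable FDR at rank r is
`1/(nPerm * r)`, so single very strong hits need `nPerm >= 20` at a 5%
target; Benjamini--Hochberg is available as an alternative mode.
Missing genotypes are mean-imputed per SNP for the matrix scan.

**A5/A3 versus AE.** Junction pairs sharing one splice site also arise
between alternative terminal exons (both terminal junctions splice into
the same acceptor of the gene body). The classifier separates the cases
by requiring, for A5/A3, that the exons flanking the differing boundary
overlap each other; terminal-exon pairs must instead be mutually
non-overlapping and share at least one body junction, with the exons next
to the terminal exons anchored in the partner isoform. This strictness is
what makes event recovery on constructed transcriptomes exact.

**Feature identity.** Domains are compared as accession sets per isoform
(multiple copies collapse; coordinates are used only for event
attribution). miRNA sites are identified by (miRNA id, genomic interval),
because the same miRNA can hit isoform-specific regions, and genomic
anchoring makes the comparison between isoforms well-defined: the same
site reached through different transcript coordinates in two isoforms is
one site. Attribution of a change to an event requires both a >= 1 bp
overlap between the event interval and the feature's genomic projection
and that the event separates the alternative isoform from the reference
(one in its inclusion set, the other in its exclusion set) -- overlap
alone over-attributes events shared by both isoforms.

**Coordinates.** All external coordinates are 1-based inclusive (GTF
convention). Peptide positions map to CDS nucleotides as
`[3(p-1)+1, 3p]` and are projected through the CDS pieces strand-aware,
splitting at introns; projections conserve length exactly and invert
(`genomicToTranscript()`) for round-trip checking.

# The synthetic study generator

`simulateStudy()` emits a complete, internally consistent study --
transcriptome GTF, genotype VCF, FPKM matrix with its row--column sample
design, junction and gene read counts, RI coverage, domain and miRNA
tables -- with the full ground truth recorded. Its defaults define the
desk-scale preset used throughout the tests: 50 individuals x 3
replicates, 200 genes, 500 SNPs, on 5 chromosomes.

* **Transcriptomes** are built by explicit exon-structure edits of a base
  isoform (merge an intron, drop an internal exon, shift a splice site by
  15--40 nt, replace the first exon by a non-overlapping upstream exon).
  The exon *and junction* footprints of the edits of one gene are kept
  disjoint, which guarantees that the planted list is the complete event
  set of the gene -- the property the classifier-recovery tests rely on.
  The event-type mix (RI 30%, A3 24%, A5 20%, AE 15%, SE 11%) follows the
  ordering reported for plant transcriptomes, retained introns most
  common and skipped exons least.
* **Genotypes** are biallelic SNPs at Hardy--Weinberg proportions with
  MAF uniform on [0.05, 0.5], Poisson depth and Gaussian genotype
  quality; 10% of SNPs deliberately fail one of the five filters (low
  MAF, excess homozygosity, low depth, low GQ, high missingness) and are
  labelled in the ground truth.
* **Expression** is log-normal FPKM: an intercept plus experiment,
  genotype (per-individual), row, column, planted-QTL and residual terms
  on the log scale, exponentiated. Log-normality gives the positive,
  right-skewed marginals of real FPKM; because the heritability model is
  fitted on FPKM directly, estimates on these data are attenuated
  relative to the log-scale truth, which mirrors the same attenuation on
  real data. For estimator *calibration* the package therefore provides
  `simulateTraits()`, which draws Gaussian traits straight from the
  variance-component model; recovery and type-I-error checks run there.
  Default variances are `s2_r = s2_c = 0.25`, `s2_e = 1`, and `s2_g` is
  zero for 30% of isoforms and Gamma(2, 0.5) otherwise, spreading true
  H2 over [0, ~0.8].
* **Read counts** are Poisson gene totals with binomial junction shares
  tied to the carrier isoforms' FPKM (expected usage = 0.8 x the carrier
  share), the simplest count model consistent with the usage statistic;
  planted sQTL shift the share on the logit scale.
* **Annotations** place a domain or miRNA site on exactly one side of a
  planted event (guaranteeing a gain or loss with known attribution) plus
  isoform-invariant controls shared by all coding isoforms.

What the generator does **not** emulate: read-level artifacts (mapping
bias, duplicates), linkage disequilibrium between SNPs, population
structure or kinship, batch effects beyond the row--column--experiment
design, and assembly errors in the transcriptome. Passing tests therefore
demonstrate the correctness of the algorithms under the stated model, not
robustness to those real-data complications.

# Problem sizes and numerical choices

The test suite exercises the estimators at sizes chosen to make the
Monte-Carlo noise small relative to the tolerances asserted: 500 random
two-isoform genes against the brute-force classifier oracle; 200 traits
per heritability level at 100 genotypes x 3 replicates (mean recovery
within 0.05); 500 null traits with 1000-permutation thresholds for the
type-I check; 50 scan replicates at n = 200 for QTL power and realized
FDR. The end-to-end pipeline runs the desk-scale preset and is
byte-identical across reruns with the same seed: every random stage draws
from a seed derived from the single root seed, and output tables carry a
version/seed/threshold header but no timestamps.

Ties are always broken lexicographically by identifier (reference
isoform selection, major-isoform crediting), which makes every reported
table deterministic. Quantiles of permutation nulls use R's default
(type 7) definition.

# Known limitations

* The AE category covers alternative first and last exons jointly; the
  generator plants only alternative *first* exons, and mutually exclusive
  exon pairs are classified as two independent SE events.
* Junction usage is undefined for an individual when no replicate has
  gene reads; the pipeline mean-imputes such traits before the sQTL scan.
* Heritability on FPKM (rather than log FPKM) follows the convention of
  fitting abundance directly; users wanting scale-stable estimates can
  pass transformed matrices to `estimateHeritability()` unchanged.
* The scan fits one SNP at a time with no kinship or covariate
  correction; with population structure the empirical FDR is calibrated
  against the permuted null, not against confounding.
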