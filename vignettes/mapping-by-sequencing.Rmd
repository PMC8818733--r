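---
title: "Mapping EMS-induced mutations by bulked segregant sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping EMS-induced mutations by bulked segregant sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The mapping problem

Forward-genetics screens of EMS-mutagenized plant collections routinely
isolate recessive mutants whose causal lesion must then be located among
hundreds of thousands of SNPs. The standard mapping-by-sequencing design for
a recessive mutation works as follows. The mutant line is backcrossed to its
background genotype (twice, typically) and selfed, producing a family that
segregates 1:2:1 at the causal locus and therefore 3:1 phenotypically. Two
DNA bulks are sequenced: a mutant bulk pooled from homozygous-mutant plants
(often selected for the most extreme phenotype) and a wild-type bulk pooled
from phenotypically normal plants, which are a mixture of homozygous
reference and heterozygous carriers. At the causal site and everything
tightly linked to it, the mutant bulk is fixed for the variant allele
(alternate allele frequency, AF, of 1) while the WT bulk sits well below 0.5;
everywhere else both bulks drift around 0.5 (for segregating induced
mutations) or 1 (for shared background differences against the reference
assembly). A filter cascade on the two-bulk VCF -- allele frequencies, EMS
canonicality, call quality, and finally variant impact on gene models --
typically leaves a single protein-altering candidate, which is then confirmed
by co-segregation in a few hundred genotyped plants.

`bsamap` implements this entire analysis as reusable, tested components, plus
a forward-genetics simulator that generates inputs with exactly the genetic
structure the analysis assumes. Because raw reads for such studies are often
not deposited, the simulator is the package's source of test data: every
downstream stage is validated against known ground truth.

## The simulator

### Genomes and gene models

`make_toy_genome()` builds random chromosomes and packs non-overlapping
multi-exon gene models onto both strands. Each model carries UTR margins and
a complete ORF (ATG start, no internal stop, terminal stop, coding length
divisible by three) written into the chromosome sequence, so that protein
effects of coding SNPs are well defined. FASTA and GFF3 round trips are
exact; non-ATG starts are rejected at GFF3 load.

### Mutations

`mutagenize_ems()` mutates every G or C base independently with a given rate,
emitting only canonical EMS transitions (G>A or C>T as written on the
reference strand); the site count is therefore binomial in the G+C content.
`add_background_variants()` emits variants homozygous in both founders --
pre-existing differences from the reference assembly -- which surface at AF 1
in both bulks and can also be removed with a blacklist shared across mutant
families. `plant_missense()` rewrites one codon of a chosen gene to proline
(CCA) so that a single canonical transition at its second base produces a
proline-to-leucine missense, giving the simulation a realistic causal lesion
with a known amino-acid change.

### Pedigrees

`cross()` models meiosis with Poisson-distributed crossovers per chromosome
(mean 1 by default), uniform breakpoints and no interference -- the simplest
recombination model that produces the linkage structure the analysis relies
on. `run_pedigree()` chains crosses from a scheme string: `"BC2S1"` (default)
backcrosses a heterozygous carrier to the recurrent parent twice and selfs
once. The scheme is configurable because published descriptions of this
design sometimes disagree between methods and results sections about the
number of backcrosses; both `"BC1S1"` and `"BC2S1"` segregate identically at
the causal locus and differ only in how many unlinked passenger mutations
remain (each backcross halves the retention probability of an unlinked
heterozygous passenger, giving 1/4 after two backcrosses).

### Phenotypes

The phenotype model is deterministically recessive: a plant is mutant if and
only if it is homozygous at the causal site. Partial penetrance is not
modelled, matching the 100% co-segregation the design is meant to confirm.
Mutant plants draw per-flower stamen-development scores (0 = fully female to
3 = hermaphrodite) i.i.d. from a categorical distribution; wild-type and
heterozygous plants bear only score-0 flowers. The default score
distribution, `c(0.10, 0.15, 0.30, 0.45)`, was chosen once so that its mean
is 2.1, the genotype-level andromonoecy index reported for homozygous mutants
in the system this package models; the per-flower distribution itself is not
published, so only the mean is calibrated.

### Bulks and sequencing

`build_bulk()` selects bulk members: mutant bulks at random or by extreme
andromonoecy index, WT bulks at random or with a fixed genotype composition.
The designed experiment fixes the WT bulk at 15 homozygous-reference plus 15
heterozygous plants, i.e. a true causal-site AF of 0.25. This choice follows
the published expectation of AF 0.25 in the WT bulk; note that a purely
random draw from the 1:2 phenotypic-WT mixture would give an expected AF of
1/3, so the expectation and the 0.3 filter ceiling are only consistent under
a composition-controlled (or chance-favoured) bulk. Both options are
available.

`sequence_bulks()` models site-level pooled sequencing: depth is Poisson
around the mean (only mean depths are typically published), and the alt-read
count is binomial with success probability equal to the true bulk AF adjusted
for per-base error, `p(1-e) + (1-p)e`, making the observed AF an unbiased
estimator of the error-adjusted truth. Genotypes are maximum-likelihood
diploid-pool calls over expected alt fractions `{e, 1/2, 1-e}`; GQ is the
phred-scaled gap between the best and second-best binomial likelihood, capped
at 99. The caller that produced the original data does something more
elaborate internally, but this definition is monotone in the evidence, cheap,
and testable, which is what the filter cascade requires of it.

## The filter cascade

`apply_cascade()` applies four stages in the conventional reporting order,
recording survivors after each:

1. **Allele frequency**: mutant-bulk AF of 1 and WT-bulk AF at most 0.3.
2. **EMS canonicality**: G>A or C>T as written on the reference strand.
   Reverse-strand events already appear complemented in a VCF, so no strand
   handling is needed.
3. **Quality**: GQ >= 90 and DP >= 10 in *both* bulks. Published filter
   descriptions rarely say which bulk the quality filter applies to; both is
   the safe choice because a failed call in either bulk corrupts the AF
   contrast.
4. **Impact**: effect class in a configurable candidate set, `{HIGH,
   MODERATE}` by default, so protein-altering missense variants are
   candidates.

Because the stages are a pure conjunction, the final candidate set is
invariant under stage permutation; only the intermediate counts depend on the
order. The tests verify this, along with record-by-record brute-force
equivalence and count monotonicity.

Numerical boundary choices, all configurable:

* *"AF = 1"* is implemented strictly as zero reference-supporting reads.
  With raw error-bearing reads in the AD field this is too strict: at depth
  500 and error 1e-3 a truly fixed site carries Poisson(0.5) reference reads
  and would fail about 40% of the time. `run_bsa_pipeline()` therefore
  defaults the tolerance to `10 * error_rate` (AF >= 0.99 at the designed
  error rate), which keeps the false-negative probability of a fixed site
  below 1e-4 while excluding heterozygous sites (AF near 0.5) by an enormous
  margin. `filter_params()` itself keeps the strict default, which is
  appropriate for callers that report error-filtered allele depths.
* The WT-side comparator is inclusive (`<= 0.3`) by default with a strict
  option, since printed descriptions alternate between the two; likewise GQ
  and DP default to `>=`.
* Records with undefined AF (zero depth in a bulk) are not failed at the AF
  stage; the depth filter removes them, which keeps each stage's meaning
  clean.

`scan_af_profile()` produces the chromosome-wide windowed AF profile used to
visualise the causal region: the mutant-bulk mean AF plateaus near 1 around
the causal locus while the WT-bulk mean stays near its expectation under
selection. Peaks are maximal runs of windows with mutant-bulk mean above 0.9
and WT-bulk mean at most the AF ceiling plus a margin; threshold, window and
step are configurable because the windowing used for published figures is
generally not described.

## Effect annotation

`classify_region()` assigns each position the most severe of CDS, splice
site, UTR, intron or intergenic, with splice sites defined as the two
intronic bases flanking each exon boundary (the canonical donor/acceptor
dinucleotides). `predict_protein_effect()` splices the CDS in transcription
order, reverse-complements minus-strand genes, and translates the reference
and mutant codons, detecting missense, synonymous, stop-gain, stop-loss and
start-loss. The property suite checks the annotator against an independent
oracle -- applying the SNP to the chromosome, re-extracting and translating
the full CDS, and diffing the proteins -- over 1,000 randomized gene/variant
cases including minus-strand genes, plus an exact strand-mirror symmetry
test.

Impact taxonomy follows the standard convention (missense is MODERATE, not
HIGH), while cascade candidacy is a separate configurable set. This
reproduces the common informal usage in which a single exonic missense
surviving the cascade is called the "high impact" candidate, without
corrupting the taxonomy. Overlapping gene models are all annotated and the
most severe call feeds the cascade; only the first transcript of a gene is
considered, and indels and multi-allelic sites are out of scope.

## Phenotype and expression statistics

* `andromonoecy_index()`: mean per-flower score; genotype-level AI is the
  mean of plant means (not the pooled flower mean). Fewer than 10 flowers is
  a warning, not an error, since 10 is a phenotyping protocol minimum.
* `classify_sex_phenotype()`: monoecious at AI exactly 0, fully
  andromonoecious at AI >= 2.5. The 2.5 cutoff is a classification
  convenience -- no published numeric definition of "partially
  andromonoecious" exists -- and is configurable.
* `segregation_test()`: closed-form one-degree-of-freedom chi-square against
  an expected ratio, checked in the tests against `stats::chisq.test()`.
* `cosegregation()`: percent concordance between causal-site genotype and
  phenotype under the recessive rule, listing discordant plants; missing
  genotypes are excluded with a warning.
* `relative_expression_ddct()`: Livak 2^-ddCt relative expression. Multiple
  calibrators are averaged on the dCt scale (standard practice where the
  method citation leaves this open), so the calibrator mean has fold change
  exactly 1.

## The designed experiment

`simulate_bsa_experiment()` bundles the study conditions into one call: a
two-chromosome, 100 kb-per-chromosome toy genome with 10 genes; one causal
CDS missense (P5L by construction) on chromosome 1; 200 linked intergenic EMS
passengers on the causal chromosome; 100 shared background variants; a BC2S1
family of 300 plants; 30-plant bulks (mutant bulk by extreme AI, WT bulk at
15+15 composition); mean depth 500 and error 1e-3. `run_bsa_pipeline()` then
writes the VCF, reads it back, subtracts the background blacklist, annotates
and filters.

```{r, eval = FALSE}
sim <- simulate_bsa_experiment(seed = 1)
res <- run_bsa_pipeline(sim)
res$cascade
```

Under these conditions the cascade returns the causal missense as the single
protein-altering candidate in well over 90% of seeded runs; the dominant
failure mode is the binomial upper tail of the WT-bulk AF at the causal site
(true AF 0.25 observed above the 0.3 ceiling, roughly a 0.5% event at depth
500). The linked intergenic passengers that survive the AF, EMS and quality
stages are removed by the impact stage, mirroring how real cascades shrink
hundreds of linked EMS SNPs to one exonic candidate.

## Problem sizes and runtime

The test suite uses 10,000-offspring families for Mendelian calibration
(3-sigma binomial bands), 40,000 offspring for the 1:2:1 and backcross
checks, 1,000 seeds for sequencing-unbiasedness and mutation-count
calibration, 1,000 randomized cases for the translation oracle, and 100
seeded end-to-end pipeline runs for the recovery power property. These sizes
keep every statistical check inside tight analytic tolerances while the whole
suite runs in a few minutes on one CPU.

## Known limitations

The simulator emits site-level observations, not reads: alignment artifacts,
mapping bias, indels, multi-allelic sites and local depth structure are not
modelled, so passing tests demonstrate correctness of the analysis logic, not
robustness to upstream calling noise. Recombination has no interference or
chromosome-structure heterogeneity. The phenotype model is fully penetrant by
construction. GQ values are internally consistent but not numerically
comparable to any specific caller's output.
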