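# bsamap

Mapping-by-sequencing (bulked segregant analysis, BSA-seq) of EMS-induced
mutations, for forward geneticists who need the full analysis path — and a
ground-truth simulator to validate it — without any external data.

The design this package implements is the standard one for a recessive
mutant isolated from an EMS screen. The mutant is backcrossed to its
background genotype and selfed (BC₂S₁), giving a family segregating 1:2:1 at
the causal locus (3:1 phenotypically). Two DNA pools are sequenced: a mutant
bulk of homozygous-mutant plants and a wild-type bulk mixing homozygous
reference and heterozygous carriers. At the causal site the expected
alternate allele frequency (AF) is 1 in the mutant bulk and ~0.25–0.33 in
the WT bulk, while unlinked segregating sites sit near 0.5 in both. The SNP
filter cascade on the two-bulk VCF is:

1. **AF**: AF(mutant bulk) = 1 and AF(WT bulk) ≤ 0.3
2. **EMS canonicality**: G>A or C>T transitions only
3. **Quality**: GQ ≥ 90 and DP ≥ 10 in both bulks
4. **Impact**: protein-altering effect on a gene model (e.g. a missense such
   as P5L)

plus subtraction of variants shared across mutant families (background
differences from the reference assembly), a chromosome-wide windowed AF scan
to visualise the causal plateau, χ² segregation tests, genotype–phenotype
co-segregation, the andromonoecy index (AI: per-flower stamen-development
scores 0–3 averaged per plant and genotype), and 2^−ΔΔCt relative
expression.

Because raw reads for such studies are frequently not deposited, the package
includes a first-class simulator — toy genomes with translatable gene
models, EMS mutagenesis, backcross/selfing pedigrees with Poisson
recombination, phenotype-selected bulks, and site-level pooled sequencing
with ML diploid-pool genotype calls — that emits two-sample VCF, FASTA, GFF3
and a truth table.

## Worked example

```r
library(bsamap)

sim <- simulate_bsa_experiment(seed = 1)  # BC2S1 family, 30+30 bulks, depth 500
res <- run_bsa_pipeline(sim)              # VCF -> blacklist -> annotate -> cascade
res$cascade
#> SNP filter cascade:
#>   total              201
#>   allele_frequency   4
#>   ems_canonical      4
#>   quality            4
#>   impact             1
#> candidates:
#>   chrom   pos ref alt gene_id aa_change   impact
#> 1  chr1 15991   C   T gene001       P5L MODERATE
```

The cascade starts from 201 records (1 causal missense + 200 linked
intergenic EMS passengers; the 100 shared background variants were removed by
the blacklist), keeps the 4 sites fixed in the mutant bulk and rare in the WT
bulk, and the impact stage leaves exactly one protein-altering candidate —
the planted causal mutation (`sim$causal`: chr1:15991 C>T, a
proline-to-leucine change at residue 5 of gene001).

The supporting statistics on the same simulated family of 300 plants:

```r
seg <- segregation_test(sum(sim$population$phenotype == "WT"),
                        sum(sim$population$phenotype == "mutant"))
#> 214 WT : 86 mutant; chi-square = 2.151, p = 0.142  (consistent with 3:1)

cosegregation(data.frame(plant_id = 1:300,
                         genotype = genotype_at(sim$population),
                         phenotype = sim$population$phenotype))$percent
#> [1] 100
```

A windowed AF scan localises the causal region as the run of windows where
the mutant-bulk mean AF stays near 1 while the WT-bulk mean stays low:

```r
prof <- scan_af_profile(res$records, window = 2000,
                        lengths = chrom_lengths(sim$genome))
prof$peaks[prof$peaks$is_peak_region, ]
#>   chrom start   end n_windows is_peak_region
#> 1  chr1 16001 22000         3           TRUE
```

A thin command-line front end over the same functions is installed at
`inst/cli/bsamap` (subcommands `simulate`, `filter`, `scan`, `annotate`,
`pheno`, `ddct`).

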