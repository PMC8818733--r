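#' Simulate a complete bulked-segregant mapping experiment
#'
#' End-to-end generator with known ground truth, emulating the standard design
#' for mapping a recessive EMS mutation: a mutagenized founder carrying one
#' causal coding missense plus linked intergenic EMS passenger mutations and
#' shared background variants, backcrossed to the recurrent parent and selfed
#' (BC2S1 by default), phenotyped, bulked (30 + 30 plants) and sequenced as
#' two pooled samples.
#'
#' Defaults encode the study conditions: 300 plants in the segregating
#' family, a 30-plant mutant bulk selected for extreme andromonoecy, a
#' 30-plant WT bulk fixed at 15 homozygous-reference + 15 heterozygous plants
#' (true causal-site AF 0.25), mean depth 500 and per-base error 1e-3.
#'
#' @param seed Integer seed governing the whole simulation.
#' @param n_chrom,chrom_length,n_genes Toy genome dimensions.
#' @param n_linked_passengers Intergenic EMS passenger sites on the causal
#'   chromosome.
#' @param n_background Shared background variants (both parents homozygous).
#' @param scheme Pedigree scheme (see [run_pedigree()]).
#' @param n_plants Size of the final segregating family.
#' @param bulk_size Plants per bulk.
#' @param wt_composition Causal-site genotype mix of the WT bulk.
#' @param mean_depth,error_rate Sequencing model parameters.
#' @param causal_residue Residue index of the planted missense (see
#'   [plant_missense()]).
#' @return list with `genome`, `sites`, `causal` (one-row truth), `population`,
#'   `wt_bulk`, `mut_bulk`, `observations`, `blacklist` (the background sites,
#'   as recovered from sibling families) and `error_rate`.
#' @export
simulate_bsa_experiment <- function(seed = NULL, n_chrom = 2,
                                    chrom_length = 1e5, n_genes = 10,
                                    n_linked_passengers = 200,
                                    n_background = 100, scheme = "BC2S1",
                                    n_plants = 300, bulk_size = 30,
                                    wt_composition = c(hom_ref = 15, het = 15),
                                    mean_depth = 500, error_rate = 1e-3,
                                    causal_residue = 5) {
  with_seed(seed, {
    genome <- make_toy_genome(n_chrom, chrom_length, n_genes)
    # causal gene: first plus-strand gene on chromosome 1
    on_chr1 <- Filter(function(g) g$chrom == "chr1", genome$genes)
    plus <- Filter(function(g) g$strand == "+", on_chr1)
    causal_gene <- if (length(plus)) plus[[1]] else on_chr1[[1]]
    planted <- plant_missense(genome, causal_gene$gene_id, causal_residue)
    genome <- planted$genome
    causal <- planted$site
    passengers <- sample_intergenic_ems(genome, n_linked_passengers,
                                        chrom = causal$chrom,
                                        exclude_pos = causal)
    background <- add_background_variants(genome, n_background,
                                          exclude_pos = rbind(
                                            causal[, c("chrom", "pos")],
                                            passengers[, c("chrom", "pos")]))
    sites <- combine_sites(causal, passengers, background, genome = genome)
    lengths <- chrom_lengths(genome)
    founder <- make_founder(sites, lengths, c("EMS", "background"))
    recurrent <- make_founder(sites, lengths, "background")
    pop <- run_pedigree(founder, recurrent, scheme = scheme,
                        n_final = n_plants)
    pop <- assign_phenotype(pop)
    wt_bulk <- build_bulk(pop, "WT", size = bulk_size,
                          composition = wt_composition)
    mut_bulk <- build_bulk(pop, "mutant", size = bulk_size,
                           selection = "extreme_ai")
    obs <- sequence_bulks(wt_bulk, mut_bulk, mean_depth = mean_depth,
                          error_rate = error_rate)
    list(genome = genome, sites = sites, causal = causal, population = pop,
         wt_bulk = wt_bulk, mut_bulk = mut_bulk, observations = obs,
         blacklist = background, error_rate = error_rate)
  })
}

#' Run the full mapping pipeline on a simulated experiment
#'
#' Writes the two-bulk VCF, reads it back, subtracts the blacklist of shared
#' background variants, annotates every record against the gene models and
#' applies the filter cascade. By default the mutant-bulk AF tolerance is set
#' to `10 * error_rate`: with raw error-bearing reads in AD, the expected
#' number of reference-supporting reads at a truly homozygous site is
#' `error_rate * depth`, and a band of ten times the error rate keeps the
#' false-negative probability negligible while excluding heterozygous sites
#' (AF near 0.5) by a wide margin. Pass `params` explicitly to override.
#'
#' @param sim Output of [simulate_bsa_experiment()].
#' @param params Optional [filter_params()]; default derives `af_mut_tol`
#'   from the simulation's error rate.
#' @param vcf_path Optional path for the intermediate VCF (a temp file by
#'   default).
#' @return list with `records` (as re-read from the VCF), `effects`,
#'   `cascade` (a `cascade_result`) and `vcf_path`.
#' @export
run_bsa_pipeline <- function(sim, params = NULL, vcf_path = NULL) {
  if (is.null(params)) {
    params <- filter_params(af_mut_tol = 10 * sim$error_rate)
  }
  if (is.null(vcf_path)) {
    vcf_path <- tempfile(fileext = ".vcf")
    on.exit(unlink(vcf_path), add = TRUE)
  }
  write_bulk_vcf(sim$observations, vcf_path, lengths = chrom_lengths(sim$genome))
  records <- read_bulk_vcf(vcf_path)
  records <- subtract_common(records, sim$blacklist)
  effects <- annotate_sites(records, sim$genome$genes, sim$genome)
  cascade <- apply_cascade(records, effects, params)
  list(records = records, effects = effects, cascade = cascade,
       vcf_path = vcf_path)
}
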