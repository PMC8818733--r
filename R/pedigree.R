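#' Population constructor
#'
#' A diploid population is stored as two haplotype matrices (sites x
#' individuals, entries 0 = reference allele, 1 = variant allele) over a
#' shared `variant_sites` table. Phenotype fields are filled by
#' [assign_phenotype()].
#'
#' @param sites A `variant_sites` table.
#' @param lengths Named chromosome lengths (bp), e.g. [chrom_lengths()].
#' @param hapA,hapB Integer matrices, `nrow(sites)` x n individuals.
#' @return An object of class `bsa_population`.
#' @export
bsa_population <- function(sites, lengths, hapA, hapB) {
  hapA <- as.matrix(hapA); hapB <- as.matrix(hapB)
  stopifnot(nrow(hapA) == nrow(sites), nrow(hapB) == nrow(sites),
            ncol(hapA) == ncol(hapB),
            all(hapA %in% 0:1), all(hapB %in% 0:1),
            all(sites$chrom %in% names(lengths)))
  n <- ncol(hapA)
  structure(list(sites = sites, lengths = lengths, hapA = hapA, hapB = hapB,
                 phenotype = rep(NA_character_, n),
                 flower_scores = rep(list(NULL), n),
                 plant_ai = rep(NA_real_, n)),
            class = "bsa_population")
}

#' Number of individuals in a population
#' @param pop A `bsa_population`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) ncol(pop$hapA)

#' @export
print.bsa_population <- function(x, ...) {
  cat(sprintf("bsa_population: %d individual(s), %d variant site(s)%s\n",
              n_individuals(x), nrow(x$sites),
              if (all(is.na(x$phenotype))) "" else sprintf(
                " (%d WT / %d mutant)", sum(x$phenotype == "WT", na.rm = TRUE),
                sum(x$phenotype == "mutant", na.rm = TRUE))))
  invisible(x)
}

#' Extract individuals from a population
#' @param pop A `bsa_population`.
#' @param idx Indices of the individuals to keep.
#' @return A `bsa_population` restricted to `idx`.
#' @export
individual <- function(pop, idx) {
  out <- pop
  out$hapA <- pop$hapA[, idx, drop = FALSE]
  out$hapB <- pop$hapB[, idx, drop = FALSE]
  out$phenotype <- pop$phenotype[idx]
  out$flower_scores <- pop$flower_scores[idx]
  out$plant_ai <- pop$plant_ai[idx]
  out
}

#' Founder individual homozygous for a set of variant origins
#'
#' The mutagenized founder carries its EMS mutations (and shared background
#' variants) in homozygous state; the recurrent background parent carries only
#' the shared background variants.
#'
#' @param sites A `variant_sites` table.
#' @param lengths Named chromosome lengths.
#' @param carrier_of Origins carried homozygously, subset of
#'   `c("EMS", "background")`.
#' @return A one-individual `bsa_population`.
#' @export
make_founder <- function(sites, lengths, carrier_of) {
  allele <- matrix(as.integer(sites$origin %in% carrier_of), ncol = 1)
  bsa_population(sites, lengths, allele, allele)
}

#' Diploid genotypes at a site
#' @param pop A `bsa_population`.
#' @param site_index Row index into `pop$sites`; defaults to the causal site.
#' @return Character vector of `"0/0"`, `"0/1"`, `"1/1"` per individual.
#' @export
genotype_at <- function(pop, site_index = which(pop$sites$is_causal)) {
  stopifnot(length(site_index) == 1)
  c("0/0", "0/1", "1/1")[pop$hapA[site_index, ] + pop$hapB[site_index, ] + 1L]
}

# one recombinant gamete per offspring; crossovers ~ Poisson(rate) per
# chromosome, breakpoints uniform along the chromosome, no interference
sample_gametes <- function(hapA, hapB, sites, lengths, n, rate) {
  out <- matrix(0L, nrow = nrow(sites), ncol = n)
  by_chrom <- split(seq_len(nrow(sites)), sites$chrom)
  for (ch in names(by_chrom)) {
    idx <- by_chrom[[ch]]
    pos <- sites$pos[idx]
    L <- lengths[[ch]]
    a <- hapA[idx]; b <- hapB[idx]
    for (j in seq_len(n)) {
      k <- stats::rpois(1, rate)
      start <- sample.int(2L, 1L)
      if (k == 0L) {
        hap <- rep(start, length(idx))
      } else {
        bp <- sort(stats::runif(k, 0, L))
        hap <- (start - 1L + findInterval(pos, bp)) %% 2L + 1L
      }
      out[idx, j] <- ifelse(hap == 1L, a, b)
    }
  }
  out
}

#' Cross two individuals
#'
#' Each offspring receives one recombinant gamete from each parent. Crossover
#' counts per chromosome are Poisson with mean `crossover_rate`, breakpoints
#' are uniform and there is no interference, so every offspring allele exists
#' in a parent haplotype.
#'
#' @param parent_a,parent_b One-individual `bsa_population`s over identical
#'   site tables.
#' @param n_offspring Number of offspring.
#' @param crossover_rate Expected crossovers per chromosome per meiosis.
#' @param seed Optional integer seed.
#' @return A `bsa_population` of the offspring.
#' @export
cross <- function(parent_a, parent_b, n_offspring, crossover_rate = 1,
                  seed = NULL) {
  stopifnot(n_individuals(parent_a) == 1, n_individuals(parent_b) == 1,
            identical(parent_a$sites, parent_b$sites), n_offspring >= 1)
  with_seed(seed, {
    sites <- parent_a$sites
    hapA <- sample_gametes(parent_a$hapA[, 1], parent_a$hapB[, 1], sites,
                           parent_a$lengths, n_offspring, crossover_rate)
    hapB <- sample_gametes(parent_b$hapA[, 1], parent_b$hapB[, 1], sites,
                           parent_b$lengths, n_offspring, crossover_rate)
    bsa_population(sites, parent_a$lengths, hapA, hapB)
  })
}

# pick one offspring heterozygous at the causal site, or error
pick_carrier <- function(pop) {
  causal <- which(pop$sites$is_causal)
  if (length(causal) != 1) {
    stop("pedigree schemes with selection steps need exactly one causal site")
  }
  het <- which(pop$hapA[causal, ] + pop$hapB[causal, ] == 1L)
  if (!length(het)) stop("no heterozygous carrier found among the offspring")
  individual(pop, het[sample.int(length(het), 1)])
}

#' Run a backcross/selfing pedigree
#'
#' Starts from an F1 between a homozygous mutagenized founder and the
#' homozygous recurrent (background) parent, then applies the scheme: `"BCk"`
#' backcrosses a heterozygous carrier to the background parent k times and
#' `"Sm"` selfs a heterozygous carrier m times. `"BC2S1"` is the default
#' mapping-population design: two backcrosses followed by one selfing, which
#' segregates 1:2:1 at the causal locus (3:1 phenotypically for a recessive
#' mutation). `"S1"` alone selfs the F1 (an M2-style family segregating at
#' every founder mutation).
#'
#' @param founder,background One-individual `bsa_population`s (see
#'   [make_founder()]).
#' @param scheme Scheme string such as `"BC2S1"`, `"BC1S1"` or `"S1"`.
#' @param n_final Number of individuals in the final generation.
#' @param crossover_rate Expected crossovers per chromosome.
#' @param n_intermediate Offspring produced at intermediate selection steps.
#' @param seed Optional integer seed.
#' @return A `bsa_population` of the final generation.
#' @export
run_pedigree <- function(founder, background, scheme = "BC2S1", n_final,
                         crossover_rate = 1, n_intermediate = 30, seed = NULL) {
  m <- regmatches(scheme, regexec("^(?:BC([0-9]+))?(?:S([0-9]+))?$",
                                  toupper(scheme)))[[1]]
  if (!length(m) || (m[2] == "" && m[3] == "")) {
    stop("empty or unparseable pedigree scheme: '", scheme, "'")
  }
  n_bc <- if (m[2] == "") 0L else as.integer(m[2])
  n_self <- if (m[3] == "") 0L else as.integer(m[3])
  with_seed(seed, {
    steps <- c(rep("BC", n_bc), rep("S", n_self))
    parent <- cross(founder, background, 1)  # F1, heterozygous everywhere
    pop <- NULL
    for (i in seq_along(steps)) {
      last <- i == length(steps)
      n <- if (last) n_final else n_intermediate
      pop <- if (steps[i] == "BC") {
        cross(parent, background, n, crossover_rate)
      } else {
        cross(parent, parent, n, crossover_rate)
      }
      if (!last) parent <- pick_carrier(pop)
    }
    pop
  })
}

#' Assign phenotypes and flower scores
#'
#' Deterministic recessive model: individuals homozygous for the causal allele
#' are `"mutant"`, all others `"WT"`. Wild-type plants bear only fully female
#' flowers (score 0); mutant plants draw per-flower stamen-development scores
#' i.i.d. from `flower_score_dist` over scores 0..3. The per-plant
#' andromonoecy index (AI) is the mean flower score. The default distribution
#' has mean 2.1.
#'
#' @param pop A `bsa_population` with exactly one causal site.
#' @param flower_score_dist Probabilities of scores 0, 1, 2, 3 (sums to 1).
#' @param n_flowers Flowers scored per plant.
#' @param seed Optional integer seed.
#' @return `pop` with `phenotype`, `flower_scores` and `plant_ai` filled.
#' @export
assign_phenotype <- function(pop, flower_score_dist = c(0.10, 0.15, 0.30, 0.45),
                             n_flowers = 10, seed = NULL) {
  stopifnot(length(flower_score_dist) == 4, all(flower_score_dist >= 0),
            abs(sum(flower_score_dist) - 1) < 1e-8, n_flowers >= 1)
  causal <- which(pop$sites$is_causal)
  if (length(causal) != 1) stop("population must carry exactly one causal site")
  with_seed(seed, {
    geno <- pop$hapA[causal, ] + pop$hapB[causal, ]
    pop$phenotype <- ifelse(geno == 2L, "mutant", "WT")
    pop$flower_scores <- lapply(seq_along(geno), function(j) {
      if (geno[j] == 2L) {
        sample(0:3, n_flowers, replace = TRUE, prob = flower_score_dist)
      } else {
        rep(0L, n_flowers)
      }
    })
    pop$plant_ai <- vapply(pop$flower_scores, mean, numeric(1))
    pop
  })
}
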