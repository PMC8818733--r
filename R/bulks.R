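#' Build a phenotype-selected DNA bulk
#'
#' Selects `size` individuals of the requested phenotype. Mutant bulks can be
#' drawn at random or by ranking plants on their andromonoecy index and taking
#' the most extreme ones (ties broken reproducibly under `seed`). WT bulks are
#' drawn from all phenotypically wild-type plants -- a mixture of homozygous
#' reference and heterozygous carriers -- either at random or with an explicit
#' genotype `composition`.
#'
#' @param pop A `bsa_population` with phenotypes assigned.
#' @param label `"WT"` or `"mutant"`.
#' @param size Bulk size (default 30 plants).
#' @param selection `"random"` or `"extreme_ai"` (mutant bulks only).
#' @param composition Optional named counts `c(hom_ref = , het = )` fixing the
#'   causal-site genotype mix of a WT bulk.
#' @param seed Optional integer seed.
#' @return An object of class `bsa_bulk`.
#' @export
build_bulk <- function(pop, label = c("WT", "mutant"), size = 30,
                       selection = c("random", "extreme_ai"),
                       composition = NULL, seed = NULL) {
  label <- match.arg(label)
  selection <- match.arg(selection)
  if (all(is.na(pop$phenotype))) stop("assign_phenotype() must be run first")
  with_seed(seed, {
    pool <- which(pop$phenotype == label)
    if (!is.null(composition)) {
      stopifnot(label == "WT", all(c("hom_ref", "het") %in% names(composition)),
                sum(composition) == size)
      geno <- genotype_at(pop)
      members <- integer(0)
      for (cls in c(hom_ref = "0/0", het = "0/1")[c("hom_ref", "het")]) {
        want <- composition[[if (cls == "0/0") "hom_ref" else "het"]]
        avail <- intersect(pool, which(geno == cls))
        if (length(avail) < want) {
          stop("WT bulk needs ", want, " plants of genotype ", cls,
               " but only ", length(avail), " are available")
        }
        members <- c(members, avail[sample.int(length(avail), want)])
      }
    } else {
      if (length(pool) < size) {
        stop(label, " bulk of size ", size, " requested but only ",
             length(pool), " ", label, " plants are available")
      }
      members <- if (selection == "extreme_ai") {
        if (label != "mutant") stop("extreme_ai selection applies to mutant bulks")
        shuffled <- pool[sample.int(length(pool))]  # seeded tie-break
        shuffled[order(-pop$plant_ai[shuffled])][seq_len(size)]
      } else {
        pool[sample.int(length(pool), size)]
      }
    }
    structure(list(label = label, size = size, members = sort(members),
                   sites = pop$sites, lengths = pop$lengths,
                   hapA = pop$hapA[, sort(members), drop = FALSE],
                   hapB = pop$hapB[, sort(members), drop = FALSE]),
              class = "bsa_bulk")
  })
}

#' True bulk allele frequency at every site
#' @param bulk A `bsa_bulk`.
#' @return Numeric vector: variant-allele count / (2 x bulk size) per site.
#' @export
true_allele_freq <- function(bulk) {
  (rowSums(bulk$hapA) + rowSums(bulk$hapB)) / (2 * bulk$size)
}

#' @export
print.bsa_bulk <- function(x, ...) {
  cat(sprintf("bsa_bulk: %s bulk, %d plants, %d sites\n",
              x$label, x$size, nrow(x$sites)))
  invisible(x)
}

# maximum-likelihood diploid-pool genotype call with phred-scaled quality.
# Candidate genotypes 0/0, 0/1, 1/1 have expected alt-read fractions
# e, 0.5, 1-e under per-base error e; GQ is the phred gap between the best
# and second-best binomial likelihood, capped at 99.
genotype_call <- function(alt, dp, error_rate) {
  e <- max(error_rate, 1e-10)
  p <- c(e, 0.5, 1 - e)
  ll <- vapply(p, function(pg) stats::dbinom(alt, dp, pg, log = TRUE),
               numeric(length(alt)))
  ll <- matrix(ll, ncol = 3)
  best <- max.col(ll)
  gt <- c("0/0", "0/1", "1/1")[best]
  gap <- vapply(seq_along(best), function(i) {
    o <- sort(ll[i, ], decreasing = TRUE)
    o[1] - o[2]
  }, numeric(1))
  gq <- pmin(99L, as.integer(round(10 * gap / log(10))))
  gt[dp == 0] <- "./."
  gq[dp == 0] <- 0L
  list(gt = gt, gq = gq)
}

#' Simulate short-read sequencing of two bulks
#'
#' For every site and bulk, read depth is Poisson around `mean_depth` and the
#' alt-read count is binomial with success probability equal to the true bulk
#' allele frequency adjusted for per-base sequencing error
#' (`p(1-e) + (1-p)e`). Genotypes are maximum-likelihood diploid-pool calls
#' with phred-scaled qualities.
#'
#' @param wt,mut `bsa_bulk` objects over the same site table.
#' @param mean_depth Mean read depth per site (default 45).
#' @param error_rate Per-base sequencing error (default 1e-3).
#' @param seed Optional integer seed.
#' @return data.frame of class `site_observations` with truth columns
#'   (`origin`, `is_causal`, `true_af_wt`, `true_af_mut`) and per-bulk
#'   `*_dp`, `*_ref_ad`, `*_alt_ad`, `*_gt`, `*_gq`, `*_af` columns. `*_af`
#'   is `NA` where depth is zero.
#' @seealso [write_bulk_vcf()], [write_truth_table()]
#' @export
sequence_bulks <- function(wt, mut, mean_depth = 45, error_rate = 1e-3,
                           seed = NULL) {
  stopifnot(identical(wt$sites, mut$sites), mean_depth > 0,
            error_rate >= 0, error_rate < 0.5)
  with_seed(seed, {
    sites <- wt$sites
    obs <- data.frame(sites, true_af_wt = true_allele_freq(wt),
                      true_af_mut = true_allele_freq(mut))
    for (b in c("wt", "mut")) {
      p <- obs[[paste0("true_af_", b)]]
      p_adj <- p * (1 - error_rate) + (1 - p) * error_rate
      dp <- stats::rpois(nrow(sites), mean_depth)
      alt <- stats::rbinom(nrow(sites), dp, p_adj)
      call <- genotype_call(alt, dp, error_rate)
      obs[[paste0(b, "_dp")]] <- dp
      obs[[paste0(b, "_ref_ad")]] <- dp - alt
      obs[[paste0(b, "_alt_ad")]] <- alt
      obs[[paste0(b, "_gt")]] <- call$gt
      obs[[paste0(b, "_gq")]] <- call$gq
      obs[[paste0(b, "_af")]] <- ifelse(dp > 0, alt / dp, NA_real_)
    }
    class(obs) <- c("site_observations", "data.frame")
    obs
  })
}

#' Write simulated bulk observations as a two-sample VCF
#'
#' Emits a VCF v4.2 file with samples `WT_BULK` and `MUT_BULK` and FORMAT
#' `GT:AD:DP:GQ`. The output is deterministic (no timestamps), so identical
#' observations give byte-identical files.
#'
#' @param obs A `site_observations` data.frame from [sequence_bulks()].
#' @param path Output file.
#' @param lengths Optional named chromosome lengths for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(obs, path, lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    if (!is.null(lengths)) sprintf("##contig=<ID=%s,length=%d>", names(lengths), lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "WT_BULK", "MUT_BULK", sep = "\t"))
  fmt <- function(b) sprintf("%s:%d,%d:%d:%d", obs[[paste0(b, "_gt")]],
                             obs[[paste0(b, "_ref_ad")]],
                             obs[[paste0(b, "_alt_ad")]],
                             obs[[paste0(b, "_dp")]], obs[[paste0(b, "_gq")]])
  body <- if (nrow(obs)) {
    paste(obs$chrom, obs$pos, ".", obs$ref, obs$alt, ".", "PASS", ".",
          "GT:AD:DP:GQ", fmt("wt"), fmt("mut"), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the simulation truth table
#'
#' TSV companion of the VCF: site coordinates, origin, causal flag and the
#' true per-bulk allele frequencies.
#'
#' @param obs A `site_observations` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(obs, path) {
  cols <- c("chrom", "pos", "ref", "alt", "origin", "is_causal",
            "true_af_wt", "true_af_mut")
  utils::write.table(as.data.frame(obs)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth_table()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
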