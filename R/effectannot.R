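IMPACT_LEVELS <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

# severity ranks used when a variant hits several genes or regions
region_severity <- c(cds = 5, splice_site = 4, five_prime_utr = 3,
                     three_prime_utr = 3, intron = 2, intergenic = 1)

# region of a position relative to a single gene model, or NA when outside it
region_in_gene <- function(pos, gene, splice_width = 2L) {
  sp <- gene_span(gene)
  if (pos < sp[1] || pos > sp[2]) return(NA_character_)
  if (any(pos >= gene$cds$start & pos <= gene$cds$end)) return("cds")
  ex <- gene$exons
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) {
    # intronic: splice site when within splice_width of an exon boundary
    donor_acceptor <- c(ex$end[-nrow(ex)], ex$start[-1])
    if (any(abs(pos - donor_acceptor) <= splice_width)) return("splice_site")
    return("intron")
  }
  # exonic but non-coding: UTR side depends on strand
  if (pos < min(gene$cds$start)) {
    return(if (gene$strand == "+") "five_prime_utr" else "three_prime_utr")
  }
  if (gene$strand == "+") "three_prime_utr" else "five_prime_utr"
}

#' Classify the genic region of a variant
#'
#' Applies the precedence CDS > splice site > UTR > intron > intergenic.
#' Splice sites are the `splice_width` intronic bases flanking each
#' exon/intron boundary (2 bp, the canonical donor/acceptor dinucleotides, by
#' default). When several genes overlap the position the most severe region
#' wins.
#'
#' @param chrom,pos Variant coordinates (1-based).
#' @param genes List of `gene_model`s.
#' @param chrom_names Optional vector of known chromosomes; an unknown
#'   `chrom` is an error when supplied.
#' @param splice_width Intronic bases flanking each boundary called splice site.
#' @return list with `gene_id` (`NA` for intergenic) and `region`.
#' @export
classify_region <- function(chrom, pos, genes, chrom_names = NULL,
                            splice_width = 2L) {
  if (!is.null(chrom_names) && !chrom %in% chrom_names) {
    stop("unknown chromosome '", chrom, "'")
  }
  best <- list(gene_id = NA_character_, region = "intergenic")
  for (gene in genes) {
    if (gene$chrom != chrom) next
    r <- region_in_gene(pos, gene, splice_width)
    if (!is.na(r) && region_severity[[r]] > region_severity[[best$region]]) {
      best <- list(gene_id = gene$gene_id, region = r)
    }
  }
  best
}

aa_of <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

#' Predict the protein-level effect of a coding SNP
#'
#' Splices the CDS in transcription order (reverse-complementing minus-strand
#' genes), locates the variant's codon and within-codon offset, and translates
#' the reference and mutant codons with the standard genetic code. Start-loss,
#' stop-gain and stop-loss are detected; amino-acid changes are reported as
#' e.g. `"P5L"` (reference residue, 1-based index, mutant residue).
#'
#' @param site One-row data.frame with `chrom`, `pos`, `ref`, `alt`
#'   (reference-strand alleles).
#' @param gene A `gene_model` whose CDS contains the site.
#' @param genome A `toy_genome`.
#' @return One-row data.frame (an effect call): `gene_id`, `region`,
#'   `codon_change`, `aa_change`, `consequence`, `impact`.
#' @export
predict_protein_effect <- function(site, gene, genome) {
  if (cds_length(gene) %% 3L != 0L) {
    stop("CDS length of gene '", gene$gene_id, "' is not divisible by 3")
  }
  map <- cds_coordinate_map(gene)
  idx <- which(map == site$pos)
  if (length(idx) != 1) {
    stop("variant ", variant_key(site), " is not in the CDS of gene '",
         gene$gene_id, "'")
  }
  minus <- gene$strand == "-"
  tx_ref <- if (minus) chartr("ACGT", "TGCA", site$ref) else site$ref
  tx_alt <- if (minus) chartr("ACGT", "TGCA", site$alt) else site$alt
  codon_i <- (idx - 1L) %/% 3L + 1L
  offset <- (idx - 1L) %% 3L + 1L
  codon_pos <- map[((codon_i - 1L) * 3L + 1L):((codon_i - 1L) * 3L + 3L)]
  bases <- substring(genome$sequences[[gene$chrom]], codon_pos, codon_pos)
  if (minus) bases <- chartr("ACGT", "TGCA", bases)
  ref_codon <- paste(bases, collapse = "")
  if (bases[offset] != tx_ref) {
    stop("reference allele of ", variant_key(site),
         " does not match the genome")
  }
  bases[offset] <- tx_alt
  alt_codon <- paste(bases, collapse = "")
  ref_aa <- aa_of(ref_codon)
  alt_aa <- aa_of(alt_codon)
  consequence <-
    if (codon_i == 1L && alt_codon != "ATG") "start_loss"
    else if (ref_aa != "*" && alt_aa == "*") "stop_gain"
    else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  call <- data.frame(gene_id = gene$gene_id, region = "cds",
                     codon_change = paste0(ref_codon, ">", alt_codon),
                     aa_change = paste0(ref_aa, codon_i, alt_aa),
                     consequence = consequence, impact = NA_character_,
                     stringsAsFactors = FALSE)
  call$impact <- classify_impact(call)
  call
}

#' Impact class of an effect call
#'
#' Default policy follows the usual annotation taxonomies: HIGH for
#' stop-gain, stop-loss, start-loss and splice-site variants; MODERATE for
#' missense; LOW for synonymous; MODIFIER for intron, UTR and intergenic.
#' Which classes make a variant a mapping candidate is decided separately by
#' the cascade's `candidate_impacts` (HIGH + MODERATE by default, so a
#' protein-altering missense is a candidate).
#'
#' @param call One-row effect call with `region` and `consequence` columns
#'   (vectorised over rows).
#' @param policy Named character vector mapping consequences/regions to
#'   impact classes; override to change the taxonomy.
#' @return Character vector of impact classes.
#' @export
classify_impact <- function(call,
                            policy = c(start_loss = "HIGH", stop_gain = "HIGH",
                                       stop_loss = "HIGH", splice_site = "HIGH",
                                       missense = "MODERATE",
                                       synonymous = "LOW",
                                       intron = "MODIFIER",
                                       five_prime_utr = "MODIFIER",
                                       three_prime_utr = "MODIFIER",
                                       intergenic = "MODIFIER")) {
  key <- ifelse(call$region == "cds", call$consequence, call$region)
  unname(policy[key])
}

# effect call for a non-coding region
modifier_call <- function(gene_id, region) {
  call <- data.frame(gene_id = gene_id, region = region,
                     codon_change = NA_character_, aa_change = NA_character_,
                     consequence = region, impact = NA_character_,
                     stringsAsFactors = FALSE)
  call$impact <- classify_impact(call)
  call
}

#' Annotate a set of variants against gene models
#'
#' For each site, every overlapping gene is annotated and the most severe call
#' (by impact class, then region severity) is reported, so overlapping gene
#' models cannot hide a coding change.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` (e.g. a
#'   `variant_sites` table or the records read from a bulk VCF).
#' @param genes List of `gene_model`s.
#' @param genome A `toy_genome` providing the reference sequence.
#' @param splice_width See [classify_region()].
#' @return data.frame keyed by `chrom`, `pos`, `ref`, `alt` with `gene_id`,
#'   `region`, `codon_change`, `aa_change`, `consequence`, `impact` columns.
#' @export
annotate_sites <- function(sites, genes, genome, splice_width = 2L) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, , drop = FALSE]
    calls <- list()
    for (gene in genes) {
      if (gene$chrom != site$chrom) next
      r <- region_in_gene(site$pos, gene, splice_width)
      if (is.na(r)) next
      calls[[length(calls) + 1]] <- if (r == "cds") {
        predict_protein_effect(site, gene, genome)
      } else {
        modifier_call(gene$gene_id, r)
      }
    }
    best <- if (!length(calls)) {
      modifier_call(NA_character_, "intergenic")
    } else {
      sev <- vapply(calls, function(cl) {
        match(cl$impact, IMPACT_LEVELS) * 10 + region_severity[[cl$region]]
      }, numeric(1))
      calls[[which.max(sev)]]
    }
    cbind(site[, c("chrom", "pos", "ref", "alt")], best,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), region = character(0),
                      codon_change = character(0), aa_change = character(0),
                      consequence = character(0), impact = character(0))
  }
  rownames(out) <- NULL
  out
}
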