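# fixtures and independent oracles shared across test files

# handcrafted one-gene genome: plus-strand gene with a two-exon CDS spelling
# ATG GCT GCT GCT CCA GGT TAA, so codon 5 is CCA (proline) and a C>T at the
# genomic position of its second base gives CTA (leucine) -> "P5L"
p5l_fixture <- function() {
  spliced <- "ATGGCTGCTGCTCCAGGTTAA"  # 7 codons, 21 bases
  set.seed(99)
  chars <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  chars[101:110] <- strsplit(substr(spliced, 1, 10), "")[[1]]
  chars[161:171] <- strsplit(substr(spliced, 11, 21), "")[[1]]
  cds <- data.frame(start = c(101, 161), end = c(110, 171))
  gene <- gene_model("geneP", "chr1", "+", exons = cds, cds = cds)
  genome <- toy_genome(c(chr1 = paste(chars, collapse = "")), list(gene))
  # spliced index 14 (2nd base of codon 5) sits at genomic 160 + (14 - 10)
  list(genome = genome, gene = gene, p5l_pos = 164L)
}

# independent full-CDS translation: extract the spliced CDS from the raw
# chromosome string and translate it with Biostrings
translate_gene <- function(chrom_seq, gene) {
  parts <- substring(chrom_seq, gene$cds$start, gene$cds$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

apply_snp <- function(chrom_seq, pos, alt) {
  substr(chrom_seq, pos, pos) <- alt
  chrom_seq
}

# brute-force, record-by-record application of the four cascade predicates,
# independent of apply_cascade's vectorised implementation
brute_force_cascade <- function(records, effects, p,
                                order = c("af", "ems", "quality", "impact")) {
  ekey <- paste(effects$chrom, effects$pos, effects$ref, effects$alt)
  counts <- c(total = nrow(records))
  keep <- records
  for (stage in order) {
    ok <- vapply(seq_len(nrow(keep)), function(i) {
      r <- keep[i, ]
      eff <- effects[match(paste(r$chrom, r$pos, r$ref, r$alt), ekey), ]
      switch(stage,
        af = {
          mut_ok <- if (is.na(r$mut_af)) TRUE
            else if (p$af_mut_tol == 0) r$mut_ref_ad == 0 && r$mut_alt_ad > 0
            else r$mut_af >= 1 - p$af_mut_tol
          wt_ok <- if (is.na(r$wt_af)) TRUE
            else if (p$af_wt_strict) r$wt_af < p$af_wt_max
            else r$wt_af <= p$af_wt_max
          mut_ok && wt_ok
        },
        ems = (r$ref == "G" && r$alt == "A") || (r$ref == "C" && r$alt == "T"),
        quality = {
          q <- function(x, t, strict) !is.na(x) && if (strict) x > t else x >= t
          q(r$wt_gq, p$gq_min, p$gq_strict) && q(r$mut_gq, p$gq_min, p$gq_strict) &&
            q(r$wt_dp, p$dp_min, p$dp_strict) && q(r$mut_dp, p$dp_min, p$dp_strict)
        },
        impact = eff$impact %in% p$candidate_impacts)
    }, logical(1))
    keep <- keep[ok, , drop = FALSE]
    counts <- c(counts, stats::setNames(nrow(keep), stage))
  }
  list(counts = counts, survivors = keep)
}

# random two-bulk records plus matching effect table, for property tests
random_records <- function(n, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  df <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, n)),
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  for (b in c("wt", "mut")) {
    dp <- rpois(n, 20)
    alt_ad <- rbinom(n, dp, runif(n))
    df[[paste0(b, "_dp")]] <- dp
    df[[paste0(b, "_ref_ad")]] <- dp - alt_ad
    df[[paste0(b, "_alt_ad")]] <- alt_ad
    df[[paste0(b, "_gt")]] <- "0/1"
    df[[paste0(b, "_gq")]] <- sample(0:99, n, replace = TRUE)
    df[[paste0(b, "_af")]] <- ifelse(dp > 0, alt_ad / dp, NA_real_)
  }
  effects <- data.frame(df[, c("chrom", "pos", "ref", "alt")],
                        gene_id = NA_character_,
                        region = sample(c("cds", "intron", "intergenic"),
                                        n, replace = TRUE),
                        codon_change = NA_character_,
                        aa_change = NA_character_,
                        consequence = NA_character_,
                        impact = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                                        n, replace = TRUE),
                        stringsAsFactors = FALSE)
  list(records = df, effects = effects)
}

# single-site population helpers: founder homozygous for one causal EMS site
one_site_setup <- function() {
  sites <- variant_sites("chr1", 5000L, "C", "T", "EMS", is_causal = TRUE)
  lengths <- c(chr1 = 10000L)
  list(sites = sites, lengths = lengths,
       founder = make_founder(sites, lengths, "EMS"),
       background = make_founder(sites, lengths, "background"))
}
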