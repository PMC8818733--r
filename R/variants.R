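#' Variant site table constructor
#'
#' Validates and sorts a table of simulated SNP sites. Each row is a single
#' biallelic substitution with a ground-truth origin (`"EMS"` or
#' `"background"`) and a causal flag.
#'
#' @param chrom,pos,ref,alt Site coordinates and alleles (reference-strand).
#' @param origin `"EMS"` or `"background"` per site.
#' @param is_causal Logical flag; at most one `TRUE` per table.
#' @param genome Optional `toy_genome` used to check that `ref` matches the
#'   reference base at `pos`.
#' @return data.frame of class `variant_sites`, sorted by chromosome and
#'   position.
#' @export
variant_sites <- function(chrom, pos, ref, alt, origin, is_causal = FALSE,
                          genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   origin = as.character(origin),
                   is_causal = rep_len(as.logical(is_causal), length(chrom)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$ref %in% c("A", "C", "G", "T")),
              all(df$alt %in% c("A", "C", "G", "T")),
              all(df$origin %in% c("EMS", "background")))
    if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
    if (anyDuplicated(df[, c("chrom", "pos")])) {
      stop("at most one variant site per (chrom, pos)")
    }
    if (sum(df$is_causal) > 1) stop("at most one site may be flagged causal")
    if (!is.null(genome)) {
      at <- substring(genome$sequences[df$chrom], df$pos, df$pos)
      bad <- which(at != df$ref)
      if (length(bad)) {
        stop("ref allele does not match the genome at ",
             paste(variant_key(df[bad[1], ]), collapse = ", "))
      }
    }
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("variant_sites", "data.frame")
  df
}

#' Combine variant site tables
#' @param ... `variant_sites` tables.
#' @param genome Optional `toy_genome` for revalidation.
#' @return A single sorted, validated `variant_sites` table.
#' @export
combine_sites <- function(..., genome = NULL) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  variant_sites(df$chrom, df$pos, df$ref, df$alt, df$origin, df$is_causal,
                genome = genome)
}

empty_sites <- function() {
  variant_sites(character(0), integer(0), character(0), character(0), character(0))
}

#' Simulate EMS mutagenesis
#'
#' EMS alkylates guanine, producing almost exclusively G>A and C>T transitions
#' as read on the reference strand. Every G or C base in the genome mutates
#' independently with probability `rate`, so the number of induced sites is
#' binomial in the G+C count.
#'
#' @param genome A `toy_genome`.
#' @param rate Per eligible base mutation probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A `variant_sites` table with `origin = "EMS"`.
#' @export
mutagenize_ems <- function(genome, rate, seed = NULL) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate >= 0, rate <= 1)
  with_seed(seed, {
    hits <- lapply(names(genome$sequences), function(ch) {
      bases <- strsplit(genome$sequences[[ch]], "")[[1]]
      elig <- which(bases %in% c("G", "C"))
      mut <- elig[stats::runif(length(elig)) < rate]
      if (!length(mut)) return(NULL)
      data.frame(chrom = ch, pos = mut, ref = bases[mut],
                 alt = ifelse(bases[mut] == "G", "A", "T"))
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits)) return(empty_sites())
    variant_sites(hits$chrom, hits$pos, hits$ref, hits$alt, "EMS",
                  genome = genome)
  })
}

#' Sample intergenic EMS-type sites
#'
#' Draws `n` canonical EMS transitions (G>A / C>T) at positions outside every
#' gene span, optionally restricted to one chromosome. Used to plant linked
#' non-coding passenger mutations around a causal locus.
#'
#' @param genome A `toy_genome`.
#' @param n Number of sites.
#' @param chrom Optional chromosome to restrict to.
#' @param exclude_pos Optional data.frame with `chrom`,`pos` to avoid.
#' @param seed Optional integer seed.
#' @return A `variant_sites` table with `origin = "EMS"`.
#' @export
sample_intergenic_ems <- function(genome, n, chrom = NULL, exclude_pos = NULL,
                                  seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(empty_sites())
  with_seed(seed, {
    chroms <- chrom %||% names(genome$sequences)
    pool <- do.call(rbind, lapply(chroms, function(ch) {
      bases <- strsplit(genome$sequences[[ch]], "")[[1]]
      ok <- bases %in% c("G", "C")
      for (gene in genome$genes) {
        if (gene$chrom == ch) {
          sp <- gene_span(gene)
          ok[sp[1]:sp[2]] <- FALSE
        }
      }
      data.frame(chrom = ch, pos = which(ok), ref = bases[ok])
    }))
    if (!is.null(exclude_pos) && nrow(pool)) {
      pool <- pool[!paste(pool$chrom, pool$pos) %in%
                     paste(exclude_pos$chrom, exclude_pos$pos), , drop = FALSE]
    }
    if (nrow(pool) < n) {
      stop("requested ", n, " intergenic EMS sites but only ", nrow(pool),
           " eligible positions exist")
    }
    sel <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    variant_sites(sel$chrom, sel$pos, sel$ref,
                  ifelse(sel$ref == "G", "A", "T"), "EMS", genome = genome)
  })
}

#' Simulate shared background variants
#'
#' Background variants are pre-existing differences between the mutagenized
#' line (and its background genotype) and the reference assembly. They are
#' homozygous in both founders, so they surface at allele frequency 1 in both
#' bulks and are removable either by the allele-frequency filter or by a
#' blacklist built from sibling mutant families sharing the background.
#'
#' @param genome A `toy_genome`.
#' @param n Number of variants.
#' @param exclude_pos Optional data.frame with `chrom`,`pos` to avoid.
#' @param seed Optional integer seed.
#' @return A `variant_sites` table with `origin = "background"`.
#' @export
add_background_variants <- function(genome, n, exclude_pos = NULL, seed = NULL) {
  stopifnot(n >= 0)
  if (n == 0) return(empty_sites())
  with_seed(seed, {
    lens <- chrom_lengths(genome)
    pool <- data.frame(chrom = rep(names(lens), lens),
                       pos = unlist(lapply(lens, seq_len), use.names = FALSE))
    if (!is.null(exclude_pos)) {
      pool <- pool[!paste(pool$chrom, pool$pos) %in%
                     paste(exclude_pos$chrom, exclude_pos$pos), , drop = FALSE]
    }
    if (nrow(pool) < n) {
      stop("requested ", n, " background variants but only ", nrow(pool),
           " positions are available")
    }
    sel <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    ref <- substring(genome$sequences[sel$chrom], sel$pos, sel$pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1), USE.NAMES = FALSE)
    variant_sites(sel$chrom, sel$pos, ref, alt, "background", genome = genome)
  })
}

#' Plant a causal EMS missense mutation inside a gene
#'
#' Rewrites one codon of the gene so that a single canonical EMS transition at
#' its second base produces a proline-to-leucine substitution (codon CCA to
#' CTA). On minus-strand genes the same transcript change appears as G>A on
#' the reference strand, which is still EMS-canonical. The returned site is
#' flagged causal.
#'
#' @param genome A `toy_genome`.
#' @param gene_id Target gene.
#' @param residue 1-based residue index of the planted codon (not the first or
#'   last codon of the CDS).
#' @return list with elements `genome` (modified) and `site` (a one-row
#'   `variant_sites` table, `is_causal = TRUE`).
#' @export
plant_missense <- function(genome, gene_id, residue = 5) {
  gene <- genome$genes[[gene_id]]
  if (is.null(gene)) stop("unknown gene '", gene_id, "'")
  n_cod <- cds_length(gene) %/% 3L
  stopifnot(residue >= 2, residue <= n_cod - 1)
  map <- cds_coordinate_map(gene)
  tx_idx <- ((residue - 1L) * 3L + 1L):((residue - 1L) * 3L + 3L)
  gpos <- map[tx_idx]
  chars <- strsplit(genome$sequences[[gene$chrom]], "")[[1]]
  codon_plus <- if (gene$strand == "+") "CCA" else revcomp_string("CCA")
  chars[sort(gpos)] <- strsplit(codon_plus, "")[[1]]
  genome$sequences[[gene$chrom]] <- paste(chars, collapse = "")
  site_pos <- gpos[2]  # second codon base carries the C>T (or G>A) change
  ref <- chars[site_pos]
  alt <- if (ref == "C") "T" else "A"
  site <- variant_sites(gene$chrom, site_pos, ref, alt, "EMS",
                        is_causal = TRUE, genome = genome)
  list(genome = genome, site = site)
}
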