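#' Gene model constructor
#'
#' A strand-aware single-transcript gene model: non-overlapping exons plus the
#' coding chain (CDS) they contain, with GFF3-style phases. Coordinates are
#' 1-based inclusive on the reference (plus) strand; transcription order is
#' derived from `strand`.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (1-based inclusive), sorted and
#'   non-overlapping.
#' @param cds data.frame with `start`, `end` and optionally `phase`; every CDS
#'   interval must lie within an exon. When `phase` is missing it is computed
#'   from the cumulative coding length in transcription order.
#' @param product Optional functional annotation string.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds, product = NA_character_) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  cds_in <- as.data.frame(cds)
  cds <- cds_in[order(cds_in$start), c("start", "end"), drop = FALSE]
  stopifnot(strand %in% c("+", "-"),
            all(exons$end >= exons$start),
            all(cds$end >= cds$start))
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons of gene '", gene_id, "' overlap")
  }
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
  }, logical(1))
  if (!all(in_exon)) stop("CDS of gene '", gene_id, "' extends outside exons")
  if ("phase" %in% names(cds_in)) {
    cds$phase <- cds_in$phase[order(cds_in$start)]
  } else {
    cds$phase <- cds_phases(cds, strand)
  }
  rownames(exons) <- rownames(cds) <- NULL
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, product = product),
            class = "gene_model")
}

# GFF3 phase of each CDS interval, computed in transcription order
cds_phases <- function(cds, strand) {
  lens <- cds$end - cds$start + 1L
  ord <- if (strand == "+") seq_along(lens) else rev(seq_along(lens))
  before <- cumsum(c(0L, lens[ord]))[seq_along(lens)]
  phase <- (3L - before %% 3L) %% 3L
  phase[order(ord)]
}

gene_span <- function(gene) c(min(gene$exons$start), max(gene$exons$end))

cds_length <- function(gene) sum(gene$cds$end - gene$cds$start + 1L)

# genomic positions of the spliced CDS, in transcription order
cds_coordinate_map <- function(gene) {
  pos <- unlist(Map(seq.int, gene$cds$start, gene$cds$end), use.names = FALSE)
  if (gene$strand == "-") pos <- rev(pos)
  pos
}

#' Toy genome constructor
#'
#' Bundles chromosome sequences with gene models and validates the container
#' invariants (unique chromosome names, A/C/G/T alphabet, genes within their
#' chromosome, coding length divisible by three).
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param genes List of [gene_model()] objects (may be empty).
#' @return An object of class `toy_genome`.
#' @export
toy_genome <- function(sequences, genes = list()) {
  stopifnot(is.character(sequences), length(sequences) >= 1,
            !is.null(names(sequences)), !anyDuplicated(names(sequences)))
  if (any(grepl("[^ACGT]", sequences))) {
    stop("chromosome sequences must be over the A/C/G/T alphabet")
  }
  g <- structure(list(sequences = sequences, genes = genes), class = "toy_genome")
  names(g$genes) <- vapply(genes, `[[`, character(1), "gene_id")
  for (gene in genes) {
    if (!gene$chrom %in% names(sequences)) {
      stop("gene '", gene$gene_id, "' lies on unknown chromosome '", gene$chrom, "'")
    }
    sp <- gene_span(gene)
    if (sp[1] < 1 || sp[2] > nchar(sequences[[gene$chrom]])) {
      stop("gene '", gene$gene_id, "' extends outside its chromosome")
    }
    if (cds_length(gene) %% 3L != 0L) {
      stop("CDS length of gene '", gene$gene_id, "' is not divisible by 3")
    }
  }
  g
}

#' Chromosome lengths of a toy genome
#' @param genome A `toy_genome`.
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(genome$sequences), names(genome$sequences))
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosome(s), %s bp total, %d gene model(s)\n",
              length(x$sequences), format(sum(nchar(x$sequences)), big.mark = ","),
              length(x$genes)))
  invisible(x)
}

# one random multi-exon gene structure (lengths only; placement comes later)
random_gene_structure <- function(strand, exons_per_gene, exon_bp, intron_bp,
                                  utr5_bp, utr3_bp) {
  n_ex <- if (length(exons_per_gene) == 1) exons_per_gene else sample(exons_per_gene, 1)
  cds_lens <- sample(seq(exon_bp[1], exon_bp[2]), n_ex, replace = TRUE)
  rem <- sum(cds_lens) %% 3L
  cds_lens[n_ex] <- cds_lens[n_ex] - rem
  intron_lens <- if (n_ex > 1) sample(seq(intron_bp[1], intron_bp[2]), n_ex - 1, replace = TRUE) else integer(0)
  left_ext <- if (strand == "+") utr5_bp else utr3_bp
  right_ext <- if (strand == "+") utr3_bp else utr5_bp
  list(n_ex = n_ex, cds_lens = cds_lens, intron_lens = intron_lens,
       left_ext = left_ext, right_ext = right_ext,
       span = sum(cds_lens) + sum(intron_lens) + left_ext + right_ext)
}

# codons excluding the three stops
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate a reproducible toy genome with multi-exon gene models
#'
#' Builds random chromosome sequences and packs non-overlapping gene models
#' onto them. Each gene has 2 or more exons, UTR margins on its outermost
#' exons, and a complete coding sequence (ATG start, no internal stop, one
#' terminal stop, length divisible by three) written into the chromosome so
#' the models can be translated. Both strands are used when two or more genes
#' are requested. The genome is byte-identical across runs with the same seed.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes to place.
#' @param seed Optional integer seed.
#' @param exons_per_gene Candidate exon counts per gene.
#' @param exon_bp,intron_bp Ranges (min, max) for coding-exon and intron sizes.
#' @param utr5_bp,utr3_bp UTR widths added to the outermost exons.
#' @param min_gap Minimum intergenic gap in bp.
#' @return A [toy_genome()].
#' @export
#' @examples
#' g <- make_toy_genome(1, 10000, 1, seed = 7)
#' chrom_lengths(g)
make_toy_genome <- function(n_chrom, chrom_length, n_genes, seed = NULL,
                            exons_per_gene = 2:4,
                            exon_bp = c(90, 240), intron_bp = c(120, 360),
                            utr5_bp = 30, utr3_bp = 45, min_gap = 400) {
  stopifnot(n_chrom >= 1, chrom_length >= 200, n_genes >= 0)
  with_seed(seed, {
    chrom_names <- sprintf("chr%d", seq_len(n_chrom))
    gene_chrom <- if (n_genes > 0) sort(rep_len(seq_len(n_chrom), n_genes)) else integer(0)
    strands <- rep_len(c("+", "-"), max(n_genes, 1))
    genes <- vector("list", n_genes)
    gi <- 0L
    seqs <- character(n_chrom)
    for (ci in seq_len(n_chrom)) {
      chars <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
      k <- sum(gene_chrom == ci)
      if (k > 0) {
        structs <- lapply(seq_len(k), function(i)
          random_gene_structure(strands[gi + i], exons_per_gene, exon_bp,
                                intron_bp, utr5_bp, utr3_bp))
        spans <- vapply(structs, `[[`, numeric(1), "span")
        slack <- chrom_length - sum(spans) - (k + 1) * min_gap
        if (slack < 0) {
          stop(sprintf("cannot place %d gene(s) on a %d bp chromosome", k, chrom_length))
        }
        extra <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1)))
        cursor <- 0L
        for (i in seq_len(k)) {
          cursor <- cursor + min_gap + extra[i]
          start <- cursor + 1L
          gi <- gi + 1L
          gene <- materialize_gene(sprintf("gene%03d", gi), chrom_names[ci],
                                   strands[gi], start, structs[[i]])
          chars <- write_cds_sequence(chars, gene)
          genes[[gi]] <- gene
          cursor <- cursor + structs[[i]]$span
        }
      }
      seqs[ci] <- paste(chars, collapse = "")
    }
    names(seqs) <- chrom_names
    toy_genome(seqs, genes)
  })
}

# lay a gene structure down at a genomic start coordinate
materialize_gene <- function(gene_id, chrom, strand, start, st) {
  cur <- start + st$left_ext
  cds <- data.frame(start = integer(st$n_ex), end = integer(st$n_ex))
  for (i in seq_len(st$n_ex)) {
    cds$start[i] <- cur
    cds$end[i] <- cur + st$cds_lens[i] - 1L
    cur <- cds$end[i] + 1L
    if (i < st$n_ex) cur <- cur + st$intron_lens[i]
  }
  exons <- cds[, c("start", "end")]
  exons$start[1] <- exons$start[1] - st$left_ext
  exons$end[st$n_ex] <- exons$end[st$n_ex] + st$right_ext
  gene_model(gene_id, chrom, strand, exons, cds,
             product = sprintf("hypothetical protein %s", gene_id))
}

# overwrite the chromosome characters so the spliced CDS is a complete ORF
write_cds_sequence <- function(chars, gene) {
  n_cod <- cds_length(gene) %/% 3L
  stopifnot(n_cod >= 3)
  body <- sample(sense_codons(), n_cod - 2L, replace = TRUE)
  cds_seq <- paste0("ATG", paste(body, collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1))
  plus_seq <- if (gene$strand == "+") cds_seq else revcomp_string(cds_seq)
  pos <- unlist(Map(seq.int, gene$cds$start, gene$cds$end), use.names = FALSE)
  chars[pos] <- strsplit(plus_seq, "")[[1]]
  chars
}

#' Write a toy genome to FASTA
#' @param genome A `toy_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

#' Read chromosome sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences (names truncated at whitespace).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS features (one transcript per gene) with
#' 1-based inclusive coordinates and CDS phases.
#'
#' @param genome A `toy_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genome, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(genome$sequences),
                     nchar(genome$sequences)))
  for (gene in genome$genes) {
    sp <- gene_span(gene)
    tid <- paste0(gene$gene_id, ".1")
    attr_gene <- sprintf("ID=%s;product=%s", gene$gene_id,
                         ifelse(is.na(gene$product), "unknown", gene$product))
    lines <- c(lines,
               paste(gene$chrom, "bsamap", "gene", sp[1], sp[2], ".",
                     gene$strand, ".", attr_gene, sep = "\t"),
               paste(gene$chrom, "bsamap", "mRNA", sp[1], sp[2], ".",
                     gene$strand, ".",
                     sprintf("ID=%s;Parent=%s", tid, gene$gene_id), sep = "\t"),
               paste(gene$chrom, "bsamap", "exon", gene$exons$start,
                     gene$exons$end, ".", gene$strand, ".",
                     sprintf("Parent=%s", tid), sep = "\t"),
               paste(gene$chrom, "bsamap", "CDS", gene$cds$start, gene$cds$end,
                     ".", gene$strand, gene$cds$phase,
                     sprintf("ID=cds-%s;Parent=%s", gene$gene_id, tid), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reconstructs single-transcript gene models from gene/mRNA/exon/CDS
#' features. When `sequences` are supplied, each model is validated: the
#' spliced CDS must start with ATG and have length divisible by three;
#' non-ATG starts are rejected.
#'
#' @param path GFF3 file.
#' @param sequences Optional named character vector of chromosome sequences
#'   (e.g. from [read_genome_fasta()]) used to validate start codons.
#' @return List of [gene_model()] objects.
#' @export
read_gene_models_gff3 <- function(path, sequences = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- df[df$type == "mRNA" & df$Parent == gid, , drop = FALSE]
    if (nrow(tx) < 1) stop("gene '", gid, "' has no mRNA feature")
    tid <- tx$ID[1]  # first transcript only
    ex <- df[df$type == "exon" & df$Parent == tid, c("start", "end")]
    cd <- df[df$type == "CDS" & df$Parent == tid, c("start", "end", "phase")]
    product <- if ("product" %in% names(genes)) genes$product[i] else NA_character_
    gm <- gene_model(gid, as.character(genes$seqnames[i]),
                     as.character(genes$strand[i]), ex, cd, product = product)
    if (!is.null(sequences)) {
      spliced <- spliced_cds(sequences[[gm$chrom]], gm)
      if (substr(spliced, 1, 3) != "ATG") {
        stop("gene '", gid, "' does not start with an ATG codon; ",
             "only ATG-initiated models are supported")
      }
    }
    out[[i]] <- gm
  }
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}

# spliced CDS sequence in transcription order (transcript-strand letters)
spliced_cds <- function(chrom_seq, gene) {
  parts <- substring(chrom_seq, gene$cds$start, gene$cds$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp_string(s)
  s
}
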