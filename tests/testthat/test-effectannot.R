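test_that("region classification follows the stated precedence", {
  fx <- p5l_fixture()
  genes <- list(fx$gene)
  # intergenic, CDS containment, intron interior, 2 bp splice windows
  expect_equal(classify_region("chr1", 50, genes)$region, "intergenic")
  expect_true(is.na(classify_region("chr1", 50, genes)$gene_id))
  expect_equal(classify_region("chr1", 105, genes),
               list(gene_id = "geneP", region = "cds"))
  expect_equal(classify_region("chr1", 135, genes)$region, "intron")
  # intron spans 111..160; splice sites are 111, 112, 159, 160
  for (p in c(111, 112, 159, 160)) {
    expect_equal(classify_region("chr1", p, genes)$region, "splice_site")
  }
  expect_equal(classify_region("chr1", 113, genes)$region, "intron")
  expect_equal(classify_region("chr1", 158, genes)$region, "intron")
  expect_error(classify_region("chrX", 1, genes, chrom_names = "chr1"),
               "unknown chromosome")
})

test_that("UTR classification is strand-aware", {
  g <- make_toy_genome(1, 20000, 2, seed = 31)  # one + and one - gene
  for (gene in g$genes) {
    cds_lo <- min(gene$cds$start); cds_hi <- max(gene$cds$end)
    lo_utr <- classify_region(gene$chrom, min(gene$exons$start), list(gene))$region
    hi_utr <- classify_region(gene$chrom, max(gene$exons$end), list(gene))$region
    if (gene$strand == "+") {
      expect_equal(lo_utr, "five_prime_utr")
      expect_equal(hi_utr, "three_prime_utr")
    } else {
      expect_equal(lo_utr, "three_prime_utr")
      expect_equal(hi_utr, "five_prime_utr")
    }
  }
})

test_that("every position in a gene maps to exactly one region", {
  g <- make_toy_genome(1, 20000, 2, seed = 32)
  for (gene in g$genes) {
    span <- seq(min(gene$exons$start), max(gene$exons$end))
    regions <- vapply(span, function(p)
      classify_region(gene$chrom, p, list(gene))$region, character(1))
    expect_false(any(regions == "intergenic"))
    counts <- table(regions)
    expect_equal(sum(counts), length(span))
    expect_equal(unname(counts["cds"]), sum(gene$cds$end - gene$cds$start + 1))
    n_introns <- nrow(gene$exons) - 1
    expect_equal(unname(counts["splice_site"]), 4 * n_introns)
  }
})

test_that("the planted proline-to-leucine codon annotates as P5L", {
  fx <- p5l_fixture()
  site <- data.frame(chrom = "chr1", pos = fx$p5l_pos, ref = "C", alt = "T")
  call <- predict_protein_effect(site, fx$gene, fx$genome)
  expect_equal(call$aa_change, "P5L")
  expect_equal(call$codon_change, "CCA>CTA")
  expect_equal(call$consequence, "missense")
  expect_equal(call$impact, "MODERATE")
})

test_that("synonymous, stop-gain and start-loss calls are detected", {
  fx <- p5l_fixture()
  # codon 2 GCT -> GCC at its 3rd base (genomic 106, T>C): synonymous A2A
  syn <- predict_protein_effect(
    data.frame(chrom = "chr1", pos = 106, ref = "T", alt = "C"),
    fx$gene, fx$genome)
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$aa_change, "A2A")
  expect_equal(syn$impact, "LOW")
  # codon 6 GGT -> TGT is missense; GGT with G>T at base 1 (genomic 166)
  # use codon 4 GCT -> TCT? instead test stop-gain via codon 5 CCA -> TCA? not stop.
  # stop-gain: mutate codon 6 GGT at base 2? GTT no. Build directly: codon 4
  # GCT: G>T at genomic 110 gives TCT (S). For a stop, change codon 5 CCA to
  # TCA (S) - none are stops; instead test stop-loss on the terminal TAA.
  stop_loss <- predict_protein_effect(
    data.frame(chrom = "chr1", pos = 169, ref = "T", alt = "C"),
    fx$gene, fx$genome)  # TAA -> CAA (Q)
  expect_equal(stop_loss$consequence, "stop_loss")
  expect_equal(stop_loss$impact, "HIGH")
  # start-loss: ATG -> GTG at genomic 101
  start_loss <- predict_protein_effect(
    data.frame(chrom = "chr1", pos = 101, ref = "A", alt = "G"),
    fx$gene, fx$genome)
  expect_equal(start_loss$consequence, "start_loss")
  expect_equal(start_loss$impact, "HIGH")
  # variant outside the CDS errors
  expect_error(predict_protein_effect(
    data.frame(chrom = "chr1", pos = 130, ref = "A", alt = "G"),
    fx$gene, fx$genome), "not in the CDS")
})

test_that("a minus-strand premature stop is called HIGH impact", {
  # mirror the handcrafted gene onto the minus strand and create TGG -> TGA
  # (transcript) via a genomic C>T... use a direct construction: transcript
  # codon 6 GGT; on the minus strand genomic ref is the reverse complement.
  spliced <- "ATGGCTGCTGCTCCATGGTAA"  # codon 6 = TGG (W)
  chrom <- paste(c(rep("A", 100),
                   strsplit(as.character(
                     Biostrings::reverseComplement(Biostrings::DNAString(spliced))),
                     "")[[1]],
                   rep("A", 100)), collapse = "")
  cds <- data.frame(start = 101, end = 121)
  gene <- gene_model("gneg", "chr1", "-", exons = cds, cds = cds)
  genome <- toy_genome(c(chr1 = chrom), list(gene))
  # transcript TGG codon occupies transcript positions 16..18; genomic
  # positions run 121..101 in transcription order, so transcript 18 sits at
  # genomic 121 - 17 = 104; TGG -> TGA needs transcript G>A at position 18,
  # i.e. genomic C>T at 104
  site <- data.frame(chrom = "chr1", pos = 104, ref = "C", alt = "T")
  call <- predict_protein_effect(site, gene, genome)
  expect_equal(call$consequence, "stop_gain")
  expect_equal(call$aa_change, "W6*")
  expect_equal(call$impact, "HIGH")
  # oracle: full-CDS translation diff agrees
  prot_ref <- translate_gene(genome$sequences[[1]], gene)
  prot_alt <- translate_gene(apply_snp(genome$sequences[[1]], 104, "T"), gene)
  expect_equal(substr(prot_ref, 6, 6), "W")
  expect_equal(substr(prot_alt, 6, 6), "*")
})

test_that("annotator agrees with full-CDS translation on random genes", {
  set.seed(1234)
  n_cases <- 1000
  checked <- 0
  while (checked < n_cases) {
    g <- make_toy_genome(1, 6000, 2)  # one plus- and one minus-strand gene
    gene <- g$genes[[sample(2, 1)]]
    map <- unlist(Map(seq.int, gene$cds$start, gene$cds$end), use.names = FALSE)
    pos <- sample(map, 1)
    ref <- substr(g$sequences[[gene$chrom]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    site <- data.frame(chrom = gene$chrom, pos = pos, ref = ref, alt = alt)
    call <- predict_protein_effect(site, gene, g)
    prot_ref <- translate_gene(g$sequences[[gene$chrom]], gene)
    prot_alt <- translate_gene(apply_snp(g$sequences[[gene$chrom]], pos, alt),
                               gene)
    diffs <- which(strsplit(prot_ref, "")[[1]] != strsplit(prot_alt, "")[[1]])
    if (call$consequence == "synonymous") {
      expect_length(diffs, 0)
    } else {
      expect_length(diffs, 1)
      idx <- as.integer(gsub("[^0-9]", "", call$aa_change))
      expect_equal(diffs, idx)
      expect_equal(substr(prot_ref, idx, idx),
                   substr(call$aa_change, 1, 1))
      expect_equal(substr(prot_alt, idx, idx),
                   substr(call$aa_change, nchar(call$aa_change),
                          nchar(call$aa_change)))
    }
    checked <- checked + 1
  }
})

test_that("strand-mirrored genes yield identical protein calls", {
  set.seed(77)
  for (i in 1:20) {
    g <- make_toy_genome(1, 5000, 1)
    gene <- g$genes[[1]]
    L <- nchar(g$sequences[[1]])
    mirror_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(g$sequences[[1]])))
    flip <- function(df) data.frame(start = L - df$end + 1, end = L - df$start + 1)
    gene_m <- gene_model(gene$gene_id, "chr1",
                         if (gene$strand == "+") "-" else "+",
                         flip(gene$exons), flip(gene$cds[, c("start", "end")]))
    genome_m <- toy_genome(c(chr1 = mirror_seq), list(gene_m))
    map <- unlist(Map(seq.int, gene$cds$start, gene$cds$end), use.names = FALSE)
    pos <- sample(map, 1)
    ref <- substr(g$sequences[[1]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    call <- predict_protein_effect(
      data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt), gene, g)
    call_m <- predict_protein_effect(
      data.frame(chrom = "chr1", pos = L - pos + 1,
                 ref = chartr("ACGT", "TGCA", ref),
                 alt = chartr("ACGT", "TGCA", alt)), gene_m, genome_m)
    expect_equal(call_m$aa_change, call$aa_change)
    expect_equal(call_m$codon_change, call$codon_change)
    expect_equal(call_m$consequence, call$consequence)
  }
})

test_that("impact policy separates taxonomy from candidacy", {
  syn <- data.frame(region = "cds", consequence = "synonymous")
  mis <- data.frame(region = "cds", consequence = "missense")
  sg <- data.frame(region = "cds", consequence = "stop_gain")
  spl <- data.frame(region = "splice_site", consequence = "splice_site")
  expect_equal(classify_impact(syn), "LOW")
  expect_equal(classify_impact(mis), "MODERATE")
  expect_equal(classify_impact(sg), "HIGH")
  expect_equal(classify_impact(spl), "HIGH")
  # a missense is a cascade candidate under the default impact set
  expect_true("MODERATE" %in% filter_params()$candidate_impacts)
})
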