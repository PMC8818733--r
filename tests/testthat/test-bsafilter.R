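# one hand-written record that passes every stage, for fixture surgery
good_record <- function() {
  data.frame(chrom = "chr1", pos = 100L, ref = "C", alt = "T",
             wt_dp = 30L, wt_ref_ad = 24L, wt_alt_ad = 6L, wt_gt = "0/1",
             wt_gq = 95L, wt_af = 0.2,
             mut_dp = 30L, mut_ref_ad = 0L, mut_alt_ad = 30L, mut_gt = "1/1",
             mut_gq = 95L, mut_af = 1,
             stringsAsFactors = FALSE)
}

effect_for <- function(records, impact = "MODERATE", consequence = "missense") {
  data.frame(records[, c("chrom", "pos", "ref", "alt")],
             gene_id = "geneX", region = "cds", codon_change = "CCA>CTA",
             aa_change = "P5L", consequence = consequence, impact = impact,
             stringsAsFactors = FALSE)
}

test_that("allele frequencies derive from AD and parse errors are located", {
  obs <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L), ref = "C", alt = "T",
                    origin = "EMS", is_causal = FALSE,
                    true_af_wt = 0, true_af_mut = 0,
                    wt_dp = c(20L, 20L, 10L), wt_ref_ad = c(0L, 14L, 10L),
                    wt_alt_ad = c(20L, 6L, 0L), wt_gt = "0/1",
                    wt_gq = 90L, wt_af = 0,
                    mut_dp = 10L, mut_ref_ad = 0L, mut_alt_ad = 10L,
                    mut_gt = "1/1", mut_gq = 90L, mut_af = 1)
  path <- tempfile(fileext = ".vcf")
  write_bulk_vcf(obs, path)
  rec <- read_bulk_vcf(path)
  expect_equal(rec$wt_af, c(1, 0.3, 0))  # AD (0,20), (14,6), (10,0)
  expect_error(read_bulk_vcf(path, wt_sample = "NOPE"), "not found")
  # corrupt one AD field
  lines <- sub("0,20", "0;20", readLines(path))
  bad <- tempfile(fileext = ".vcf")
  writeLines(lines, bad)
  expect_error(read_bulk_vcf(bad), "AD")
  unlink(c(path, bad))
})

test_that("blacklist subtraction is keyed on the full variant", {
  r <- rbind(good_record(), good_record(), good_record())
  r$pos <- c(100L, 200L, 300L)
  expect_identical(subtract_common(r, r[0, ]), r)          # empty blacklist
  expect_equal(nrow(subtract_common(r, r)), 0)             # full blacklist
  bl <- r[2, ]; bl$alt <- "G"                              # same pos, other alt
  expect_identical(subtract_common(r, bl), r)
  expect_equal(subtract_common(r, r[2, ])$pos, c(100L, 300L))
})

test_that("a fully passing record survives all cascade stages", {
  r <- good_record()
  res <- apply_cascade(r, effect_for(r), filter_params())
  expect_equal(res$stages$n, c(1, 1, 1, 1, 1))
  expect_equal(res$candidates$pos, 100L)
})

test_that("each cascade stage removes exactly its designed failure", {
  base <- good_record()
  records <- do.call(rbind, replicate(6, base, simplify = FALSE))
  records$pos <- seq(100L, 600L, by = 100L)
  records$wt_af[2] <- 0.5                                   # fails WT AF
  records$mut_ref_ad[3] <- 2L; records$mut_alt_ad[3] <- 28L # fails AF = 1
  records$mut_af[3] <- 28 / 30
  records$ref[4] <- "A"; records$alt[4] <- "G"              # fails EMS
  records$wt_gq[5] <- 50L                                   # fails GQ
  effects <- effect_for(records)
  effects$impact[6] <- "MODIFIER"; effects$region[6] <- "intron"  # fails impact
  res <- apply_cascade(records, effects, filter_params())
  expect_equal(res$stages$stage,
               c("total", "allele_frequency", "ems_canonical", "quality",
                 "impact"))
  expect_equal(res$stages$n, c(6, 4, 3, 2, 1))
  expect_equal(res$candidates$pos, 100L)
  # counts never increase along the cascade
  expect_true(all(diff(res$stages$n) <= 0))
})

test_that("empty input yields an all-zero cascade", {
  r <- good_record()[0, ]
  res <- apply_cascade(r, effect_for(good_record())[0, ], filter_params())
  expect_true(all(res$stages$n == 0))
  expect_equal(nrow(res$candidates), 0)
})

test_that("cascade equals brute-force predicate application on random inputs", {
  for (s in 1:10) {
    rr <- random_records(80, seed = s)
    p <- filter_params(af_mut_tol = sample(c(0, 0.05), 1),
                       af_wt_strict = sample(c(TRUE, FALSE), 1),
                       gq_min = 40, dp_min = 15)
    mine <- apply_cascade(rr$records, rr$effects, p)
    oracle <- brute_force_cascade(rr$records, rr$effects, p)
    expect_equal(mine$stages$n, unname(oracle$counts))
    expect_equal(mine$candidates$pos, oracle$survivors$pos)
    expect_true(all(diff(mine$stages$n) <= 0))
  }
})

test_that("the final candidate set is invariant under stage permutation", {
  rr <- random_records(100, seed = 42)
  p <- filter_params(gq_min = 40, dp_min = 15)
  ref_set <- sort(apply_cascade(rr$records, rr$effects, p)$candidates$pos)
  perms <- list(c("ems", "af", "impact", "quality"),
                c("impact", "quality", "ems", "af"),
                c("quality", "impact", "af", "ems"))
  for (ord in perms) {
    alt_set <- sort(brute_force_cascade(rr$records, rr$effects, p,
                                        order = ord)$survivors$pos)
    expect_equal(alt_set, ref_set)
  }
})

test_that("cascade reports render the same numbers in TSV and JSON", {
  r <- good_record()
  res <- apply_cascade(r, effect_for(r), filter_params())
  tsv <- report_cascade(res, "tsv")
  js <- jsonlite::fromJSON(report_cascade(res, "json"))
  expect_equal(js$stages$n, res$stages$n)
  expect_match(tsv, "allele_frequency\t1")
  expect_match(tsv, "P5L")
  expect_equal(js$candidates$aa_change, "P5L")
  # empty result renders a header-only table
  empty <- apply_cascade(r[0, ], effect_for(r)[0, ], filter_params())
  lines <- strsplit(report_cascade(empty, "tsv"), "\n")[[1]]
  expect_equal(lines[1], "stage\tn")
  expect_match(lines[length(lines)], "^chrom\t")
})

test_that("AF scans find the causal plateau and respect window contracts", {
  # null profile: AF 0.5 everywhere in both bulks -> no peak
  null_rec <- data.frame(chrom = "chr1", pos = seq(1000L, 50000L, 1000L),
                         wt_af = 0.5, mut_af = 0.5)
  prof <- scan_af_profile(null_rec, window = 5000, lengths = c(chr1 = 50000))
  expect_equal(nrow(prof$peaks), 0)
  expect_true(all(prof$windows$wt_af >= 0 & prof$windows$wt_af <= 1,
                  na.rm = TRUE))
  # windows tile the chromosome
  expect_equal(prof$windows$start, seq(1L, 50000L, 5000L))
  expect_equal(prof$windows$end[-nrow(prof$windows)] + 1L,
               prof$windows$start[-1])

  # single site -> one informative window carrying that AF
  one <- data.frame(chrom = "chr1", pos = 100L, wt_af = 0.25, mut_af = 1)
  prof1 <- scan_af_profile(one, window = 1000)
  expect_equal(nrow(prof1$windows), 1)
  expect_equal(prof1$windows$mut_af, 1)
  expect_equal(prof1$windows$wt_af, 0.25)

  # simulated plateau: peak region contains the causal site
  sim <- simulate_bsa_experiment(seed = 6)
  res <- run_bsa_pipeline(sim)
  prof2 <- scan_af_profile(res$records, window = 2000,
                           lengths = chrom_lengths(sim$genome))
  peak <- prof2$peaks[prof2$peaks$is_peak_region, ]
  expect_equal(peak$chrom, sim$causal$chrom)
  expect_gte(sim$causal$pos, peak$start)
  expect_lte(sim$causal$pos, peak$end)
  bed <- tempfile(fileext = ".bed")
  write_peaks_bed(prof2, bed)
  expect_equal(length(readLines(bed)), nrow(prof2$peaks))
  unlink(bed)
})

test_that("records with undefined AF are retained until the depth filter", {
  r <- good_record()
  r$wt_dp <- 0L; r$wt_ref_ad <- 0L; r$wt_alt_ad <- 0L
  r$wt_af <- NA_real_; r$wt_gt <- "./."; r$wt_gq <- 0L
  res <- apply_cascade(r, effect_for(r), filter_params())
  # survives the AF stage (undefined), dies at quality
  expect_equal(res$stages$n[res$stages$stage == "allele_frequency"], 1)
  expect_equal(res$stages$n[res$stages$stage == "quality"], 0)
})
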