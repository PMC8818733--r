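#' Filter cascade parameters
#'
#' Thresholds of the bulked-segregant SNP filter cascade. Defaults mirror the
#' standard design for a recessive EMS mutant mapped with a homozygous-mutant
#' bulk and a phenotypic-WT bulk: alternate allele frequency exactly 1 in the
#' mutant bulk and at most 0.3 in the WT bulk, canonical EMS changes only,
#' genotype quality >= 90 and depth >= 10 in both bulks, and candidate
#' variants restricted to protein-altering impact classes.
#'
#' "AF = 1" is strict by default (zero reference-supporting reads);
#' `af_mut_tol` relaxes it to `AF >= 1 - af_mut_tol`, which is appropriate
#' when raw error-bearing reads are counted in AD. The WT-side, GQ and DP
#' comparators can be switched between inclusive (default) and strict.
#'
#' @param af_wt_max Maximum WT-bulk alternate AF (default 0.3).
#' @param af_mut_tol Tolerance below 1 for the mutant-bulk AF (default 0,
#'   i.e. strict equality).
#' @param gq_min Minimum genotype quality, both bulks (default 90).
#' @param dp_min Minimum read depth, both bulks (default 10).
#' @param ems_only Keep only canonical EMS changes, G>A or C>T as written on
#'   the reference strand (default TRUE).
#' @param candidate_impacts Impact classes accepted as candidates.
#' @param af_wt_strict,gq_strict,dp_strict Use strict (`<`, `>`) instead of
#'   inclusive comparators.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(af_wt_max = 0.3, af_mut_tol = 0, gq_min = 90,
                          dp_min = 10, ems_only = TRUE,
                          candidate_impacts = c("HIGH", "MODERATE"),
                          af_wt_strict = FALSE, gq_strict = FALSE,
                          dp_strict = FALSE) {
  stopifnot(af_wt_max >= 0, af_wt_max <= 1, af_mut_tol >= 0, af_mut_tol < 1,
            gq_min >= 0, dp_min >= 0,
            all(candidate_impacts %in% IMPACT_LEVELS))
  structure(list(af_wt_max = af_wt_max, af_mut_tol = af_mut_tol,
                 gq_min = gq_min, dp_min = dp_min, ems_only = ems_only,
                 candidate_impacts = candidate_impacts,
                 af_wt_strict = af_wt_strict, gq_strict = gq_strict,
                 dp_strict = dp_strict),
            class = "filter_params")
}

#' Read a two-bulk VCF into filterable records
#'
#' Parses a VCF with the two named bulk samples and per-sample GT/AD/DP/GQ.
#' Allele frequencies are computed from AD as alt / (ref + alt); a bulk with
#' missing or zero depth gets `NA` AF (the record is retained and later fails
#' the depth filter).
#'
#' @param path VCF file (plain or bgzipped).
#' @param wt_sample,mut_sample Sample names of the WT and mutant bulks.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt` and per-bulk
#'   `wt_*`/`mut_*` columns matching [sequence_bulks()] output.
#' @export
read_bulk_vcf <- function(path, wt_sample = "WT_BULK", mut_sample = "MUT_BULK") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  if (nrow(out) == 0) return(out)
  samples <- colnames(v@gt)[-1]
  for (s in c(wt_sample, mut_sample)) {
    if (!s %in% samples) {
      stop("sample '", s, "' not found in ", path,
           " (samples: ", paste(samples, collapse = ", "), ")")
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  for (b in c(wt = wt_sample, mut = mut_sample)) {
    pre <- names(which(c(wt = wt_sample, mut = mut_sample) == b))[1]
    ads <- strsplit(ad[, b], ",", fixed = TRUE)
    bad <- which(lengths(ads) != 2 & !is.na(ad[, b]))
    if (length(bad)) {
      stop("malformed AD field for sample ", b, " at ",
           out$chrom[bad[1]], ":", out$pos[bad[1]])
    }
    adm <- suppressWarnings(vapply(ads, function(x) {
      if (length(x) != 2) c(NA_integer_, NA_integer_) else as.integer(x)
    }, integer(2)))
    if (any(is.na(adm) & !is.na(ad[, b]))) {
      i <- which(apply(is.na(adm), 2, any) & !is.na(ad[, b]))[1]
      stop("non-numeric AD field for sample ", b, " at ",
           out$chrom[i], ":", out$pos[i])
    }
    tot <- adm[1, ] + adm[2, ]
    out[[paste0(pre, "_dp")]] <- as.integer(dp[, b])
    out[[paste0(pre, "_ref_ad")]] <- adm[1, ]
    out[[paste0(pre, "_alt_ad")]] <- adm[2, ]
    out[[paste0(pre, "_gt")]] <- unname(gt[, b])
    out[[paste0(pre, "_gq")]] <- as.integer(gq[, b])
    out[[paste0(pre, "_af")]] <- ifelse(!is.na(tot) & tot > 0,
                                        adm[2, ] / tot, NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Remove blacklisted (shared) variants
#'
#' Variants observed across independent mutant families are almost always
#' common differences between the line's background and the reference
#' assembly, not induced mutations, and are discarded before filtering.
#' Matching is on the full (chrom, pos, ref, alt) key; a blacklist entry at
#' the same position with a different alt allele does not remove the record.
#'
#' @param records data.frame of records (from [read_bulk_vcf()]).
#' @param blacklist data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return `records` without blacklisted rows, order preserved.
#' @export
subtract_common <- function(records, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0 || nrow(records) == 0) {
    return(records)
  }
  keep <- !variant_key(records) %in% variant_key(blacklist)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# the four cascade predicates; NA comparisons count as failures except that an
# undefined AF does not fail the AF stage (the depth stage removes it)
pass_af <- function(r, p) {
  mut_ok <- ifelse(is.na(r$mut_af), TRUE,
                   if (p$af_mut_tol == 0) r$mut_ref_ad == 0 & r$mut_alt_ad > 0
                   else r$mut_af >= 1 - p$af_mut_tol)
  wt_ok <- ifelse(is.na(r$wt_af), TRUE,
                  if (p$af_wt_strict) r$wt_af < p$af_wt_max
                  else r$wt_af <= p$af_wt_max)
  mut_ok & wt_ok
}

pass_ems <- function(r) {
  (r$ref == "G" & r$alt == "A") | (r$ref == "C" & r$alt == "T")
}

pass_quality <- function(r, p) {
  cmp <- function(x, t, strict) !is.na(x) & (if (strict) x > t else x >= t)
  cmp(r$wt_gq, p$gq_min, p$gq_strict) & cmp(r$mut_gq, p$gq_min, p$gq_strict) &
    cmp(r$wt_dp, p$dp_min, p$dp_strict) & cmp(r$mut_dp, p$dp_min, p$dp_strict)
}

pass_impact <- function(impact, p) impact %in% p$candidate_impacts

#' Apply the SNP filter cascade
#'
#' Runs the four-stage filter in order: (1) bulk allele frequencies (mutant
#' bulk at AF 1, WT bulk at most `af_wt_max`); (2) EMS canonicality (G>A or
#' C>T as written on the reference strand); (3) genotype quality and depth in
#' both bulks; (4) variant impact class. Per-stage survivor counts are
#' recorded; because the stages are a pure conjunction, the final candidate
#' set does not depend on their order, only the intermediate counts do.
#'
#' @param records data.frame of records (see [read_bulk_vcf()]).
#' @param effects Effect annotations from [annotate_sites()] covering every
#'   record (intergenic calls allowed).
#' @param params A [filter_params()] object.
#' @return An object of class `cascade_result`: `stages` (data.frame of stage
#'   name and surviving count, starting at the unfiltered total) and
#'   `candidates` (surviving records joined with their effect columns).
#' @export
apply_cascade <- function(records, effects, params = filter_params()) {
  key <- variant_key(records)
  m <- match(key, variant_key(effects))
  if (nrow(records) > 0 && anyNA(m)) {
    stop("effect annotation missing for ", key[which(is.na(m))[1]])
  }
  eff_cols <- c("gene_id", "region", "codon_change", "aa_change",
                "consequence", "impact")
  joined <- cbind(records, effects[m, eff_cols, drop = FALSE])
  rownames(joined) <- NULL
  stages <- data.frame(stage = "total", n = nrow(joined))
  keep <- joined
  advance <- function(df, name, ok) {
    df <- df[ok, , drop = FALSE]
    stages <<- rbind(stages, data.frame(stage = name, n = nrow(df)))
    df
  }
  keep <- advance(keep, "allele_frequency",
                  if (nrow(keep)) pass_af(keep, params) else logical(0))
  if (params$ems_only) {
    keep <- advance(keep, "ems_canonical",
                    if (nrow(keep)) pass_ems(keep) else logical(0))
  }
  keep <- advance(keep, "quality",
                  if (nrow(keep)) pass_quality(keep, params) else logical(0))
  keep <- advance(keep, "impact",
                  if (nrow(keep)) pass_impact(keep$impact, params) else logical(0))
  rownames(keep) <- NULL
  structure(list(stages = stages, candidates = keep, params = params),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("SNP filter cascade:\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-18s %d\n", x$stages$stage[i], x$stages$n[i]))
  }
  if (nrow(x$candidates)) {
    cat("candidates:\n")
    print(x$candidates[, c("chrom", "pos", "ref", "alt", "gene_id",
                           "aa_change", "impact")])
  }
  invisible(x)
}

#' Render a cascade report
#'
#' Emits the stage table plus one line per final candidate (coordinates,
#' alleles, gene, effect, impact), as TSV text or JSON.
#'
#' @param result A `cascade_result`.
#' @param format `"tsv"` or `"json"`.
#' @param path Optional output file.
#' @return Character scalar (the document), invisibly when `path` is given.
#' @export
report_cascade <- function(result, format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  cand_cols <- c("chrom", "pos", "ref", "alt", "gene_id", "region",
                 "codon_change", "aa_change", "consequence", "impact")
  cand <- result$candidates[, intersect(cand_cols, names(result$candidates)),
                            drop = FALSE]
  doc <- if (format == "tsv") {
    stage_lines <- c("stage\tn",
                     sprintf("%s\t%d", result$stages$stage, result$stages$n))
    cand_lines <- c(paste(names(cand), collapse = "\t"),
                    if (nrow(cand)) do.call(paste,
                      c(lapply(cand, as.character), sep = "\t")))
    paste(c(stage_lines, "", cand_lines), collapse = "\n")
  } else {
    jsonlite::toJSON(list(stages = result$stages, candidates = cand),
                     dataframe = "rows", auto_unbox = TRUE, na = "null",
                     pretty = TRUE)
  }
  if (!is.null(path)) {
    writeLines(as.character(doc), path)
    return(invisible(as.character(doc)))
  }
  as.character(doc)
}

#' Chromosome-wide alternate allele frequency scan
#'
#' Tiles each chromosome with windows and averages the per-bulk alternate
#' allele frequency of the sites in each window. A causal region shows a
#' plateau where the mutant-bulk mean AF stays near 1 while the WT-bulk mean
#' stays near its expectation under selection; peaks are maximal runs of
#' windows where the mutant-bulk mean exceeds `peak_mut_min` and the WT-bulk
#' mean stays at or below `af_wt_max + wt_margin`. Chromosomes without sites
#' produce no windows.
#'
#' @param records data.frame with `chrom`, `pos`, `wt_af`, `mut_af`.
#' @param window Window size in bp.
#' @param step Step between window starts (default `window`, i.e. tiling).
#' @param lengths Optional named chromosome lengths; defaults to the maximal
#'   observed position per chromosome.
#' @param peak_mut_min Minimum mutant-bulk mean AF inside a peak (default 0.9).
#' @param af_wt_max,wt_margin WT-bulk ceiling inside a peak.
#' @return An object of class `af_profile`: `windows` (chrom, start, end,
#'   n_sites, wt_af, mut_af, in_peak) and `peaks` (one row per maximal run,
#'   the widest flagged as the peak region).
#' @export
scan_af_profile <- function(records, window, step = window, lengths = NULL,
                            peak_mut_min = 0.9, af_wt_max = 0.3,
                            wt_margin = 0.1) {
  stopifnot(window >= step, step > 0)
  chroms <- unique(records$chrom)
  win_list <- list()
  for (ch in chroms) {
    rc <- records[records$chrom == ch, , drop = FALSE]
    if (!nrow(rc)) next
    L <- if (!is.null(lengths)) lengths[[ch]] else max(rc$pos)
    starts <- seq(1L, max(1L, L), by = step)
    ends <- pmin(starts + window - 1L, L)
    wt <- mut <- ns <- numeric(length(starts))
    for (i in seq_along(starts)) {
      inw <- rc$pos >= starts[i] & rc$pos <= ends[i]
      ns[i] <- sum(inw)
      wt[i] <- if (ns[i]) mean(rc$wt_af[inw], na.rm = TRUE) else NA_real_
      mut[i] <- if (ns[i]) mean(rc$mut_af[inw], na.rm = TRUE) else NA_real_
    }
    win_list[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                                 n_sites = ns, wt_af = wt, mut_af = mut)
  }
  windows <- if (length(win_list)) do.call(rbind, win_list) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_sites = integer(0), wt_af = numeric(0), mut_af = numeric(0))
  }
  rownames(windows) <- NULL
  qual <- !is.na(windows$mut_af) & !is.na(windows$wt_af) &
    windows$mut_af >= peak_mut_min & windows$wt_af <= af_wt_max + wt_margin
  windows$in_peak <- qual
  peaks <- list()
  for (ch in unique(windows$chrom)) {
    sel <- windows$chrom == ch
    r <- rle(qual[sel])
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    runs <- which(r$values)
    for (k in runs) {
      wsub <- windows[sel, ][starts_i[k]:ends_i[k], , drop = FALSE]
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, start = min(wsub$start), end = max(wsub$end),
        n_windows = nrow(wsub))
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0))
  }
  peaks$is_peak_region <- if (nrow(peaks)) {
    seq_len(nrow(peaks)) == which.max(peaks$n_windows)
  } else logical(0)
  structure(list(windows = windows, peaks = peaks), class = "af_profile")
}

#' @export
print.af_profile <- function(x, ...) {
  cat(sprintf("af_profile: %d window(s), %d peak run(s)\n",
              nrow(x$windows), nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Write peak regions as BED
#'
#' BED uses 0-based half-open intervals; the profile's 1-based inclusive
#' windows are converted accordingly.
#'
#' @param profile An `af_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(profile, path) {
  p <- profile$peaks
  lines <- if (nrow(p)) {
    sprintf("%s\t%d\t%d\tpeak_%d", p$chrom, p$start - 1L, p$end, seq_len(nrow(p)))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
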