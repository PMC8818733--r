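#' Andromonoecy index of a plant
#'
#' Each pistillate flower is scored 0 (fully female, no stamen development)
#' to 3 (hermaphrodite, complete stamens with pollen); the plant AI is the
#' arithmetic mean of its flower scores. Fewer than 10 scored flowers is
#' accepted with a warning, since 10 is the usual phenotyping protocol
#' minimum rather than a formula requirement.
#'
#' @param scores Integer flower scores in `{0, 1, 2, 3}`.
#' @return Plant AI in `[0, 3]`.
#' @export
andromonoecy_index <- function(scores) {
  if (!length(scores)) stop("at least one flower score is required")
  if (!all(scores %in% 0:3)) stop("flower scores must be integers in 0..3")
  if (length(scores) < 10) {
    warning("plant AI computed from fewer than 10 flowers")
  }
  mean(scores)
}

#' Per-plant AI table
#'
#' Builds the plant-level record table used by [cosegregation()] and
#' [genotype_ai()].
#'
#' @param plant_id Plant identifiers.
#' @param genotype `"0/0"`, `"0/1"`, `"1/1"` or `NA` per plant.
#' @param flower_scores List of integer score vectors, one per plant.
#' @param phenotype Optional observed phenotype (`"WT"`/`"mutant"`).
#' @return data.frame with one row per plant and a `plant_ai` column.
#' @export
ai_table <- function(plant_id, genotype, flower_scores, phenotype = NULL) {
  stopifnot(length(plant_id) == length(genotype),
            length(plant_id) == length(flower_scores))
  ai <- vapply(flower_scores, andromonoecy_index, numeric(1))
  out <- data.frame(plant_id = as.character(plant_id),
                    genotype = as.character(genotype),
                    plant_ai = ai, stringsAsFactors = FALSE)
  if (!is.null(phenotype)) out$phenotype <- as.character(phenotype)
  out$flower_scores <- flower_scores
  out
}

#' Genotype-level AI
#'
#' Mean of the plant-level AIs within each genotype class (mean of plant
#' means, not the pooled flower mean).
#'
#' @param ai data.frame from [ai_table()].
#' @return data.frame with `genotype`, `n_plants`, `mean_ai`.
#' @export
genotype_ai <- function(ai) {
  agg <- stats::aggregate(plant_ai ~ genotype, data = ai, FUN = mean)
  n <- stats::aggregate(plant_ai ~ genotype, data = ai, FUN = length)
  data.frame(genotype = agg$genotype, n_plants = n$plant_ai,
             mean_ai = agg$plant_ai, stringsAsFactors = FALSE)
}

#' Sex phenotype class from plant AI
#'
#' Default bins: monoecious at AI exactly 0, partially andromonoecious for
#' 0 < AI < 2.5, andromonoecious for AI >= 2.5. The cutoff at 2.5 is a
#' classification convenience (no standard numeric definition exists) and is
#' configurable.
#'
#' @param plant_ai Numeric AI values in `[0, 3]`.
#' @param andro_min AI at or above which a plant is fully andromonoecious.
#' @return Character vector of classes.
#' @export
classify_sex_phenotype <- function(plant_ai, andro_min = 2.5) {
  stopifnot(all(plant_ai >= 0), all(plant_ai <= 3))
  ifelse(plant_ai == 0, "monoecious",
         ifelse(plant_ai < andro_min, "partially_andromonoecious",
                "andromonoecious"))
}

#' Chi-square goodness of fit for a segregation ratio
#'
#' One-degree-of-freedom test of observed WT/mutant counts against an
#' expected Mendelian ratio (3:1 for a recessive mutation in a selfed
#' heterozygote's progeny).
#'
#' @param n_wt,n_mut Observed counts.
#' @param expected_ratio Expected `c(WT, mutant)` ratio (default `c(3, 1)`).
#' @return list with `statistic`, `p_value`, `expected`.
#' @export
segregation_test <- function(n_wt, n_mut, expected_ratio = c(3, 1)) {
  total <- n_wt + n_mut
  if (total <= 0) stop("at least one plant is required")
  expected <- total * expected_ratio / sum(expected_ratio)
  obs <- c(n_wt, n_mut)
  statistic <- sum((obs - expected)^2 / expected)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Genotype-phenotype co-segregation
#'
#' Percent of plants whose observed phenotype matches the prediction from
#' their causal-site genotype under the recessive model (mutant iff `1/1`).
#' 100% concordance across a large segregating family is the classical
#' evidence that a marker is the causal mutation (or tightly linked to it).
#' Plants with missing genotype are excluded with a warning.
#'
#' @param records data.frame with `plant_id`, `genotype` and `phenotype`
#'   columns (e.g. from [ai_table()] plus an observed phenotype).
#' @return list with `percent`, `n_used`, `n_excluded` and `discordant`
#'   (data.frame of mismatching plants).
#' @export
cosegregation <- function(records) {
  if (!nrow(records)) stop("no plants to evaluate")
  missing_gt <- is.na(records$genotype) | records$genotype == ""
  if (any(missing_gt)) {
    warning(sum(missing_gt), " plant(s) excluded for missing genotype")
  }
  r <- records[!missing_gt, , drop = FALSE]
  if (!nrow(r)) stop("no plants with genotype calls")
  predicted <- ifelse(r$genotype == "1/1", "mutant", "WT")
  ok <- predicted == r$phenotype
  discordant <- r[!ok, c("plant_id", "genotype", "phenotype"), drop = FALSE]
  rownames(discordant) <- NULL
  list(percent = 100 * mean(ok), n_used = nrow(r),
       n_excluded = sum(missing_gt), discordant = discordant)
}

#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification: per sample, dCt = Ct(target) -
#' Ct(reference); ddCt = dCt - mean calibrator dCt (multiple calibrators are
#' averaged on the dCt scale); fold change = 2^(-ddCt). The calibrator group
#' mean therefore has fold change exactly 1.
#'
#' @param samples data.frame with `sample_id`, `ct_target`, `ct_reference`
#'   and `group` (`"calibrator"` or `"test"`).
#' @return `samples` with `dct`, `ddct` and `fold_change` columns added.
#' @export
relative_expression_ddct <- function(samples) {
  stopifnot(all(c("sample_id", "ct_target", "ct_reference", "group") %in%
                  names(samples)))
  if (!all(samples$group %in% c("calibrator", "test"))) {
    stop("group must be 'calibrator' or 'test'")
  }
  ct <- c(samples$ct_target, samples$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be positive and finite")
  }
  if (!any(samples$group == "calibrator")) {
    stop("at least one calibrator sample is required")
  }
  samples$dct <- samples$ct_target - samples$ct_reference
  cal <- mean(samples$dct[samples$group == "calibrator"])
  samples$ddct <- samples$dct - cal
  samples$fold_change <- 2^(-samples$ddct)
  samples
}
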