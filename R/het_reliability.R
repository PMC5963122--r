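# Reliable-heterozygote screen: allele balance + depth.

#' Allele-balance statistic |AD1 - AD2| / DP
#'
#' The screening statistic for false-positive heterozygotes: the absolute
#' difference between the two allele depths scaled by total depth. A true
#' heterozygote samples both alleles at roughly equal depth, so the ratio
#' concentrates near 0; an artifactual het call (an undercalled homozygote)
#' shows a skewed ratio near 1. `AD1 + AD2` need not equal `DP`: the
#' reported total depth may include reads not assigned to either allele, or
#' differ through caller-side filtering, and the statistic uses `DP` as
#' printed.
#'
#' Vectorized; `NA` inputs propagate to `NA` results.
#'
#' @param ad1,ad2 Non-negative allele depths.
#' @param dp Positive total read depth.
#' @return `|ad1 - ad2| / dp` at full floating precision (round only for
#'   display).
#' @examples
#' allele_balance(33, 42, 75)   # 0.12, a balanced (reliable) het
#' allele_balance(76, 10, 84)   # 0.786, a skewed (artifactual) het
#' @export
allele_balance <- function(ad1, ad2, dp) {
  if (any(!is.na(dp) & dp <= 0)) {
    stop("dp must be positive: allele balance is undefined at dp <= 0",
         call. = FALSE)
  }
  if (any(!is.na(ad1) & ad1 < 0) || any(!is.na(ad2) & ad2 < 0)) {
    stop("allele depths must be non-negative", call. = FALSE)
  }
  abs(ad1 - ad2) / dp
}

#' Classify heterozygous calls as reliable or artifactual
#'
#' Applies the joint depth / allele-balance acceptance rule for reliable
#' heterozygotes: a call passes iff it is heterozygous, `DP >= dp_min`, and
#' `|AD1 - AD2| / DP < ratio_max` (strict). The comparison uses the
#' full-precision ratio, never a rounded display value. `reason` records the
#' first failed criterion, checked in the order `not_het`, `missing_fields`,
#' `low_dp`, `high_imbalance`.
#'
#' Defaults are the empirically calibrated thresholds `DP >= 50` and
#' ratio `< 0.3`; a ratio of exactly 0.3 fails, a depth of exactly 50
#' passes.
#'
#' @param calls Data frame of genotype calls with columns `zygosity`, `dp`,
#'   `ad1`, `ad2` (e.g. from [genotype_call()] or an [exo_cohort()]'s
#'   `calls` table).
#' @param dp_min Minimum depth (inclusive), default 50.
#' @param ratio_max Allele-balance ceiling (exclusive), default 0.3.
#' @return Data frame with one row per call: `ratio` (NA when dp or an AD is
#'   missing or dp is 0), `reliable` (logical), `reason` (character).
#'   `reliable` is `TRUE` iff `reason == "pass"`.
#' @examples
#' classify_het(genotype_call("P01", "het", 99, 75, 33, 42))  # pass
#' classify_het(genotype_call("P01", "het", 99, 84, 76, 10))  # high_imbalance
#' @export
classify_het <- function(calls, dp_min = 50, ratio_max = 0.3) {
  stopifnot(is.data.frame(calls),
            all(c("zygosity", "dp", "ad1", "ad2") %in% names(calls)))
  dp <- as.numeric(calls$dp)
  ad1 <- as.numeric(calls$ad1)
  ad2 <- as.numeric(calls$ad2)
  ratio <- rep(NA_real_, nrow(calls))
  ok <- !is.na(dp) & dp > 0 & !is.na(ad1) & !is.na(ad2)
  ratio[ok] <- abs(ad1[ok] - ad2[ok]) / dp[ok]

  reason <- rep("pass", nrow(calls))
  is_het <- !is.na(calls$zygosity) & calls$zygosity == "het"
  missing_fields <- is.na(dp) | is.na(ad1) | is.na(ad2)
  low_dp <- !is.na(dp) & dp < dp_min
  high_imbalance <- !is.na(ratio) & ratio >= ratio_max

  reason[high_imbalance] <- "high_imbalance"
  reason[low_dp] <- "low_dp"
  reason[missing_fields] <- "missing_fields"
  reason[!is_het] <- "not_het"

  data.frame(ratio = ratio, reliable = reason == "pass", reason = reason,
             stringsAsFactors = FALSE)
}

#' Recompute allele-balance ratios for a table of validated sites
#'
#' Utility for calibration tables that pair AD/DP triples with a published
#' (display-rounded) ratio: recomputes the statistic, compares it at 2
#' decimals, and flags rows whose printed ratio disagrees with the formula.
#' The bundled fixture `system.file("extdata", "sanger_validated_sites.tsv",
#' package = "exocascade")` carries six Sanger-validated sites used to
#' calibrate the screen; one of its printed ratios is internally
#' inconsistent and is flagged, not silently corrected.
#'
#' Published tables print the ratio at two decimals but are not uniform in
#' how they get there (most rows match nearest-rounding, one matches
#' truncation), so a row counts as consistent when the printed value lies
#' within one unit in the last printed digit (0.01) of the recomputed
#' statistic. A genuinely wrong printed ratio sits far outside that band.
#'
#' @param path TSV with columns `location`, `ad1`, `ad2`, `dp`,
#'   `printed_ratio`, `sanger_result`.
#' @return The table with `recomputed_ratio` (full precision) and
#'   `consistent` appended.
#' @export
check_validated_sites <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("location", "ad1", "ad2", "dp", "printed_ratio")
  if (!all(needed %in% names(tab))) {
    stop("validated-sites table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  tab$recomputed_ratio <- allele_balance(tab$ad1, tab$ad2, tab$dp)
  tab$consistent <- abs(tab$recomputed_ratio - tab$printed_ratio) <= 0.01 + 1e-12
  tab
}
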