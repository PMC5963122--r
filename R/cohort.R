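#' exocascade: multistep variant prioritization for exome cohorts
#'
#' Tools for prioritizing candidate variants from multi-sample whole-exome
#' VCFs under an autosomal-dominant hypothesis: a reliable-heterozygote
#' screen based on allele balance and depth, a rarity and functional-class
#' filter, an in-silico predictor consensus, a joint CADD/REVEL gate, and
#' keyword-gene-set functional selection, with per-stage accounting. A
#' synthetic cohort simulator with recorded ground truth supports testing
#' every stage without access to patient data.
#'
#' @keywords internal
"_PACKAGE"

# Canonical annotation vocabulary ------------------------------------------

#' Names of the population-frequency databases consulted for rarity
#'
#' @return Character vector: `kg1000` (1000 Genomes), `esp` (Exome
#'   Sequencing Project), `exac` (ExAC), `gnomad` (gnomAD).
#' @export
maf_databases <- function() c("kg1000", "esp", "exac", "gnomad")

#' Names of the ten in-silico pathogenicity predictors
#'
#' The consensus vote counts `damaging` calls from this fixed panel
#' (dbNSFP-style categorical verdicts).
#'
#' @return Character vector of ten tool names.
#' @export
predictor_tools <- function() {
  c("sift", "provean", "polyphen2_hvar", "polyphen2_hdiv", "fathmm",
    "mutation_assessor", "mutation_taster", "lrt", "meta_svm", "meta_lr")
}

zygosity_levels <- function() c("hom_ref", "het", "hom_alt", "missing")
func_class_levels <- function() c("missense", "nonsense", "synonymous", "other")
predictor_levels <- function() c("damaging", "tolerated", "unknown")

maf_columns <- function() paste0("maf_", maf_databases())
predictor_columns <- function() paste0("pred_", predictor_tools())

annotation_columns <- function() {
  c(maf_columns(), predictor_columns(), "cadd_phred", "revel")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Constructors --------------------------------------------------------------

#' Construct a single genotype call
#'
#' A convenience constructor producing the one-row call data frame used
#' throughout the package. `dp` is the approximated read depth at the site;
#' `ad1`/`ad2` are the per-allele read depths in the order the alleles are
#' listed. Their sum need not equal `dp`.
#'
#' @param sample_id Sample identifier.
#' @param zygosity One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`.
#' @param gq Phred-scaled genotype quality (conventionally capped at 99), or
#'   `NA`.
#' @param dp Total read depth, non-negative integer or `NA`.
#' @param ad1,ad2 Allele depths for the first and second listed allele,
#'   non-negative integers or `NA`.
#' @return A one-row data frame with columns `sample_id`, `zygosity`, `gq`,
#'   `dp`, `ad1`, `ad2`.
#' @examples
#' genotype_call("P01", "het", gq = 99, dp = 75, ad1 = 33, ad2 = 42)
#' @export
genotype_call <- function(sample_id, zygosity, gq = NA, dp = NA,
                          ad1 = NA, ad2 = NA) {
  zygosity <- match.arg(zygosity, zygosity_levels())
  for (v in list(gq = gq, dp = dp, ad1 = ad1, ad2 = ad2)) {
    if (!is.na(v) && (!is.numeric(v) || v < 0)) {
      stop("gq, dp, ad1, ad2 must be non-negative or NA", call. = FALSE)
    }
  }
  data.frame(sample_id = as.character(sample_id), zygosity = zygosity,
             gq = as.integer(gq), dp = as.integer(dp),
             ad1 = as.integer(ad1), ad2 = as.integer(ad2),
             stringsAsFactors = FALSE)
}

empty_variants <- function() {
  df <- data.frame(key = character(), chrom = character(), pos = integer(),
                   ref = character(), alt = character(), gene = character(),
                   func_class = character(), stringsAsFactors = FALSE)
  for (col in annotation_columns()) df[[col]] <- numeric()
  for (col in predictor_columns()) df[[col]] <- character()
  df$cascade_stage <- integer()
  df
}

empty_calls <- function() {
  data.frame(key = character(), sample_id = character(),
             zygosity = character(), gq = integer(), dp = integer(),
             ad1 = integer(), ad2 = integer(), stringsAsFactors = FALSE)
}

#' Assemble an exome cohort object
#'
#' The central container: a variant table (site, gene, functional class and
#' annotations), a long table of per-sample genotype calls, and the sample
#' order of the source file. One call row exists per variant x sample.
#'
#' @param variants Data frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   optionally `gene`, `func_class`, MAF columns (`maf_kg1000`, ...),
#'   predictor columns (`pred_sift`, ...), `cadd_phred`, `revel`,
#'   `cascade_stage`.
#' @param calls Data frame with `key`, `sample_id`, `zygosity`, `gq`, `dp`,
#'   `ad1`, `ad2`.
#' @param samples Character vector giving sample order.
#' @return An object of class `exo_cohort`.
#' @export
exo_cohort <- function(variants, calls, samples) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(variants) > 0 && is.null(variants$key)) {
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  }
  if (is.null(variants$gene)) variants$gene <- rep(NA_character_, nrow(variants))
  if (is.null(variants$func_class)) {
    variants$func_class <- rep(NA_character_, nrow(variants))
  }
  for (col in c(maf_columns(), "cadd_phred", "revel")) {
    if (is.null(variants[[col]])) variants[[col]] <- rep(NA_real_, nrow(variants))
  }
  for (col in predictor_columns()) {
    if (is.null(variants[[col]])) variants[[col]] <- rep(NA_character_, nrow(variants))
  }
  if (is.null(variants$cascade_stage)) {
    variants$cascade_stage <- rep(NA_integer_, nrow(variants))
  }
  validate_cohort(structure(
    list(variants = variants, calls = calls, samples = as.character(samples)),
    class = "exo_cohort"))
}

validate_cohort <- function(x) {
  v <- x$variants
  if (anyDuplicated(v$key)) {
    stop("duplicate variant keys (chrom:pos:ref:alt must be unique): ",
         paste(unique(v$key[duplicated(v$key)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(v) > 0 && any(v$pos < 1, na.rm = TRUE)) {
    stop("variant positions must be 1-based (pos >= 1)", call. = FALSE)
  }
  bad_maf <- unlist(lapply(maf_columns(), function(col) {
    m <- v[[col]]
    m[!is.na(m) & (m < 0 | m > 1)]
  }))
  if (length(bad_maf)) stop("MAF values must lie in [0, 1]", call. = FALSE)
  if (any(!is.na(v$revel) & (v$revel < 0 | v$revel > 1))) {
    stop("REVEL scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(v$cadd_phred) & v$cadd_phred < 0)) {
    stop("CADD Phred scores must be non-negative", call. = FALSE)
  }
  cz <- x$calls$zygosity
  if (length(cz) && !all(cz %in% zygosity_levels())) {
    stop("unknown zygosity label in calls", call. = FALSE)
  }
  n_expected <- nrow(v) * length(x$samples)
  if (nrow(x$calls) != n_expected) {
    stop("calls must hold one row per variant per sample (expected ",
         n_expected, ", got ", nrow(x$calls), ")", call. = FALSE)
  }
  x
}

#' @export
print.exo_cohort <- function(x, ...) {
  cat("<exo_cohort> ", nrow(x$variants), " variants x ",
      length(x$samples), " samples\n", sep = "")
  n_ann <- sum(!is.na(x$variants$cadd_phred) | !is.na(x$variants$revel))
  cat("  annotated (CADD or REVEL present): ", n_ann, "\n", sep = "")
  invisible(x)
}

# Subset a cohort to a set of variant keys, keeping every sample's call.
subset_cohort <- function(cohort, keys) {
  variants <- cohort$variants[cohort$variants$key %in% keys, , drop = FALSE]
  calls <- cohort$calls[cohort$calls$key %in% keys, , drop = FALSE]
  rownames(variants) <- NULL
  rownames(calls) <- NULL
  structure(list(variants = variants, calls = calls, samples = cohort$samples),
            class = "exo_cohort")
}

normalize_func_class <- function(x) {
  x <- tolower(as.character(x))
  x[!is.na(x) & !(x %in% func_class_levels())] <- "other"
  x
}

normalize_predictor_call <- function(x) {
  x <- tolower(as.character(x))
  x[x %in% c("d", "damaging", "deleterious", "p", "pathogenic")] <- "damaging"
  x[x %in% c("t", "tolerated", "b", "benign", "n", "neutral")] <- "tolerated"
  x[!is.na(x) & !(x %in% c("damaging", "tolerated"))] <- "unknown"
  x
}
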