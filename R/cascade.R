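# The prioritization cascade: primary selection -> het reliability ->
# rarity/functional class -> predictor consensus -> CADD/REVEL gate.

cascade_stage_names <- function() {
  c("input", "primary_selection", "het_reliability", "rare_functional",
    "predictor_consensus", "combined_gate")
}

#' Configuration for the prioritization cascade
#'
#' Defaults are the published operating point of the strategy: heterozygous
#' calls with GQ at the conventional VCF cap of 99 and depth >= 50; an
#' allele-balance ceiling of 0.3; MAF <= 1% in 1000 Genomes and ESP (ExAC
#' and gnomAD available by configuration); at least 4 of the 10 predictors
#' calling the variant damaging; CADD Phred > 20 (strict) and REVEL >= 0.75
#' (inclusive); missense and nonsense classes kept.
#'
#' `gq_min` is an inclusive bound: genotype quality is capped at 99 in
#' standard VCFs, so a strict `> 99` would select nothing; set `gq_min =
#' 100` to recover the strict reading.
#'
#' @param gq_min Minimum genotype quality (inclusive), default 99.
#' @param dp_min Minimum read depth (inclusive), default 50.
#' @param ratio_max Allele-balance ceiling (exclusive), default 0.3.
#' @param maf_max Maximum population MAF (inclusive), default 0.01.
#' @param maf_databases Databases consulted for rarity; default
#'   `c("kg1000", "esp")`, any subset of [maf_databases()].
#' @param consensus_k Minimum damaging votes, default 4.
#' @param cadd_min CADD Phred threshold (exclusive), default 20.
#' @param revel_min REVEL threshold (inclusive), default 0.75.
#' @param func_classes_kept Functional classes retained, default
#'   `c("missense", "nonsense")`.
#' @param missing_score_policy How a missing CADD or REVEL score meets the
#'   combined gate: `"fail"` (default; missing fails), `"pass_if_nonsense"`
#'   (missing passes for nonsense variants, which several predictors do not
#'   score), or `"pass"` (missing passes).
#' @return A validated list of class `cascade_config`.
#' @export
cascade_config <- function(gq_min = 99, dp_min = 50, ratio_max = 0.3,
                           maf_max = 0.01, maf_databases = c("kg1000", "esp"),
                           consensus_k = 4, cadd_min = 20, revel_min = 0.75,
                           func_classes_kept = c("missense", "nonsense"),
                           missing_score_policy = c("fail", "pass_if_nonsense",
                                                    "pass")) {
  missing_score_policy <- match.arg(missing_score_policy)
  cfg <- list(gq_min = gq_min, dp_min = dp_min, ratio_max = ratio_max,
              maf_max = maf_max, maf_databases = maf_databases,
              consensus_k = as.integer(consensus_k), cadd_min = cadd_min,
              revel_min = revel_min, func_classes_kept = func_classes_kept,
              missing_score_policy = missing_score_policy)
  nums <- c(cfg$gq_min, cfg$dp_min, cfg$ratio_max, cfg$maf_max,
            cfg$consensus_k, cfg$cadd_min, cfg$revel_min)
  if (any(!is.finite(nums))) stop("all thresholds must be finite", call. = FALSE)
  if (cfg$maf_max <= 0 || cfg$maf_max >= 1) {
    stop("maf_max must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$consensus_k < 1 || cfg$consensus_k > length(predictor_tools())) {
    stop("consensus_k must lie in 1..", length(predictor_tools()), call. = FALSE)
  }
  if (!all(cfg$maf_databases %in% maf_databases())) {
    stop("unknown MAF database: ",
         paste(setdiff(cfg$maf_databases, maf_databases()), collapse = ", "),
         call. = FALSE)
  }
  if (!all(cfg$func_classes_kept %in% func_class_levels())) {
    stop("unknown functional class in func_classes_kept", call. = FALSE)
  }
  structure(cfg, class = "cascade_config")
}

#' Primary selection: heterozygous, high-quality, well-covered calls
#'
#' The cascade's first gate under the dominant model: a call passes iff it
#' is heterozygous with `gq >= gq_min` and `dp >= dp_min`. Missing GQ or DP
#' fails.
#'
#' @param calls Data frame with `zygosity`, `gq`, `dp`.
#' @param cfg A [cascade_config()].
#' @return Logical vector, one element per call.
#' @export
passes_primary <- function(calls, cfg = cascade_config()) {
  !is.na(calls$zygosity) & calls$zygosity == "het" &
    !is.na(calls$gq) & calls$gq >= cfg$gq_min &
    !is.na(calls$dp) & calls$dp >= cfg$dp_min
}

#' Rarity filter over population frequency databases
#'
#' A variant is rare iff, in every consulted database, its MAF is missing
#' or `<= maf_max`. A variant absent from all databases (novel) is rare.
#'
#' @param ann Data frame with MAF columns `maf_kg1000`, `maf_esp`,
#'   `maf_exac`, `maf_gnomad` (an [exo_cohort()]'s `variants` table works).
#' @param cfg A [cascade_config()]; `cfg$maf_databases` selects the columns
#'   consulted.
#' @return Logical vector, one element per row.
#' @export
is_rare <- function(ann, cfg = cascade_config()) {
  out <- rep(TRUE, nrow(ann))
  for (db in cfg$maf_databases) {
    m <- ann[[paste0("maf_", db)]]
    if (is.null(m)) m <- rep(NA_real_, nrow(ann))
    out <- out & (is.na(m) | m <= cfg$maf_max)
  }
  out
}

#' Predictor consensus vote
#'
#' Counts `damaging` verdicts across the ten-tool panel; `tolerated`,
#' `unknown` and missing verdicts contribute nothing (a conservative rule:
#' an unscored variant accrues no support). The consensus passes at
#' `vote_count >= consensus_k`.
#'
#' @param ann Data frame with predictor columns `pred_sift`, ...,
#'   `pred_meta_lr`.
#' @param cfg A [cascade_config()].
#' @return Data frame with `vote_count` (integer) and `verdict` (logical).
#' @export
consensus_damaging <- function(ann, cfg = cascade_config()) {
  votes <- rep(0L, nrow(ann))
  for (col in predictor_columns()) {
    p <- ann[[col]]
    if (is.null(p)) next
    votes <- votes + as.integer(!is.na(p) & p == "damaging")
  }
  data.frame(vote_count = votes, verdict = votes >= cfg$consensus_k)
}

#' Joint CADD/REVEL gate
#'
#' The final annotation gate: `cadd_phred > cadd_min` (strict; >20 selects
#' roughly the 1% most deleterious substitutions genome-wide) and `revel >=
#' revel_min` (inclusive; >=0.75 is a high-specificity operating point for
#' rare missense variants). Missing scores are resolved by
#' `cfg$missing_score_policy`: under `"fail"` they fail, under `"pass"` they
#' pass, under `"pass_if_nonsense"` they pass only for nonsense variants
#' (which requires a `func_class` column in `ann`).
#'
#' @param ann Data frame with `cadd_phred` and `revel` columns.
#' @param cfg A [cascade_config()].
#' @return Logical vector, one element per row.
#' @export
passes_combined_gate <- function(ann, cfg = cascade_config()) {
  cadd <- ann$cadd_phred
  revel <- ann$revel
  if (is.null(cadd)) cadd <- rep(NA_real_, nrow(ann))
  if (is.null(revel)) revel <- rep(NA_real_, nrow(ann))
  policy <- cfg$missing_score_policy
  if (policy == "pass_if_nonsense" && is.null(ann$func_class)) {
    stop("missing_score_policy 'pass_if_nonsense' needs a func_class column",
         call. = FALSE)
  }
  missing_ok <- switch(policy,
    fail = rep(FALSE, length(cadd)),
    pass = rep(TRUE, length(cadd)),
    pass_if_nonsense = !is.na(ann$func_class) & ann$func_class == "nonsense")
  cadd_ok <- ifelse(is.na(cadd), missing_ok, cadd > cfg$cadd_min)
  revel_ok <- ifelse(is.na(revel), missing_ok, revel >= cfg$revel_min)
  cadd_ok & revel_ok
}

#' Run the full prioritization cascade
#'
#' Applies, in order: primary selection (het, GQ, DP) per call; the
#' reliable-heterozygote allele-balance screen per call; functional-class
#' and rarity filters per variant; predictor consensus; and the joint
#' CADD/REVEL gate. A variant survives a per-call stage if at least one
#' sample's call survives. Every stage is a pure conjunctive predicate, so
#' the survivor set equals the one-shot conjunction of all predicates and
#' the cascade is idempotent on its own output.
#'
#' @param cohort An [exo_cohort()] with annotations joined.
#' @param cfg A [cascade_config()].
#' @return List with `survivors` (an `exo_cohort` whose variants carry
#'   `cascade_stage = 5`; calls retain every sample) and `report` (a
#'   `cascade_report` data frame with columns `stage`, `n_variants`,
#'   `n_genes`, `n_patients`, one row per stage including the input row;
#'   attribute `multi_hit` tabulates patients carrying >= 2 distinct
#'   surviving variants in one gene — under a dominant single-hit model a
#'   diagnostic, not a filter).
#' @export
run_cascade <- function(cohort, cfg = cascade_config()) {
  stopifnot(inherits(cohort, "exo_cohort"))
  v <- cohort$variants
  calls <- cohort$calls

  # per-call gates
  call_primary <- passes_primary(calls, cfg)
  call_reliable <- call_primary &
    classify_het(calls, dp_min = cfg$dp_min, ratio_max = cfg$ratio_max)$reliable

  surv_call <- function(ok) unique(calls$key[ok])
  # per-variant gates (annotation-level)
  var_func <- !is.na(v$func_class) & v$func_class %in% cfg$func_classes_kept
  var_rare <- is_rare(v, cfg)
  var_consensus <- consensus_damaging(v, cfg)$verdict
  var_gate <- passes_combined_gate(v, cfg)

  alive <- list()
  alive[[1]] <- v$key                                        # input
  alive[[2]] <- intersect(alive[[1]], surv_call(call_primary))
  alive[[3]] <- intersect(alive[[2]], surv_call(call_reliable))
  alive[[4]] <- intersect(alive[[3]], v$key[var_func & var_rare])
  alive[[5]] <- intersect(alive[[4]], v$key[var_consensus])
  alive[[6]] <- intersect(alive[[5]], v$key[var_gate])

  # patients: distinct samples whose surviving call sits in a live variant;
  # at the input stage, carriers of any non-reference call.
  carrier0 <- !is.na(calls$zygosity) & calls$zygosity %in% c("het", "hom_alt")
  patients <- function(stage_keys, ok) {
    length(unique(calls$sample_id[ok & calls$key %in% stage_keys]))
  }
  call_ok <- list(carrier0, call_primary, call_reliable, call_reliable,
                  call_reliable, call_reliable)
  genes_of <- function(keys) {
    g <- v$gene[v$key %in% keys]
    length(unique(g[!is.na(g)]))
  }
  report <- data.frame(
    stage = cascade_stage_names(),
    n_variants = vapply(alive, length, 0L),
    n_genes = vapply(alive, genes_of, 0L),
    n_patients = mapply(patients, alive, call_ok),
    stringsAsFactors = FALSE)
  if (any(diff(report$n_variants) > 0)) {
    stop("internal error: stage counts increased", call. = FALSE)  # nocov
  }
  class(report) <- c("cascade_report", "data.frame")

  survivors <- subset_cohort(cohort, alive[[6]])
  # tag: number of post-input stages passed (survivors have all 5)
  stage_of <- rep(0L, nrow(v))
  for (s in 2:6) stage_of[v$key %in% alive[[s]]] <- s - 1L
  survivors$variants$cascade_stage <-
    stage_of[match(survivors$variants$key, v$key)]

  attr(report, "multi_hit") <- multi_hit_table(survivors, call_reliable, calls)
  list(survivors = survivors, report = report)
}

# Patients with >= 2 distinct surviving variants in the same gene.
multi_hit_table <- function(survivors, call_reliable, all_calls) {
  sv <- survivors$variants
  sc <- all_calls[call_reliable & all_calls$key %in% sv$key, , drop = FALSE]
  if (nrow(sc) == 0) {
    return(data.frame(sample_id = character(), gene = character(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  }
  sc$gene <- sv$gene[match(sc$key, sv$key)]
  sc <- sc[!is.na(sc$gene), , drop = FALSE]
  tab <- unique(sc[, c("sample_id", "gene", "key")])
  agg <- stats::aggregate(key ~ sample_id + gene, data = tab,
                          FUN = function(k) length(unique(k)))
  names(agg)[names(agg) == "key"] <- "n_variants"
  agg <- agg[agg$n_variants >= 2, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
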