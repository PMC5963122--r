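# Synthetic annotated-VCF cohort generator with recorded ground truth.
#
# Emulates the statistical structure the cascade assumes: balanced
# binomial allele depths for true heterozygotes vs. skewed depths for
# artifact ("false") heterozygotes, negative-binomial coverage, a rare-
# tailed MAF spectrum with a point mass of novel variants, predictor /
# CADD / REVEL scores coupled through a shared latent pathogenicity, and
# an optional set of planted variants constructed to pass every filter.

#' Parameters for the synthetic cohort generator
#'
#' Defaults describe a 48-patient exome cohort at 40x mean on-target
#' coverage. `dp_dispersion` is the negative-binomial size parameter
#' (variance `mu + mu^2/size`); `Inf` fixes every depth at `dp_mean`,
#' which is what the screen-calibration experiments use.
#'
#' @param n_samples Patients in the cohort (default 48).
#' @param n_variants Variant sites (default 2000).
#' @param seed RNG seed; identical parameters and seed give identical
#'   cohorts and files.
#' @param dp_mean,dp_dispersion Negative-binomial read-depth model.
#' @param true_het_fraction Per call, probability of a genuine heterozygote.
#' @param false_het_fraction Per call, probability of an artifact het (a
#'   true homozygote mis-called heterozygous with skewed allele depths).
#' @param false_het_alt_fraction Expected minor-allele fraction of artifact
#'   hets, in (0, 0.5); default 0.1.
#' @param low_gq_fraction Fraction of calls given GQ below 99, so the
#'   primary GQ filter is exercised; all other calls sit at the cap.
#' @param rare_fraction Fraction of variants with population MAF <= 1%.
#' @param novel_fraction Within rare variants, fraction absent from every
#'   database (all MAFs missing).
#' @param maf_tail_shape Beta shape for the rare-MAF tail (smaller = more
#'   mass near 0).
#' @param predictor_damaging_rate Marginal per-tool damaging rate.
#' @param score_correlation In `[0, 1]`: coupling of predictor votes, CADD
#'   and REVEL through a shared latent pathogenicity.
#' @param n_planted Variants constructed to pass every default filter
#'   (including the bundled example gene lists); `<= n_variants`.
#' @return Validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_samples = 48, n_variants = 2000, seed = 1,
                              dp_mean = 40, dp_dispersion = 8,
                              true_het_fraction = 0.2,
                              false_het_fraction = 0.05,
                              false_het_alt_fraction = 0.1,
                              low_gq_fraction = 0.05,
                              rare_fraction = 0.5, novel_fraction = 0.3,
                              maf_tail_shape = 0.3,
                              predictor_damaging_rate = 0.15,
                              score_correlation = 0.7,
                              n_planted = 0) {
  p <- list(n_samples = as.integer(n_samples),
            n_variants = as.integer(n_variants), seed = as.integer(seed),
            dp_mean = dp_mean, dp_dispersion = dp_dispersion,
            true_het_fraction = true_het_fraction,
            false_het_fraction = false_het_fraction,
            false_het_alt_fraction = false_het_alt_fraction,
            low_gq_fraction = low_gq_fraction,
            rare_fraction = rare_fraction, novel_fraction = novel_fraction,
            maf_tail_shape = maf_tail_shape,
            predictor_damaging_rate = predictor_damaging_rate,
            score_correlation = score_correlation,
            n_planted = as.integer(n_planted))
  if (p$n_samples < 1 || p$n_variants < 1) {
    stop("n_samples and n_variants must be >= 1", call. = FALSE)
  }
  fracs <- c(p$true_het_fraction, p$false_het_fraction, p$low_gq_fraction,
             p$rare_fraction, p$novel_fraction, p$predictor_damaging_rate,
             p$score_correlation)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions and score_correlation must lie in [0, 1]", call. = FALSE)
  }
  if (p$true_het_fraction + p$false_het_fraction > 1) {
    stop("true_het_fraction + false_het_fraction must not exceed 1",
         call. = FALSE)
  }
  if (p$false_het_alt_fraction <= 0 || p$false_het_alt_fraction >= 0.5) {
    stop("false_het_alt_fraction must lie strictly in (0, 0.5)", call. = FALSE)
  }
  if (p$dp_mean <= 0 || p$dp_dispersion <= 0) {
    stop("dp_mean and dp_dispersion must be positive", call. = FALSE)
  }
  if (p$maf_tail_shape <= 0) stop("maf_tail_shape must be positive", call. = FALSE)
  if (p$n_planted < 0 || p$n_planted > p$n_variants) {
    stop("n_planted must lie in 0..n_variants", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

bundled_gene_lists <- function() {
  pd <- read_gene_set(system.file("extdata", "genes_pd.txt",
                                  package = "exocascade"), "PD")
  neuron <- read_gene_set(system.file("extdata", "genes_neuron.txt",
                                      package = "exocascade"), "neuron")
  list(pd, neuron)
}

#' Simulate an annotated cohort in memory
#'
#' The in-memory core of [generate_cohort()]: returns the cohort object and
#' its ground truth without touching disk. A single seeded RNG stream,
#' consumed in a fixed (variant-major) order, makes the output reproducible.
#'
#' @param params A [simulation_params()].
#' @return List with `cohort` (an [exo_cohort()]) and `truth` (data frame
#'   with one row per variant x sample: `key`, `sample_id`,
#'   `true_zygosity`, `is_false_het`, `is_planted`).
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(p$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  nv <- p$n_variants
  ns <- p$n_samples
  samples <- sprintf("P%03d", seq_len(ns))

  # -- variant sites -------------------------------------------------------
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  list_genes <- unique(unlist(lapply(bundled_gene_lists(), `[[`, "genes")))
  background <- sprintf("GENE%04d", seq_len(300))
  gene <- sample(c(background, list_genes), nv, replace = TRUE,
                 prob = c(rep(0.9 / length(background), length(background)),
                          rep(0.1 / length(list_genes), length(list_genes))))
  variants <- data.frame(
    chrom = as.character(sample(1:22, nv, replace = TRUE)),
    pos = sort(sample.int(5e7, nv)), ref = ref, alt = alt, gene = gene,
    func_class = sample(func_class_levels(), nv, replace = TRUE,
                        prob = c(0.5, 0.05, 0.3, 0.15)),
    stringsAsFactors = FALSE)
  variants$key <- variant_key(variants$chrom, variants$pos, ref, alt)

  # -- annotation scores coupled through latent pathogenicity --------------
  rho <- p$score_correlation
  mix <- function(z) rho * z + sqrt(1 - rho^2) * stats::rnorm(nv)
  z <- stats::rnorm(nv)
  variants$cadd_phred <- pmax(0, 12 + 8 * mix(z))
  variants$revel <- stats::plogis(-1.5 + 2.2 * mix(z))
  cut_dmg <- stats::qnorm(1 - p$predictor_damaging_rate)
  for (col in predictor_columns()) {
    lat <- mix(z)
    call <- ifelse(lat > cut_dmg, "damaging", "tolerated")
    call[stats::runif(nv) < 0.05] <- "unknown"
    variants[[col]] <- call
  }
  variants$cadd_phred[stats::runif(nv) < 0.05] <- NA_real_
  variants$revel[stats::runif(nv) < 0.05] <- NA_real_

  # -- MAF spectrum: rare tail + novel point mass --------------------------
  rare <- stats::runif(nv) < p$rare_fraction
  base_maf <- ifelse(rare,
                     0.01 * stats::rbeta(nv, p$maf_tail_shape, 1),
                     0.01 + 0.49 * stats::rbeta(nv, 2, 2))
  novel <- rare & (stats::runif(nv) < p$novel_fraction)
  for (col in maf_columns()) {
    m <- pmin(1, pmax(0, base_maf * stats::runif(nv, 0.85, 1.18)))
    m[novel | stats::runif(nv) < 0.1] <- NA_real_
    variants[[col]] <- m
  }

  # -- genotype calls (variant-major order) --------------------------------
  n <- nv * ns
  state <- sample(c("het", "false_het", "hom_ref"), n, replace = TRUE,
                  prob = c(p$true_het_fraction, p$false_het_fraction,
                           1 - p$true_het_fraction - p$false_het_fraction))
  dp <- if (is.infinite(p$dp_dispersion)) {
    rep(as.integer(round(p$dp_mean)), n)
  } else {
    pmax(1L, stats::rnbinom(n, size = p$dp_dispersion, mu = p$dp_mean))
  }
  ad1 <- integer(n)
  ad2 <- integer(n)
  i_het <- state == "het"
  ad1[i_het] <- stats::rbinom(sum(i_het), dp[i_het], 0.5)
  i_fh <- state == "false_het"
  minor <- stats::rbinom(sum(i_fh), dp[i_fh], p$false_het_alt_fraction)
  flip <- stats::runif(sum(i_fh)) < 0.5
  ad1[i_fh] <- ifelse(flip, dp[i_fh] - minor, minor)
  i_hr <- state == "hom_ref"
  ad1[i_hr] <- dp[i_hr]
  ad2 <- dp - ad1
  gq <- rep(99L, n)
  low <- stats::runif(n) < p$low_gq_fraction
  gq[low] <- sample(10:98, sum(low), replace = TRUE)

  calls <- data.frame(
    key = rep(variants$key, times = ns),
    sample_id = rep(samples, each = nv),
    zygosity = ifelse(state == "hom_ref", "hom_ref", "het"),
    gq = gq, dp = as.integer(dp), ad1 = as.integer(ad1),
    ad2 = as.integer(ad2), stringsAsFactors = FALSE)
  truth <- data.frame(
    key = calls$key, sample_id = calls$sample_id,
    true_zygosity = ifelse(state == "het", "het", "hom_ref"),
    is_false_het = state == "false_het",
    is_planted = FALSE, stringsAsFactors = FALSE)

  # -- planted candidates: constructed to pass every default filter --------
  planted_idx <- if (p$n_planted > 0) sample(nv, p$n_planted) else integer(0)
  for (i in planted_idx) {
    variants$func_class[i] <- "missense"
    variants$gene[i] <- sample(list_genes, 1)
    for (col in maf_columns()) {
      variants[[col]][i] <- if (stats::runif(1) < 0.7) NA_real_
                            else stats::runif(1, 0, 0.009)
    }
    n_dmg <- sample(5:10, 1)
    dmg_cols <- sample(predictor_columns(), n_dmg)
    for (col in predictor_columns()) {
      variants[[col]][i] <- if (col %in% dmg_cols) "damaging" else "tolerated"
    }
    variants$cadd_phred[i] <- stats::runif(1, 22, 40)
    variants$revel[i] <- stats::runif(1, 0.78, 0.99)
    carriers <- sample(ns, sample(1:3, 1))
    for (s in carriers) {
      row <- (s - 1L) * nv + i
      cdp <- 60L + stats::rpois(1, 25)
      repeat {
        a1 <- stats::rbinom(1, cdp, 0.5)
        if (abs(2 * a1 - cdp) / cdp < 0.3) break
      }
      calls$zygosity[row] <- "het"
      calls$gq[row] <- 99L
      calls$dp[row] <- cdp
      calls$ad1[row] <- a1
      calls$ad2[row] <- cdp - a1
      truth$true_zygosity[row] <- "het"
      truth$is_false_het[row] <- FALSE
    }
    truth$is_planted[truth$key == variants$key[i]] <- TRUE
  }

  list(cohort = exo_cohort(variants, calls, samples), truth = truth)
}

write_annotation_sidecar <- function(cohort, path,
                                     info_keys = default_info_keys()) {
  v <- cohort$variants
  out <- v[, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  for (col in setdiff(names(info_keys), "cascade_stage")) {
    out[[info_keys[[col]]]] <- v[[col]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Generate a synthetic cohort on disk
#'
#' Runs [simulate_cohort()] and writes three plain-text files into
#' `out_dir`: a genotype-only multi-sample VCF (`cohort.vcf`), an
#' annotation sidecar TSV (`annotations.tsv`) and the ground truth
#' (`truth.tsv`). Identical parameters (including seed) give byte-identical
#' files.
#'
#' @param params A [simulation_params()]; validated before any file is
#'   written.
#' @param out_dir Output directory, created if needed.
#' @return List with `vcf_path`, `sidecar_path`, `truth_path` and the
#'   `truth` data frame.
#' @export
generate_cohort <- function(params = simulation_params(), out_dir) {
  stopifnot(inherits(params, "simulation_params"))
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(params)
  vcf_path <- file.path(out_dir, "cohort.vcf")
  sidecar_path <- file.path(out_dir, "annotations.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  # genotypes in the VCF; annotations travel in the sidecar
  bare <- sim$cohort
  for (col in c("gene", "func_class", annotation_columns())) {
    bare$variants[[col]] <- bare$variants[[col]][NA]
  }
  write_vcf_text(bare, vcf_path)
  write_annotation_sidecar(sim$cohort, sidecar_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf_path = vcf_path, sidecar_path = sidecar_path,
       truth_path = truth_path, truth = sim$truth)
}

#' Read a ground-truth table written by [generate_cohort()]
#'
#' @param path Path to `truth.tsv`.
#' @return Data frame with `key`, `sample_id`, `true_zygosity`,
#'   `is_false_het`, `is_planted`.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Evaluate the reliable-heterozygote screen against ground truth
#'
#' Quantifies the allele-balance screen on a simulated cohort:
#' *sensitivity* is the fraction of genuine heterozygous calls the screen
#' retains, *specificity* the fraction of artifact heterozygotes it
#' rejects.
#'
#' @param cohort An [exo_cohort()] or a path to a cohort VCF.
#' @param truth Truth data frame (from [simulate_cohort()],
#'   [generate_cohort()] or [read_truth()]); must cover exactly the
#'   cohort's calls.
#' @param cfg A [cascade_config()] supplying `dp_min` and `ratio_max`.
#' @return List with `sensitivity`, `specificity` (each in `[0, 1]`, or
#'   `NA` when its denominator is empty), `n_true_het`, `n_false_het`.
#' @export
evaluate_screen <- function(cohort, truth, cfg = cascade_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "exo_cohort"))
  calls <- cohort$calls
  if (nrow(calls) == 0) {
    stop("cohort has no genotype calls to evaluate", call. = FALSE)
  }
  id_calls <- paste(calls$key, calls$sample_id)
  id_truth <- paste(truth$key, truth$sample_id)
  idx <- match(id_calls, id_truth)
  if (anyNA(idx) || length(id_truth) != length(id_calls)) {
    stop("truth table does not match the cohort's variant/sample keys",
         call. = FALSE)
  }
  tr <- truth[idx, , drop = FALSE]
  reliable <- classify_het(calls, dp_min = cfg$dp_min,
                           ratio_max = cfg$ratio_max)$reliable
  called_het <- !is.na(calls$zygosity) & calls$zygosity == "het"
  i_true <- called_het & tr$true_zygosity == "het" & !tr$is_false_het
  i_false <- called_het & tr$is_false_het
  sens <- if (any(i_true)) mean(reliable[i_true]) else NA_real_
  spec <- if (any(i_false)) mean(!reliable[i_false]) else NA_real_
  list(sensitivity = sens, specificity = spec,
       n_true_het = sum(i_true), n_false_het = sum(i_false))
}
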