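# The filter chain: primary selection, rarity, consensus, combined gate,
# and the staged cascade with per-stage accounting.

test_that("primary selection requires het zygosity, GQ and depth", {
  cfg <- cascade_config()
  calls <- rbind(
    genotype_call("a", "het", 99, 75, 33, 42),
    genotype_call("b", "hom_alt", 99, 200, 0, 200),
    genotype_call("c", "het", 98, 75, 40, 35),
    genotype_call("d", "het", 99, 49, 25, 24),
    genotype_call("e", "het", NA, 75, 40, 35))
  expect_equal(passes_primary(calls, cfg), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # the strict GQ > 99 reading stays available by configuration
  strict <- cascade_config(gq_min = 100)
  expect_false(passes_primary(calls[1, ], strict))
})

test_that("rarity consults the configured databases with missing = rare", {
  cfg <- cascade_config()   # kg1000 + esp
  ann <- data.frame(maf_kg1000 = c(0.0098, NA, 0.02, 0.005),
                    maf_esp = c(NA, NA, NA, 0.011),
                    maf_exac = c(0.5, NA, NA, 0.002),
                    maf_gnomad = NA_real_)
  expect_equal(is_rare(ann, cfg), c(TRUE, TRUE, FALSE, FALSE))
  # the boundary is inclusive: MAF exactly 1% is still rare
  expect_true(is_rare(data.frame(maf_kg1000 = 0.01, maf_esp = NA_real_), cfg))
  # consulting all four databases brings ExAC into play
  all4 <- cascade_config(maf_databases = maf_databases())
  expect_equal(is_rare(ann, all4), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("consensus counts damaging votes; unknown and missing count zero", {
  cfg <- cascade_config()
  mk <- function(calls) {
    ann <- as.data.frame(as.list(stats::setNames(calls,
                                                 paste0("pred_", predictor_tools()))),
                         stringsAsFactors = FALSE)
    ann
  }
  four <- mk(c(rep("damaging", 4), rep("tolerated", 6)))
  three <- mk(c(rep("damaging", 3), rep("unknown", 7)))
  all10 <- mk(rep("damaging", 10))
  res <- consensus_damaging(rbind(four, three, all10), cfg)
  expect_equal(res$vote_count, c(4L, 3L, 10L))
  expect_equal(res$verdict, c(TRUE, FALSE, TRUE))
})

test_that("the combined gate is strict on CADD and inclusive on REVEL", {
  cfg <- cascade_config()
  ann <- data.frame(cadd_phred = c(17.33, 24.3, 22.2, 20.0, 20.01, 25),
                    revel = c(0.595, 0.175, 0.731, 0.75, 0.75, NA))
  expect_equal(passes_combined_gate(ann, cfg),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("missing-score policy governs unscored variants", {
  ann <- data.frame(cadd_phred = c(NA, NA, 25), revel = c(NA, NA, NA),
                    func_class = c("nonsense", "missense", "nonsense"))
  expect_equal(passes_combined_gate(ann, cascade_config()),
               c(FALSE, FALSE, FALSE))
  expect_equal(
    passes_combined_gate(ann, cascade_config(missing_score_policy = "pass")),
    c(TRUE, TRUE, TRUE))
  expect_equal(
    passes_combined_gate(
      ann, cascade_config(missing_score_policy = "pass_if_nonsense")),
    c(TRUE, FALSE, TRUE))
  expect_error(
    passes_combined_gate(ann[, 1:2],
                         cascade_config(missing_score_policy = "pass_if_nonsense")),
    "func_class")
})

test_that("configuration is validated", {
  expect_error(cascade_config(consensus_k = 0), "consensus_k")
  expect_error(cascade_config(consensus_k = 11), "consensus_k")
  expect_error(cascade_config(maf_max = 0), "maf_max")
  expect_error(cascade_config(maf_databases = "hapmap"), "unknown MAF database")
  expect_error(cascade_config(cadd_min = Inf), "finite")
})

test_that("the staged cascade reports the hand-countable fixture correctly", {
  co <- make_small_cohort()
  res <- run_cascade(co)
  rep <- res$report
  expect_equal(rep$stage[1], "input")
  expect_equal(nrow(rep), 6)
  expect_equal(rep$n_variants, c(4, 4, 3, 1, 1, 1))
  # v1 is the only survivor: rare, missense, 7 votes, CADD 25.3, REVEL 0.91
  expect_equal(res$survivors$variants$key, "1:100:A:G")
  expect_equal(res$survivors$variants$cascade_stage, 5L)
  # monotone attrition
  expect_true(all(diff(rep$n_variants) <= 0))
  expect_true(all(diff(rep$n_patients) <= 0))
  # survivors retain one call per sample
  expect_equal(nrow(res$survivors$calls), length(co$samples))
})

test_that("an empty cohort yields a zero report, not an error", {
  empty <- exo_cohort(exocascade:::empty_variants(),
                      exocascade:::empty_calls(), c("S1"))
  res <- run_cascade(empty)
  expect_equal(nrow(res$survivors$variants), 0)
  expect_equal(res$report$n_variants, rep(0L, 6))
})

test_that("the cascade is idempotent on its own survivors", {
  sim <- simulate_cohort(simulation_params(n_samples = 8, n_variants = 400,
                                           seed = 21, n_planted = 4))
  res1 <- run_cascade(sim$cohort)
  res2 <- run_cascade(res1$survivors)
  expect_equal(sort(res2$survivors$variants$key),
               sort(res1$survivors$variants$key))
  expect_equal(res2$report$n_variants[1], res2$report$n_variants[6])
})

test_that("staged filtering equals the one-shot conjunction of predicates", {
  for (seed in c(101, 202, 303)) {
    sim <- simulate_cohort(simulation_params(
      n_samples = 6, n_variants = 500, seed = seed, n_planted = 3,
      dp_mean = 60))
    res <- run_cascade(sim$cohort)
    expect_equal(sort(res$survivors$variants$key),
                 conjunction_oracle_keys(sim$cohort))
  }
})

test_that("identical inputs give identical reports", {
  sim <- simulate_cohort(simulation_params(n_samples = 5, n_variants = 200,
                                           seed = 77))
  r1 <- run_cascade(sim$cohort)
  r2 <- run_cascade(sim$cohort)
  expect_identical(r1$report, r2$report)
})

test_that("multi-hit diagnostic finds patients with two variants in one gene", {
  co <- make_small_cohort()
  # add a second qualifying NPC1 variant carried by S1
  v2 <- co$variants[1, ]
  v2$chrom <- "5"; v2$pos <- 500L; v2$key <- "5:500:A:G"
  co2 <- exo_cohort(
    rbind(co$variants, v2),
    rbind(co$calls,
          cbind(genotype_call("S1", "het", 99, 80, 39, 41), key = "5:500:A:G"),
          cbind(genotype_call("S2", "hom_ref", 99, 70, 70, 0),
                key = "5:500:A:G")),
    co$samples)
  res <- run_cascade(co2)
  multi <- attr(res$report, "multi_hit")
  expect_equal(nrow(multi), 1)
  expect_equal(multi$sample_id, "S1")
  expect_equal(multi$gene, "NPC1")
  expect_equal(multi$n_variants, 2L)
})
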