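# Reading cohort VCFs, sidecar joining, writing candidates, round trips.

test_that("a small fixture VCF parses into the expected structure", {
  body <- c(
    paste("12", "40713899", ".", "C", "T", ".", "PASS",
          "GENE=LRRK2;FUNC_CLASS=missense;MAF_KG1000=0.001;CADD_PHRED=25.1;REVEL=0.8;PRED_SIFT=damaging",
          "GT:AD:DP:GQ", "0/1:33,42:75:99", "0/0:60,0:60:99", sep = "\t"),
    paste("1", "1000", ".", "G", "A", ".", "PASS", ".",
          "GT:DP:GQ", "0/1:55:90", "1/1:80:99", sep = "\t"),
    paste("2", "2000", ".", "T", "C", ".", "PASS", ".",
          "GT:AD:DP:GQ", "./.:.:.:.", "0/1:40,38:78:99", sep = "\t"))
  path <- write_fixture_vcf(fixture_vcf_lines(body))
  co <- read_cohort(path)

  expect_s3_class(co, "exo_cohort")
  expect_equal(nrow(co$variants), 3)
  expect_equal(co$samples, c("S1", "S2"))
  expect_equal(nrow(co$calls), 6)

  # the fully populated call round-trips its FORMAT fields
  c1 <- co$calls[co$calls$key == "12:40713899:C:T" &
                   co$calls$sample_id == "S1", ]
  expect_equal(c1$zygosity, "het")
  expect_equal(c(c1$gq, c1$dp, c1$ad1, c1$ad2), c(99L, 75L, 33L, 42L))

  # record without AD keeps the missing-data contract: NA, not 0
  c2 <- co$calls[co$calls$key == "1:1000:G:A" & co$calls$sample_id == "S1", ]
  expect_equal(c2$zygosity, "het")
  expect_true(is.na(c2$ad1) && is.na(c2$ad2))
  expect_equal(c2$dp, 55L)
  c2b <- co$calls[co$calls$key == "1:1000:G:A" & co$calls$sample_id == "S2", ]
  expect_equal(c2b$zygosity, "hom_alt")

  # missing genotype is distinct from any called state
  c3 <- co$calls[co$calls$key == "2:2000:T:C" & co$calls$sample_id == "S1", ]
  expect_equal(c3$zygosity, "missing")

  # INFO annotations land on the variant table
  v1 <- co$variants[co$variants$key == "12:40713899:C:T", ]
  expect_equal(v1$gene, "LRRK2")
  expect_equal(v1$func_class, "missense")
  expect_equal(v1$cadd_phred, 25.1)
  expect_equal(v1$pred_sift, "damaging")
  expect_true(is.na(co$variants$revel[co$variants$key == "1:1000:G:A"]))
})

test_that("multiallelic records are skipped with a warning, not dropped silently", {
  body <- c(
    paste("1", "100", ".", "A", "G", ".", "PASS", ".",
          "GT:AD:DP:GQ", "0/1:30,31:61:99", "0/0:50,0:50:99", sep = "\t"),
    paste("1", "200", ".", "C", "T,G", ".", "PASS", ".",
          "GT:AD:DP:GQ", "1/2:10,20,30:60:99", "0/1:25,30,0:55:99", sep = "\t"))
  path <- write_fixture_vcf(fixture_vcf_lines(body))
  expect_warning(co <- read_cohort(path), "1 multiallelic")
  expect_equal(co$variants$key, "1:100:A:G")
})

test_that("sidecar annotations join by key and win over INFO with a warning", {
  body <- paste("1", "100", ".", "A", "G", ".", "PASS",
                "GENE=OLD;CADD_PHRED=10", "GT:AD:DP:GQ",
                "0/1:30,31:61:99", "0/0:50,0:50:99", sep = "\t")
  path <- write_fixture_vcf(fixture_vcf_lines(body))
  sidecar <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tGENE\tCADD_PHRED\tREVEL\tPRED_SIFT",
               "1\t100\tA\tG\tNPC1\t24.5\t0.9\tD"), sidecar)
  expect_warning(co <- read_cohort(path, sidecar), "sidecar")
  expect_equal(co$variants$gene, "NPC1")        # sidecar precedence
  expect_equal(co$variants$cadd_phred, 24.5)
  expect_equal(co$variants$revel, 0.9)          # sidecar fills INFO gaps
  expect_equal(co$variants$pred_sift, "damaging")  # letter verdicts normalized
})

test_that("malformed input errors name the file", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("this is", "not a VCF"), bad)
  expect_error(read_cohort(bad), "failed to parse VCF")
  expect_error(read_cohort(tempfile(fileext = ".vcf")), "no such VCF")
})

test_that("write_candidates emits a valid empty VCF for an empty cohort", {
  empty <- exo_cohort(exocascade:::empty_variants(),
                      exocascade:::empty_calls(), c("S1", "S2"))
  out <- tempfile(fileext = ".vcf")
  expect_equal(write_candidates(empty, out), 0)
  lines <- readLines(out)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_match(lines[length(lines)], "^#CHROM\t.*S1\tS2$")
  back <- read_cohort(out)
  expect_equal(nrow(back$variants), 0)
  expect_equal(back$samples, c("S1", "S2"))
})

test_that("read-write-read is the identity on sites, calls and annotations", {
  sim <- simulate_cohort(simulation_params(n_samples = 4, n_variants = 60,
                                           seed = 303, n_planted = 2))
  co <- sim$cohort
  out1 <- tempfile(fileext = ".vcf")
  expect_equal(write_candidates(co, out1), 60)
  r1 <- read_cohort(out1)
  out2 <- tempfile(fileext = ".vcf")
  write_candidates(r1, out2)
  r2 <- read_cohort(out2)

  for (r in list(r1, r2)) {
    expect_equal(r$samples, co$samples)
    expect_equal(r$variants[order(r$variants$key),
                            setdiff(names(co$variants), "cascade_stage")],
                 co$variants[order(co$variants$key),
                             setdiff(names(co$variants), "cascade_stage")],
                 ignore_attr = TRUE)
    expect_equal(r$calls[order(r$calls$key, r$calls$sample_id), ],
                 co$calls[order(co$calls$key, co$calls$sample_id), ],
                 ignore_attr = TRUE)
  }
  # a missing REVEL stays missing, never coerced to 0
  miss <- is.na(co$variants$revel)
  if (any(miss)) {
    expect_true(all(is.na(
      r1$variants$revel[match(co$variants$key[miss], r1$variants$key)])))
  }
})

test_that("TSV output carries the variant table with NA kept blank", {
  sim <- simulate_cohort(simulation_params(n_samples = 2, n_variants = 10,
                                           seed = 5))
  out <- tempfile(fileext = ".tsv")
  expect_equal(write_candidates(sim$cohort, out), 10)
  tab <- read.delim(out, na.strings = c("NA", ""))
  expect_equal(nrow(tab), 10)
  expect_true(all(c("key", "gene", "cadd_phred", "revel") %in% names(tab)))
  expect_error(write_candidates(sim$cohort, tempfile(fileext = ".xls")),
               "vcf or .tsv")
})
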