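# Fixtures built in code: a tiny hand-countable cohort and inline VCF text.

write_fixture_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

fixture_vcf_lines <- function(body, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body)
}

# Deterministic in-memory cohort: 4 variants x 2 samples.
# v1: fully annotated candidate carried het by S1 (passes everything).
# v2: common variant (kg1000 MAF 0.2), otherwise strong scores.
# v3: skewed het in S1 (allele balance 0.786).
# v4: synonymous, weak scores, het in S2.
make_small_cohort <- function() {
  pred_damaging <- function(n_dmg) {
    calls <- rep("tolerated", 10)
    calls[seq_len(n_dmg)] <- "damaging"
    stats::setNames(as.list(calls), paste0("pred_", exocascade::predictor_tools()))
  }
  v <- data.frame(
    chrom = c("1", "2", "3", "4"), pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
    gene = c("NPC1", "MFN2", "GENE0001", "GENE0002"),
    func_class = c("missense", "missense", "missense", "synonymous"),
    maf_kg1000 = c(0.001, 0.2, NA, 0.005),
    maf_esp = c(NA, 0.15, NA, 0.004),
    maf_exac = c(0.0008, 0.2, NA, 0.005),
    maf_gnomad = c(NA, 0.21, NA, 0.004),
    cadd_phred = c(25.3, 28, 24, 3.1),
    revel = c(0.91, 0.88, 0.8, 0.05),
    stringsAsFactors = FALSE)
  for (i in seq_along(exocascade::predictor_tools())) {
    col <- paste0("pred_", exocascade::predictor_tools()[i])
    v[[col]] <- c(pred_damaging(7)[[col]], pred_damaging(9)[[col]],
                  pred_damaging(6)[[col]], pred_damaging(1)[[col]])
  }
  calls <- rbind(
    genotype_call("S1", "het", 99, 80, 41, 39),
    genotype_call("S1", "het", 99, 90, 44, 46),
    genotype_call("S1", "het", 99, 84, 76, 10),
    genotype_call("S1", "hom_ref", 99, 70, 70, 0),
    genotype_call("S2", "hom_ref", 99, 75, 75, 0),
    genotype_call("S2", "het", 99, 100, 52, 48),
    genotype_call("S2", "hom_ref", 99, 66, 66, 0),
    genotype_call("S2", "het", 99, 88, 43, 45))
  calls$key <- rep(exocascade:::variant_key(v$chrom, v$pos, v$ref, v$alt), 2)
  exo_cohort(v, calls, c("S1", "S2"))
}

# Independent one-shot conjunction oracle for the cascade: every predicate
# evaluated directly from the rule statements, in one pass, no staging.
conjunction_oracle_keys <- function(cohort, cfg = cascade_config()) {
  v <- cohort$variants
  c_ <- cohort$calls
  ratio <- abs(c_$ad1 - c_$ad2) / c_$dp
  call_ok <- !is.na(c_$zygosity) & c_$zygosity == "het" &
    !is.na(c_$gq) & c_$gq >= cfg$gq_min &
    !is.na(c_$dp) & c_$dp >= cfg$dp_min &
    !is.na(c_$ad1) & !is.na(c_$ad2) & !is.na(ratio) & ratio < cfg$ratio_max
  has_call <- v$key %in% c_$key[call_ok]
  maf_ok <- rep(TRUE, nrow(v))
  for (db in cfg$maf_databases) {
    m <- v[[paste0("maf_", db)]]
    maf_ok <- maf_ok & (is.na(m) | m <= cfg$maf_max)
  }
  votes <- rowSums(sapply(paste0("pred_", exocascade::predictor_tools()),
                          function(col) !is.na(v[[col]]) & v[[col]] == "damaging"))
  ok <- has_call &
    !is.na(v$func_class) & v$func_class %in% cfg$func_classes_kept &
    maf_ok &
    votes >= cfg$consensus_k &
    !is.na(v$cadd_phred) & v$cadd_phred > cfg$cadd_min &
    !is.na(v$revel) & v$revel >= cfg$revel_min
  sort(v$key[ok])
}
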