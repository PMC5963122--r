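# Cohort VCF input/output and sidecar annotation joining.
#
# Reading goes through vcfR; writing emits plain-text VCF v4.2 so that
# candidate files remain greppable and diffable.

#' Default INFO/sidecar key names for annotation transport
#'
#' Maps internal annotation column names to the INFO keys (and sidecar TSV
#' column headers) used on disk. Override entries to adapt to differently
#' named upstream annotation.
#'
#' @return Named character vector, internal column -> file key.
#' @export
default_info_keys <- function() {
  cols <- c("gene", "func_class", annotation_columns(), "cascade_stage")
  keys <- toupper(cols)
  names(keys) <- cols
  keys
}

parse_gt_zygosity <- function(gt) {
  # strip any trailing FORMAT payload vcfR left behind, split on / or |
  gt <- sub(":.*$", "", gt)
  out <- rep("missing", length(gt))
  parts <- strsplit(gt, "[/|]")
  n <- lengths(parts)
  a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".", "")
  a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".", "")
  diploid <- !is.na(gt) & n == 2 & a1 != "." & a2 != "."
  out[diploid & a1 == "0" & a2 == "0"] <- "hom_ref"
  out[diploid & a1 != "0" & a2 != "0"] <- "hom_alt"
  out[diploid & ((a1 == "0") != (a2 == "0"))] <- "het"
  out
}

#' Read a multi-sample cohort VCF with optional sidecar annotations
#'
#' Parses a VCF v4.2 file (plain or bgzipped) with per-sample `GT` and,
#' where present, `AD`, `DP`, `GQ` FORMAT fields into an [exo_cohort()].
#' Only biallelic records are retained: the allele-balance statistic is
#' defined for exactly two alleles, so multiallelic records are skipped
#' with a warning and a count (split them upstream if they matter).
#' Missing fields are kept as `NA`, never silently dropped.
#'
#' Annotations travel either as INFO keys (see [default_info_keys()]) or in
#' a sidecar tab-separated table keyed by `chrom`, `pos`, `ref`, `alt` with
#' the same column names. When both carry a value and they differ, the
#' sidecar wins with a warning.
#'
#' @param vcf_path Path to the VCF.
#' @param annotation_sidecar Optional path to the sidecar TSV.
#' @param info_keys Named character vector mapping internal annotation
#'   columns to INFO/sidecar keys; defaults to [default_info_keys()].
#' @return An [exo_cohort()].
#' @export
read_cohort <- function(vcf_path, annotation_sidecar = NULL,
                        info_keys = default_info_keys()) {
  if (!file.exists(vcf_path)) stop("no such VCF: ", vcf_path, call. = FALSE)
  con <- gzfile(vcf_path, "rt")
  head_lines <- tryCatch(readLines(con, n = 10000L), finally = close(con))
  if (length(head_lines) == 0 ||
      !grepl("^##fileformat=VCF", head_lines[1])) {
    stop("failed to parse VCF '", vcf_path,
         "': line 1 does not declare ##fileformat=VCF", call. = FALSE)
  }
  if (!any(grepl("^#CHROM\t", head_lines))) {
    stop("failed to parse VCF '", vcf_path, "': no #CHROM header line",
         call. = FALSE)
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", vcf_path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  samples <- if (!is.null(vcf@gt) && ncol(vcf@gt) > 1) {
    colnames(vcf@gt)[-1]
  } else character(0)

  if (nrow(fix) == 0) {
    cohort <- exo_cohort(empty_variants(), empty_calls(), samples)
    return(join_sidecar(cohort, annotation_sidecar, info_keys))
  }

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning("skipped ", sum(multi), " multiallelic record(s); ",
            "split them upstream to include them", call. = FALSE)
    vcf <- vcf[!multi, ]
    fix <- vcf@fix
  }
  if (nrow(fix) == 0) {
    cohort <- exo_cohort(empty_variants(), empty_calls(), samples)
    return(join_sidecar(cohort, annotation_sidecar, info_keys))
  }

  variants <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE)
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)

  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  }
  info_chr <- function(key) as.character(vcfR::extract.info(vcf, element = key))

  variants$gene <- info_chr(info_keys[["gene"]])
  variants$func_class <- normalize_func_class(info_chr(info_keys[["func_class"]]))
  for (col in c(maf_columns(), "cadd_phred", "revel")) {
    variants[[col]] <- info_num(info_keys[[col]])
  }
  for (col in predictor_columns()) {
    variants[[col]] <- normalize_predictor_call(info_chr(info_keys[[col]]))
  }
  cs <- info_num(info_keys[["cascade_stage"]])
  variants$cascade_stage <- as.integer(cs)

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  has_fmt <- function(el) any(grepl(paste0("(^|:)", el, "(:|$)"), vcf@gt[, "FORMAT"]))
  na_mat <- function() matrix(NA_character_, nrow = nrow(fix), ncol = length(samples))
  dp <- if (has_fmt("DP")) vcfR::extract.gt(vcf, "DP", as.numeric = TRUE) else na_mat()
  gq <- if (has_fmt("GQ")) vcfR::extract.gt(vcf, "GQ", as.numeric = TRUE) else na_mat()
  ad <- if (has_fmt("AD")) vcfR::extract.gt(vcf, "AD") else na_mat()
  ad1 <- suppressWarnings(vcfR::masplit(ad, record = 1, sort = 0, decreasing = 0))
  ad2 <- suppressWarnings(vcfR::masplit(ad, record = 2, sort = 0, decreasing = 0))

  nv <- nrow(variants)
  ns <- length(samples)
  calls <- data.frame(
    key = rep(variants$key, times = ns),
    sample_id = rep(samples, each = nv),
    zygosity = parse_gt_zygosity(as.vector(gt_raw)),
    gq = as.integer(round(as.vector(gq))),
    dp = as.integer(round(as.vector(dp))),
    ad1 = as.integer(round(as.vector(ad1))),
    ad2 = as.integer(round(as.vector(ad2))),
    stringsAsFactors = FALSE)

  cohort <- exo_cohort(variants, calls, samples)
  join_sidecar(cohort, annotation_sidecar, info_keys)
}

read_annotation_sidecar <- function(path, info_keys = default_info_keys()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("NA", ""))
  names(tab) <- tolower(names(tab))
  keycols <- c("chrom", "pos", "ref", "alt")
  if (!all(keycols %in% names(tab))) {
    stop("annotation sidecar must have columns chrom, pos, ref, alt",
         call. = FALSE)
  }
  out <- data.frame(key = variant_key(tab$chrom, tab$pos, tab$ref, tab$alt),
                    stringsAsFactors = FALSE)
  lower_keys <- tolower(info_keys)
  for (col in names(info_keys)) {
    file_col <- lower_keys[[col]]
    if (!file_col %in% names(tab)) next
    val <- tab[[file_col]]
    out[[col]] <- switch(col,
      gene = as.character(val),
      func_class = normalize_func_class(val),
      cascade_stage = as.integer(val),
      if (col %in% predictor_columns()) normalize_predictor_call(val)
      else suppressWarnings(as.numeric(val)))
  }
  if (anyDuplicated(out$key)) {
    stop("duplicate variant keys in annotation sidecar", call. = FALSE)
  }
  out
}

join_sidecar <- function(cohort, annotation_sidecar, info_keys) {
  if (is.null(annotation_sidecar)) return(cohort)
  side <- read_annotation_sidecar(annotation_sidecar, info_keys)
  v <- cohort$variants
  idx <- match(v$key, side$key)
  conflicts <- character(0)
  for (col in setdiff(names(side), "key")) {
    new <- side[[col]][idx]
    old <- v[[col]]
    clash <- !is.na(new) & !is.na(old) & new != old
    if (any(clash)) conflicts <- c(conflicts, col)
    v[[col]] <- ifelse(is.na(new), old, new)
  }
  if (length(conflicts)) {
    warning("sidecar annotation overrides differing INFO values for: ",
            paste(conflicts, collapse = ", "), call. = FALSE)
  }
  cohort$variants <- v
  cohort
}

# -- writing ---------------------------------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, digits = 15, scientific = FALSE, trim = TRUE))
}

vcf_header_lines <- function(samples, info_keys) {
  info_defs <- c(
    gene = "String,Description=\"Gene symbol\"",
    func_class = "String,Description=\"Functional class\"",
    cascade_stage = "Integer,Description=\"Last cascade stage passed\"")
  lines <- c("##fileformat=VCFv4.2",
             "##source=exocascade")
  for (col in names(info_keys)) {
    typ <- if (col %in% names(info_defs)) {
      info_defs[[col]]
    } else if (col %in% predictor_columns()) {
      "String,Description=\"Predictor verdict\""
    } else {
      "Float,Description=\"Annotation score\""
    }
    lines <- c(lines, sprintf("##INFO=<ID=%s,Number=1,Type=%s>",
                              info_keys[[col]], typ))
  }
  lines <- c(lines,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  lines
}

zygosity_to_gt <- function(z) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[z]
}

format_info_field <- function(variants, info_keys) {
  parts <- lapply(names(info_keys), function(col) {
    val <- variants[[col]]
    if (is.null(val)) return(rep(NA_character_, nrow(variants)))
    chr <- if (is.numeric(val)) fmt_num(val) else as.character(val)
    ifelse(is.na(chr), NA_character_, paste0(info_keys[[col]], "=", chr))
  })
  apply(do.call(cbind, parts), 1, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) "." else paste(p, collapse = ";")
  })
}

write_vcf_text <- function(cohort, path, info_keys = default_info_keys()) {
  v <- cohort$variants
  calls <- cohort$calls
  lines <- vcf_header_lines(cohort$samples, info_keys)
  if (nrow(v) > 0) {
    info <- format_info_field(v, info_keys)
    int_or_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
    sample_cols <- lapply(cohort$samples, function(s) {
      sc <- calls[calls$sample_id == s, , drop = FALSE]
      sc <- sc[match(v$key, sc$key), , drop = FALSE]
      ad <- ifelse(is.na(sc$ad1) & is.na(sc$ad2), ".",
                   paste0(int_or_dot(sc$ad1), ",", int_or_dot(sc$ad2)))
      paste(zygosity_to_gt(sc$zygosity), ad, int_or_dot(sc$dp),
            int_or_dot(sc$gq), sep = ":")
    })
    body <- do.call(paste, c(list(v$chrom, v$pos, ".", v$ref, v$alt, ".",
                                  "PASS", info, "GT:AD:DP:GQ"),
                             sample_cols, sep = "\t"))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write candidate variants to VCF or TSV
#'
#' Emits the given cohort's records. With a `.vcf` extension a plain-text
#' VCF v4.2 file is written whose INFO field carries the annotations and the
#' `CASCADE_STAGE` tag; `read_cohort()` on the result reproduces sites,
#' calls and annotations field for field. With a `.tsv` extension a flat
#' variant table (one row per variant, annotation columns included) is
#' written instead. Missing values are encoded as absent keys / `NA`, never
#' as 0.
#'
#' @param cohort An [exo_cohort()] (e.g. the `survivors` from
#'   [run_cascade()]).
#' @param out_path Output path ending in `.vcf` or `.tsv`.
#' @param info_keys Key mapping, see [default_info_keys()].
#' @return Number of variant records written, invisibly.
#' @export
write_candidates <- function(cohort, out_path, info_keys = default_info_keys()) {
  stopifnot(inherits(cohort, "exo_cohort"))
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "vcf") {
    write_vcf_text(cohort, out_path, info_keys)
  } else if (ext == "tsv") {
    utils::write.table(cohort$variants, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    stop("out_path must end in .vcf or .tsv", call. = FALSE)
  }
  invisible(nrow(cohort$variants))
}
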