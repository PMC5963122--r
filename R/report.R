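# Stage-by-stage funnel rendering and run manifests.

#' Render the cascade funnel as text and TSV
#'
#' Produces the human-readable funnel table (stage, surviving variants,
#' distinct genes, patients carrying a survivor) and, when `out_dir` is
#' given, machine-readable TSV artifacts carrying the identical numbers:
#' `report.tsv`, plus `summary.tsv` when a cohort summary is supplied.
#'
#' @param report A `cascade_report` from [run_cascade()].
#' @param summary Optional [summarize_cohort()] result.
#' @param out_dir Optional directory for the TSV artifacts.
#' @return List with `text` (character lines), and `report_path` /
#'   `summary_path` when written.
#' @export
render_report <- function(report, summary = NULL, out_dir = NULL) {
  stopifnot(is.data.frame(report))
  w <- max(nchar(report$stage), nchar("stage"))
  fmt <- paste0("  %-", w, "s  %10s  %8s  %9s")
  text <- c("Prioritization funnel:",
            sprintf(fmt, "stage", "variants", "genes", "patients"),
            sprintf(fmt, report$stage, report$n_variants, report$n_genes,
                    report$n_patients))
  multi <- attr(report, "multi_hit")
  if (!is.null(multi)) {
    text <- c(text, if (nrow(multi) == 0) {
      "  (no patient carries two surviving variants in one gene)"
    } else {
      c("  patients with >=2 surviving variants in one gene:",
        sprintf("    %s  %s  (%d variants)", multi$sample_id, multi$gene,
                multi$n_variants))
    })
  }
  if (!is.null(summary)) {
    text <- c(text, "", utils::capture.output(print(summary)))
  }
  out <- list(text = text)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out$report_path <- file.path(out_dir, "report.tsv")
    utils::write.table(as.data.frame(report), out$report_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(summary)) {
      out$summary_path <- file.path(out_dir, "summary.tsv")
      flat <- data.frame(
        metric = c("n_candidate_variants", "n_candidate_genes",
                   "n_patients_with_candidate", "pct_patients_with_candidate",
                   "n_patients_with_two_genes", "cohort_size"),
        value = c(summary$n_candidate_variants, summary$n_candidate_genes,
                  summary$n_patients_with_candidate,
                  summary$pct_patients_with_candidate,
                  summary$n_patients_with_two_genes, summary$cohort_size))
      utils::write.table(flat, out$summary_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  out
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the frozen configuration,
#' MD5 digests of the input files, the package version, a timestamp, and
#' the per-stage survivor counts.
#'
#' @param out_dir Directory receiving `manifest.json`.
#' @param cfg The [cascade_config()] used.
#' @param inputs Named character vector/list of input file paths.
#' @param report The `cascade_report`.
#' @return Path to the manifest, invisibly.
#' @export
write_run_manifest <- function(out_dir, cfg, inputs, report) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  digests <- lapply(inputs, function(p) {
    list(path = p, md5 = unname(tools::md5sum(p)))
  })
  manifest <- list(
    tool = "exocascade",
    version = as.character(utils::packageVersion("exocascade")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    inputs = digests,
    stages = as.data.frame(report))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
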