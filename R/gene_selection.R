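# Keyword-gene-set functional selection and cohort-level summaries.
#
# In place of a proprietary literature-network query, candidate genes are
# selected against explicit, versionable gene lists: one plain-text file of
# symbols per keyword.

#' Construct a keyword gene set
#'
#' @param keyword Non-empty label (e.g. `"PD"`, `"neuron"`).
#' @param genes Character vector of gene symbols; deduplicated,
#'   case-insensitive (stored uppercase).
#' @return List of class `gene_set` with elements `keyword` and `genes`.
#' @export
gene_set <- function(keyword, genes) {
  keyword <- as.character(keyword)
  if (length(keyword) != 1 || is.na(keyword) || !nzchar(keyword)) {
    stop("gene set keyword must be a non-empty string", call. = FALSE)
  }
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  structure(list(keyword = keyword, genes = genes), class = "gene_set")
}

#' Read a gene set from a plain-text file
#'
#' One symbol per line; blank lines and `#` comments are ignored. Matching
#' downstream is exact and case-insensitive; no alias resolution is
#' attempted, so lists should use current HGNC-style symbols.
#'
#' @param path File of gene symbols.
#' @param keyword Label for the set; defaults to the file name stem.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, keyword = NULL) {
  if (!file.exists(path)) stop("no such gene-set file: ", path, call. = FALSE)
  if (is.null(keyword)) keyword <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  gene_set(keyword, lines[nzchar(trimws(lines))])
}

as_gene_set_list <- function(sets) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (!is.list(sets) || length(sets) == 0) {
    stop("supply at least one gene set", call. = FALSE)
  }
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_set")) return(s)
    kw <- names(sets)[i]
    if (is.null(kw) || !nzchar(kw)) {
      stop("gene sets given as plain vectors must be named by keyword",
           call. = FALSE)
    }
    gene_set(kw, s)
  })
  for (s in sets) {
    if (length(s$genes) == 0) {
      stop("gene set '", s$keyword, "' is empty; an empty set would filter ",
           "everything — omit the filter instead", call. = FALSE)
    }
  }
  sets
}

#' Select surviving variants whose gene matches any keyword gene set
#'
#' A survivor is selected iff its gene symbol appears in the union of the
#' supplied sets (case-insensitive exact match). Alongside the selection,
#' reports which selected genes each keyword matched, and the genes matched
#' by *every* keyword — the strongest functional candidates.
#'
#' @param survivors An [exo_cohort()] (typically [run_cascade()]'s
#'   survivors).
#' @param sets A [gene_set()], a list of them, or a named list of symbol
#'   vectors (names = keywords).
#' @return List with `selected` (an `exo_cohort`), `per_keyword` (named list
#'   keyword -> selected genes matched), and `both` (genes matched by all
#'   keywords, restricted to selected genes).
#' @export
filter_by_gene_sets <- function(survivors, sets) {
  stopifnot(inherits(survivors, "exo_cohort"))
  sets <- as_gene_set_list(sets)
  genes_upper <- toupper(survivors$variants$gene)
  union_genes <- unique(unlist(lapply(sets, `[[`, "genes")))
  hit <- !is.na(genes_upper) & genes_upper %in% union_genes
  selected <- subset_cohort(survivors, survivors$variants$key[hit])
  sel_genes <- unique(toupper(selected$variants$gene))
  per_keyword <- lapply(sets, function(s) sort(intersect(sel_genes, s$genes)))
  names(per_keyword) <- vapply(sets, `[[`, "", "keyword")
  both <- sort(Reduce(intersect, c(list(sel_genes), lapply(sets, `[[`, "genes"))))
  list(selected = selected, per_keyword = per_keyword, both = both)
}

#' Summarize candidate variants across a patient cohort
#'
#' Cohort-level accounting of the final candidate set: how many variants
#' and genes remain, how many patients carry at least one candidate (as a
#' heterozygote, per the dominant model), how many carry candidates in two
#' or more distinct genes, and which genes recur with multiple distinct
#' variants.
#'
#' @param selected An [exo_cohort()] of selected candidate variants.
#' @param cohort_size Number of patients in the full cohort (>= 1).
#' @param both_keyword_genes Optional character vector of genes matched by
#'   all keywords, carried through for reporting.
#' @return List of class `cohort_summary`: `n_candidate_variants`,
#'   `n_candidate_genes`, `n_patients_with_candidate`,
#'   `pct_patients_with_candidate` (percentage, full precision; round for
#'   display), `n_patients_with_two_genes`, `genes_with_multiple_variants`
#'   (named integer vector, genes with >= 2 distinct variants),
#'   `both_keyword_genes`, `cohort_size`.
#' @export
summarize_cohort <- function(selected, cohort_size,
                             both_keyword_genes = character(0)) {
  stopifnot(inherits(selected, "exo_cohort"))
  if (!is.numeric(cohort_size) || cohort_size < 1) {
    stop("cohort_size must be >= 1", call. = FALSE)
  }
  v <- selected$variants
  carriers <- selected$calls[!is.na(selected$calls$zygosity) &
                               selected$calls$zygosity == "het", , drop = FALSE]
  carriers$gene <- v$gene[match(carriers$key, v$key)]
  pat <- unique(carriers$sample_id)
  genes_per_patient <- tapply(carriers$gene[!is.na(carriers$gene)],
                              carriers$sample_id[!is.na(carriers$gene)],
                              function(g) length(unique(g)))
  per_gene <- tapply(v$key[!is.na(v$gene)], v$gene[!is.na(v$gene)],
                     function(k) length(unique(k)))
  multi <- per_gene[!is.na(per_gene) & per_gene >= 2]
  structure(list(
    n_candidate_variants = nrow(v),
    n_candidate_genes = length(unique(v$gene[!is.na(v$gene)])),
    n_patients_with_candidate = length(pat),
    pct_patients_with_candidate = 100 * length(pat) / cohort_size,
    n_patients_with_two_genes = sum(genes_per_patient >= 2),
    genes_with_multiple_variants =
      stats::setNames(as.integer(multi), names(multi)),
    both_keyword_genes = both_keyword_genes,
    cohort_size = as.integer(cohort_size)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", x$cohort_size, " patients)\n", sep = "")
  cat("  candidate variants: ", x$n_candidate_variants,
      " in ", x$n_candidate_genes, " genes\n", sep = "")
  cat("  patients with >=1 candidate: ", x$n_patients_with_candidate,
      " (", round(x$pct_patients_with_candidate), "%)\n", sep = "")
  cat("  patients with candidates in >=2 genes: ",
      x$n_patients_with_two_genes, "\n", sep = "")
  if (length(x$genes_with_multiple_variants)) {
    cat("  genes with multiple distinct variants: ",
        paste(names(x$genes_with_multiple_variants),
              x$genes_with_multiple_variants, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$both_keyword_genes)) {
    cat("  genes matched by every keyword: ",
        paste(x$both_keyword_genes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
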