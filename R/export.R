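## Exporters and plot-data preparation: Krona text, per-matrix TSV tables,
## top-N summaries for stacked barplots, heatmap matrices and
## function-by-taxon breakdowns. All exporters are pure (the project is
## never mutated) and byte-stable across runs (no timestamps in data
## files).

#' Top-N rows of an abundance matrix with an "Other" remainder
#'
#' Ranks rows by descending row mean (ties broken lexicographically by
#' label) and keeps the first `n`; the excluded rows are collapsed into a
#' terminal `"Other"` row, so column sums are conserved exactly. When `n`
#' covers all rows, no `"Other"` row is added.
#'
#' @param matrix Numeric features x samples matrix.
#' @param n Number of rows to keep (>= 1).
#' @param other_label Label of the remainder row.
#' @return The summarised matrix.
#' @export
top_features <- function(matrix, n, other_label = "Other") {
  abort_if(n < 1, "n must be >= 1")
  m <- as.matrix(matrix)
  ord <- order(-rowMeans(m), rownames(m))
  m <- m[ord, , drop = FALSE]
  if (n >= nrow(m)) return(m)
  head_m <- m[seq_len(n), , drop = FALSE]
  other <- colSums(m[-seq_len(n), , drop = FALSE])
  rbind(head_m, matrix(other, nrow = 1,
                       dimnames = list(other_label, colnames(m))))
}

.sanitize_cell <- function(x) gsub("[\t\n\r]+", " ", x)

#' Export per-sample Krona text files
#'
#' Writes, for every sample, a tab-delimited file in the `ktImportText`
#' convention: first column the mapped read count, following columns the
#' lineage names from superkingdom downward. One line per distinct ORF
#' lineage plus an `Unclassified` line, so the first column sums to the
#' sample's mapped reads. Files are named `<sample>.krona.tsv`.
#'
#' @param project An `mg_project`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
export_krona <- function(project, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(out_dir), "cannot create directory %s", out_dir)
  ot <- project$orfs$table
  lin <- ot$tax
  lin[is.na(lin)] <- ""
  paths <- character(0)
  for (s in project$samples) {
    counts <- rowsum(project$orfs$reads[, s], lin)
    labels <- rownames(counts)
    lines <- character(0)
    for (i in seq_along(labels)) {
      if (counts[i] == 0) next
      if (!nzchar(labels[i])) {
        cols <- .UNCLASSIFIED
      } else {
        parts <- split_lineage(labels[i])
        cols <- .sanitize_cell(parts[!is.na(parts)])
      }
      lines <- c(lines, paste(c(fmt_num(counts[i]), cols),
                              collapse = "\t"))
    }
    path <- file.path(out_dir, paste0(s, ".krona.tsv"))
    con <- file(path, open = "wb")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Heatmap-ready matrix for selected functions
#'
#' Extracts the requested functions' TPM or copy-number rows from one
#' database profile, untransformed, optionally log10(x + pseudocount)
#' transformed, with row/column orders from average-linkage hierarchical
#' clustering of Euclidean distances (or the given order).
#'
#' @param project An `mg_project`.
#' @param function_ids Function identifiers, or a single hierarchy pattern
#'   prefixed `"hierarchy:"` to select every function under a category
#'   (case-insensitive substring against the hierarchy path).
#' @param metric `"tpm"` or `"copy_number"`.
#' @param db Database name (default `"KEGG"`).
#' @param log10_transform Apply `log10(x + pseudocount)`.
#' @param pseudocount Pseudocount for the transform (recorded in the
#'   output).
#' @param cluster Order rows/columns by hierarchical clustering.
#' @return List: `matrix`, `row_order`, `col_order`, `metric`,
#'   `log10_transform`, `pseudocount`.
#' @export
function_heatmap_data <- function(project, function_ids,
                                  metric = c("tpm", "copy_number"),
                                  db = "KEGG", log10_transform = FALSE,
                                  pseudocount = 1, cluster = TRUE) {
  metric <- match.arg(metric)
  abort_if(!(db %in% names(project$functions)),
           "unknown annotation database '%s'", db)
  prof <- project$functions[[db]]
  if (length(function_ids) == 1L &&
      startsWith(function_ids, "hierarchy:")) {
    pat <- sub("^hierarchy:", "", function_ids)
    keep <- grepl(tolower(pat), tolower(prof$info$hierarchy), fixed = TRUE)
    function_ids <- prof$info$id[keep]
    abort_if(length(function_ids) == 0,
             "no function under hierarchy pattern '%s'", pat)
  }
  unknown <- setdiff(function_ids, rownames(prof[[metric]]))
  abort_if(length(unknown) > 0, "unknown function id(s): %s",
           paste(unknown, collapse = ", "))
  m <- prof[[metric]][function_ids, , drop = FALSE]
  if (log10_transform) m <- log10(m + pseudocount)
  row_order <- rownames(m)
  col_order <- colnames(m)
  if (cluster && nrow(m) > 2) {
    row_order <- rownames(m)[stats::hclust(stats::dist(m),
                                           method = "average")$order]
  }
  if (cluster && ncol(m) > 2) {
    col_order <- colnames(m)[stats::hclust(stats::dist(t(m)),
                                           method = "average")$order]
  }
  list(matrix = m, row_order = row_order, col_order = col_order,
       metric = metric, log10_transform = log10_transform,
       pseudocount = if (log10_transform) pseudocount else NA_real_)
}

#' Function-by-taxon weight table
#'
#' For each function pattern: selects the matching ORFs (as
#' [subset_fun()]), aggregates their reads by taxonomy at `rank`, and
#' expresses them as a percentage of each sample's total sequenced reads.
#' Per pattern and sample, the values sum to that pattern's total weight in
#' percent of reads. Patterns with zero matches yield a zero-filled block
#' and a warning, so multi-panel figures stay aligned.
#'
#' @param project An `mg_project`.
#' @param fun_patterns Character vector of patterns (named entries label
#'   the output blocks).
#' @param rank Taxonomic rank for the breakdown.
#' @param use_regex,search_hierarchy As in [subset_fun()].
#' @return Long data frame: `pattern`, `taxon`, `sample`, `percent`.
#' @export
function_by_taxon_data <- function(project, fun_patterns, rank = "genus",
                                   use_regex = FALSE,
                                   search_hierarchy = TRUE) {
  rank <- match.arg(rank, mg_ranks())
  labels <- names(fun_patterns) %||% fun_patterns
  labels[!nzchar(labels)] <- fun_patterns[!nzchar(labels)]
  taxa <- rownames(project$taxonomy[[rank]]$reads)
  taxa <- setdiff(taxa, .UNMAPPED)
  out <- list()
  for (i in seq_along(fun_patterns)) {
    keep <- match_orfs_by_function(project, fun_patterns[i], use_regex,
                                   search_hierarchy)
    if (!any(keep)) {
      warning(sprintf("pattern '%s' matched no function; zero-filled",
                      fun_patterns[i]), call. = FALSE)
      block <- zero_matrix(taxa, project$samples)
    } else {
      tp <- aggregate_taxonomy(project$orfs$table[keep, , drop = FALSE],
                               project$orfs$reads[keep, , drop = FALSE],
                               rank, project$total_reads)
      block <- zero_matrix(taxa, project$samples)
      common <- intersect(taxa, rownames(tp$percent))
      block[common, ] <- tp$percent[common, , drop = FALSE]
    }
    out[[i]] <- data.frame(
      pattern = labels[i],
      taxon = rep(rownames(block), times = ncol(block)),
      sample = rep(colnames(block), each = nrow(block)),
      percent = as.vector(block),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export every profile matrix as TSV tables
#'
#' Writes one TSV per matrix under `out_dir` with stable names:
#' `orfs.tpm.tsv`, `contigs.tpm.tsv`, `fun.<db>.<metric>.tsv` for metric in
#' reads, bases, cov, tpm, copy_number, and `tax.<rank>.<metric>.tsv` for
#' reads and percent, plus a `metadata.json` sidecar recording the subset
#' provenance and the copy-number marker configuration. Files reload to
#' matrices equal within 1e-9 and are byte-identical across runs.
#'
#' @param project An `mg_project`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
export_tables <- function(project, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(out_dir), "cannot create directory %s", out_dir)
  written <- character(0)
  wm <- function(m, name) {
    df <- data.frame(Feature = .sanitize_cell(rownames(m)),
                     stringsAsFactors = FALSE, check.names = FALSE)
    for (s in colnames(m)) df[[s]] <- m[, s]
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    written <<- c(written, path)
  }
  wm(project$orfs$tpm, "orfs.tpm.tsv")
  wm(project$contigs$tpm, "contigs.tpm.tsv")
  for (db in names(project$functions)) {
    prof <- project$functions[[db]]
    for (metric in c("reads", "bases", "cov", "tpm", "copy_number")) {
      if (!is.null(prof[[metric]])) {
        wm(prof[[metric]], sprintf("fun.%s.%s.tsv", db, metric))
      }
    }
  }
  for (rk in names(project$taxonomy)) {
    wm(project$taxonomy[[rk]]$reads, sprintf("tax.%s.reads.tsv", rk))
    wm(project$taxonomy[[rk]]$percent, sprintf("tax.%s.percent.tsv", rk))
  }
  meta <- list(project_name = project$project_name,
               samples = project$samples,
               provenance = project$provenance,
               marker_mode = project$config$marker_mode,
               usicg_list = project$config$usicg_list)
  meta_path <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, meta_path)
  invisible(written)
}

#' Read back a matrix written by [export_tables()]
#'
#' @param path A TSV written by [export_tables()].
#' @return Numeric matrix with feature rownames.
#' @export
read_exported_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
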