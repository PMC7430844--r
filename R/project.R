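## The mg_project container: an S3 list holding sample metadata, feature
## tables (ORFs, contigs, bins) with per-sample count matrices, and all
## aggregate profiles (taxonomy per rank, functions per database), plus the
## subset provenance that records which denominators the normalised metrics
## refer to.

.ORF_FIXED_COLS <- c("orf_id", "contig_id", "start", "stop", "strand",
                     "length_bp", "tax")

## Default per-project configuration; overridable via a YAML config file
## (keys marker_mode, usicg_list, taxonomy_source) or the `config` argument
## of the constructors.
default_config <- function() {
  list(marker_mode = "recA",
       usicg_list = default_usicgs(),
       taxonomy_source = "orf")
}

annotation_databases <- function(orf_table) {
  setdiff(colnames(orf_table), .ORF_FIXED_COLS)
}

## Build a full mg_project from feature tables + count matrices, recomputing
## every aggregate profile (taxonomy at all ranks, function profiles with
## TPM and copy numbers, ORF/contig TPM). This is the single recompute path
## shared by the loader, the subset operations, combine() and the fixture
## generator.
build_project <- function(project_name, samples, total_reads,
                          orfs, contigs, bins = NULL,
                          fun_info = NULL, config = NULL,
                          provenance = NULL) {
  config <- utils::modifyList(default_config(), config %||% list())
  total_reads <- stats::setNames(as.numeric(total_reads[samples]), samples)

  p <- list(project_name = project_name,
            samples = samples,
            total_reads = total_reads,
            orfs = orfs, contigs = contigs, bins = bins,
            fun_info = fun_info, config = config)
  p$databases <- annotation_databases(orfs$table)

  ## ORF- and contig-level TPM over their own full row universes.
  p$orfs$tpm <- compute_tpm(compute_rpk(orfs$reads, orfs$table$length_bp))
  p$contigs$tpm <- compute_tpm(compute_rpk(contigs$reads,
                                           contigs$table$length_bp))

  ## Bin coverage: summed member bases over summed member length.
  if (!is.null(bins) && nrow(bins$table)) {
    p$bins <- recompute_bin_abundance(bins, contigs, samples)
  }

  ## Taxonomy at every canonical rank.
  contig_tax <- stats::setNames(contigs$table$tax, contigs$table$contig_id)
  p$taxonomy <- lapply(stats::setNames(nm = mg_ranks()), function(rk) {
    aggregate_taxonomy(orfs$table, orfs$reads, rk, total_reads,
                       contig_tax = contig_tax,
                       source = config$taxonomy_source)
  })

  ## Function profiles per database, with TPM and copy numbers.
  p$functions <- lapply(stats::setNames(nm = p$databases), function(db) {
    compute_function_tpm(
      aggregate_functions(orfs$table, orfs$reads, orfs$bases, orfs$cov,
                          db, fun_info))
  })
  p$functions <- add_copy_numbers(p$functions, config)

  p$provenance <- provenance %||%
    list(origin = "full", rescaled_tpm = TRUE, rescaled_copy_number = TRUE,
         description = "full project")
  class(p) <- "mg_project"
  p
}

## Fill copy_number into every profile using the COG profile of the same
## universe as marker carrier. Soft failure (NA + warning) when the marker
## is absent: loading marker-free data must still succeed.
add_copy_numbers <- function(profiles, config) {
  cogp <- profiles[["COG"]]
  marker_ok <- !is.null(cogp) &&
    (config$marker_mode == "usicg_median" ||
       "COG0468" %in% rownames(cogp$cov))
  if (config$marker_mode == "usicg_median" && !is.null(cogp)) {
    marker_ok <- length(intersect(config$usicg_list,
                                  rownames(cogp$cov))) > 0
  }
  lapply(profiles, function(pr) {
    if (marker_ok) {
      compute_copy_number(pr, cog_profile = cogp,
                          mode = config$marker_mode,
                          usicg_list = config$usicg_list)
    } else {
      warning("no usable single-copy marker in the COG profile; ",
              "copy numbers set to NA", call. = FALSE)
      pr$copy_number <- pr$cov * NA_real_
      pr$marker <- list(mode = config$marker_mode, coverage = NULL)
      pr
    }
  })
}

recompute_bin_abundance <- function(bins, contigs, samples) {
  idx <- lapply(bins$members, function(cids) {
    match(cids, contigs$table$contig_id)
  })
  agg <- function(m) {
    out <- vapply(idx, function(i) colSums(m[i, , drop = FALSE]),
                  numeric(length(samples)))
    matrix(out, nrow = length(idx), ncol = length(samples), byrow = TRUE)
  }
  bins$reads <- agg(contigs$reads)
  bins$bases <- agg(contigs$bases)
  lens <- vapply(idx, function(i) sum(contigs$table$length_bp[i]),
                 numeric(1))
  bins$cov <- bins$bases / lens
  dimnames(bins$reads) <- dimnames(bins$bases) <- dimnames(bins$cov) <-
    list(bins$table$bin_id, samples)
  bins
}

#' Validate a project object against its structural invariants
#'
#' Checks referential integrity (ORFs point to existing contigs, bin members
#' exist, bins of one method are disjoint), arithmetic consistency
#' (ORF length equals stop - start + 1; coverage x length matches bases
#' within 0.5%; mapped reads never exceed total reads; no negative counts)
#' and profile coherence (percent columns sum to 100; rescaled TPM columns
#' sum to 1e6; the RecA marker's copy number is 1 where applicable).
#'
#' Violations are reported, never thrown.
#'
#' @param project An `mg_project`.
#' @return A data frame with columns `table`, `row`, `invariant`; zero rows
#'   when the project is valid.
#' @export
validate_project <- function(project) {
  v <- list()
  note <- function(table, row, invariant) {
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row,
                                       invariant = invariant,
                                       stringsAsFactors = FALSE)
  }
  ot <- project$orfs$table
  ct <- project$contigs$table
  samples <- project$samples

  ## sample order identical across matrices
  mats <- list(orf_reads = project$orfs$reads, orf_bases = project$orfs$bases,
               orf_cov = project$orfs$cov, contig_reads = project$contigs$reads)
  for (nm in names(mats)) {
    if (!identical(colnames(mats[[nm]]), samples)) {
      note(nm, "-", "sample columns differ from project sample order")
    }
  }

  miss <- !(ot$contig_id %in% ct$contig_id)
  for (i in which(miss)) {
    note("orfs", ot$orf_id[i], "contig_id not present in contig table")
  }
  bad_len <- ot$length_bp != (ot$stop - ot$start + 1L)
  for (i in which(bad_len)) {
    note("orfs", ot$orf_id[i], "length_bp != stop - start + 1")
  }
  if (any(project$orfs$reads < 0) || any(project$orfs$bases < 0)) {
    note("orfs", "-", "negative reads or bases")
  }
  ## coverage * length == bases within 0.5% (rounding tolerance)
  expected <- project$orfs$cov * ot$length_bp
  rel <- abs(expected - project$orfs$bases) /
    pmax(project$orfs$bases, 1)
  bad <- which(rowSums(rel > 0.005) > 0)
  for (i in utils::head(bad, 20)) {
    note("orfs", ot$orf_id[i], "coverage x length inconsistent with bases")
  }

  mapped <- colSums(project$orfs$reads)
  over <- mapped > project$total_reads + 1e-6
  for (s in samples[over]) {
    note("samples", s, "summed ORF reads exceed total_reads")
  }

  if (!is.null(project$bins) && nrow(project$bins$table)) {
    bt <- project$bins$table
    for (i in seq_len(nrow(bt))) {
      cids <- project$bins$members[[bt$bin_id[i]]]
      if (!all(cids %in% ct$contig_id)) {
        note("bins", bt$bin_id[i], "member contig absent from contig table")
      }
    }
    for (m in unique(bt$method)) {
      ids <- bt$bin_id[bt$method == m]
      all_members <- unlist(project$bins$members[ids])
      if (anyDuplicated(all_members)) {
        note("bins", m, "bins of one method share contigs")
      }
    }
  }

  ## percent columns sum to 100 when the reads universe is the parent's
  for (rk in names(project$taxonomy)) {
    s <- colSums(project$taxonomy[[rk]]$percent)
    if (any(abs(s - 100) > 1e-6)) {
      note("taxonomy", rk, "percent columns do not sum to 100")
    }
  }
  if (isTRUE(project$provenance$rescaled_tpm)) {
    for (db in names(project$functions)) {
      tpm <- project$functions[[db]]$tpm
      s <- colSums(tpm)
      live <- colSums(project$functions[[db]]$reads) > 0
      if (any(abs(s[live] - 1e6) > 1e-3)) {
        note("functions", db, "TPM columns do not sum to 1e6")
      }
    }
  }
  if (isTRUE(project$provenance$rescaled_copy_number) &&
      !is.null(project$functions[["COG"]]) &&
      identical(project$config$marker_mode, "recA") &&
      "COG0468" %in% rownames(project$functions[["COG"]]$cov)) {
    cn <- project$functions[["COG"]]$copy_number["COG0468", ]
    ok <- is.na(cn) | cn == 1
    if (!all(ok)) note("functions", "COG0468", "marker copy number != 1")
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(table = character(0), row = character(0),
               invariant = character(0), stringsAsFactors = FALSE)
}

#' @export
summary.mg_project <- function(object, ...) {
  out <- list(project_name = object$project_name,
              n_orfs = nrow(object$orfs$table),
              n_contigs = nrow(object$contigs$table),
              n_bins = if (is.null(object$bins)) 0L else
                nrow(object$bins$table),
              n_samples = length(object$samples),
              samples = object$samples,
              total_reads = object$total_reads,
              mapped_reads = colSums(object$orfs$reads),
              databases = object$databases,
              provenance = object$provenance)
  class(out) <- "summary.mg_project"
  out
}

#' @export
print.summary.mg_project <- function(x, ...) {
  cat("Metagenomic project:", x$project_name, "\n")
  cat(sprintf("  %d ORFs on %d contigs (%d bins), %d samples\n",
              x$n_orfs, x$n_contigs, x$n_bins, x$n_samples))
  cat("  databases:", paste(x$databases, collapse = ", "), "\n")
  cat("  origin:", x$provenance$origin,
      if (isTRUE(x$provenance$rescaled_tpm)) "(TPM rescaled)" else
        "(TPM from parent)", "\n")
  df <- data.frame(sample = x$samples,
                   total_reads = unname(x$total_reads),
                   mapped_reads = unname(x$mapped_reads))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.mg_project <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
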