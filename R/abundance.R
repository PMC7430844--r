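## Abundance metrics: RPK, TPM, function-level aggregation, single-copy-gene
## copy numbers and taxonomy percentages.
##
## All functions operate on plain features x samples matrices so that the
## same code path serves ORF-, contig- and function-level profiles, in the
## full project and in any subset universe (the matrix passed in IS the
## denominator universe).

#' Default universal single-copy genes (USiCGs)
#'
#' Fifteen COG identifiers of single-copy ribosomal-protein and translation
#' genes, used as the default marker set for the `usicg_median` copy-number
#' mode. The list is a configuration value, not a constant of the method:
#' pass your own vector to [compute_copy_number()] or set `usicg_list` in the
#' project config to override it. Reports generated by the package record
#' the list actually used.
#'
#' @return Character vector of 15 COG identifiers.
#' @export
default_usicgs <- function() {
  c("COG0012", "COG0016", "COG0018", "COG0048", "COG0049",
    "COG0052", "COG0080", "COG0081", "COG0087", "COG0088",
    "COG0090", "COG0091", "COG0092", "COG0093", "COG0094")
}

#' Reads per kilobase (RPK)
#'
#' Divides each feature's mapped read count by the feature length in
#' kilobases: `rpk[f, s] = reads[f, s] / (length_bp[f] / 1000)`.
#'
#' @param reads Numeric matrix, features x samples, of mapped read counts.
#' @param length_bp Numeric vector of feature lengths in bp, one per row of
#'   `reads` (recycled by position; names, if present, must match rownames).
#' @return Matrix of the same shape, RPK values.
#' @export
compute_rpk <- function(reads, length_bp) {
  reads <- as.matrix(reads)
  if (!is.null(names(length_bp)) && !is.null(rownames(reads))) {
    length_bp <- length_bp[rownames(reads)]
  }
  abort_if(length(length_bp) != nrow(reads),
           "length_bp must have one entry per feature (%d != %d)",
           length(length_bp), nrow(reads))
  bad <- is.na(length_bp) | length_bp <= 0
  if (any(bad)) {
    who <- rownames(reads)[bad] %||% which(bad)
    stop("zero or missing length for feature(s): ",
         paste(utils::head(who, 5), collapse = ", "), call. = FALSE)
  }
  reads / (length_bp / 1000)
}

#' Transcripts per million (TPM) from RPK
#'
#' Divides each feature's RPK by the per-sample sum of RPKs over all features
#' in the matrix, times one million. The rows of `rpk` define the denominator
#' universe: a full-project matrix yields metagenome-wide TPMs, a subset
#' matrix yields subset-rescaled TPMs.
#'
#' Samples whose RPK column is all zero get an all-zero TPM column and a
#' warning (there is nothing to normalise against).
#'
#' @param rpk Numeric matrix, features x samples, of RPK values.
#' @return Matrix of TPM values; each column with any signal sums to 1e6.
#' @export
compute_tpm <- function(rpk) {
  rpk <- as.matrix(rpk)
  totals <- colSums(rpk)
  zero <- totals == 0
  if (any(zero)) {
    warning("sample(s) with all-zero RPK, TPM set to 0: ",
            paste(colnames(rpk)[zero] %||% which(zero), collapse = ", "),
            call. = FALSE)
    totals[zero] <- 1  # avoids 0/0; columns are all zero anyway
  }
  sweep(rpk, 2, totals, "/") * 1e6
}

## Expand ORF rows into (orf index, function id) pairs for one database.
## Unannotated ORFs map to the "Unclassified" pseudo-function.
.orf_function_pairs <- function(orf_table, db) {
  ann <- if (db %in% colnames(orf_table)) orf_table[[db]] else
    rep("", nrow(orf_table))
  ids <- split_annotations(ann)
  n <- lengths(ids)
  idx <- c(rep(seq_along(ids), n), which(n == 0L))
  fid <- c(unlist(ids, use.names = FALSE),
           rep(.UNCLASSIFIED, sum(n == 0L)))
  list(idx = idx, fid = fid)
}

#' Aggregate ORF-level counts into a function profile
#'
#' Sums reads, bases and coverage of all ORFs annotated to each function of
#' a database, and records the assembly-wide average gene length of each
#' function (the arithmetic mean of its ORFs' lengths, one number per
#' function, not per sample). An ORF with several annotations in the
#' database counts fully toward each of them; ORFs with none accumulate into
#' an always-present `"Unclassified"` row.
#'
#' @param orf_table Data frame with at least `length_bp` and a character
#'   column named `db` holding `"|"`-joined function identifiers.
#' @param reads,bases,cov ORF x sample matrices aligned with `orf_table`.
#' @param db Database name (e.g. `"KEGG"`, `"COG"`, `"PFAM"`).
#' @param fun_info Optional data frame (`db`, `id`, `name`, `hierarchy`)
#'   with function metadata; rows for other databases are ignored.
#' @return A `function_profile` list: matrices `reads`, `bases`, `cov`,
#'   vector `avg_length` (bp, `NA` for functions with no ORFs), `db`, and
#'   an `info` data frame (`id`, `name`, `hierarchy`) aligned with the rows.
#' @export
aggregate_functions <- function(orf_table, reads, bases, cov, db,
                                fun_info = NULL) {
  pairs <- .orf_function_pairs(orf_table, db)
  samples <- colnames(reads)
  if (length(pairs$idx) == 0L) {
    labels <- .UNCLASSIFIED
    out <- list(reads = zero_matrix(labels, samples),
                bases = zero_matrix(labels, samples),
                cov = zero_matrix(labels, samples),
                avg_length = stats::setNames(NA_real_, labels))
  } else {
    agg <- function(m) {
      r <- rowsum(m[pairs$idx, , drop = FALSE], pairs$fid)
      r[order_rows(rownames(r)), , drop = FALSE]
    }
    out <- list(reads = agg(reads), bases = agg(bases), cov = agg(cov))
    lens <- tapply(orf_table$length_bp[pairs$idx], pairs$fid, mean)
    out$avg_length <- stats::setNames(as.numeric(lens[rownames(out$reads)]),
                                      rownames(out$reads))
  }
  ## Materialize the Unclassified row even when every ORF is annotated, so
  ## column sums over the profile are always meaningful.
  if (!(.UNCLASSIFIED %in% rownames(out$reads))) {
    for (m in c("reads", "bases", "cov")) {
      out[[m]] <- rbind(out[[m]], zero_matrix(.UNCLASSIFIED, samples))
    }
    out$avg_length <- c(out$avg_length,
                        stats::setNames(NA_real_, .UNCLASSIFIED))
  }
  ids <- rownames(out$reads)
  info <- data.frame(id = ids, name = "", hierarchy = "",
                     stringsAsFactors = FALSE)
  if (!is.null(fun_info) && nrow(fun_info)) {
    fi <- fun_info[fun_info$db == db, , drop = FALSE]
    hit <- match(ids, fi$id)
    info$name <- ifelse(is.na(hit), "", fi$name[hit])
    info$hierarchy <- ifelse(is.na(hit), "", fi$hierarchy[hit])
  }
  rownames(info) <- NULL
  out$db <- db
  out$info <- info
  structure(out, class = "function_profile")
}

## RPK of a function profile: aggregated reads over the assembly-wide
## average gene length. Rows with zero reads get RPK 0 even when their
## average length is undefined (empty Unclassified row).
.profile_rpk <- function(profile) {
  len <- profile$avg_length
  reads <- profile$reads
  rpk <- reads
  ok <- !is.na(len) & len > 0
  rpk[ok, ] <- reads[ok, , drop = FALSE] / (len[ok] / 1000)
  if (any(!ok)) {
    bad_with_reads <- !ok & rowSums(reads) > 0
    abort_if(any(bad_with_reads),
             "function(s) with reads but no length: %s",
             paste(rownames(reads)[bad_with_reads], collapse = ", "))
    rpk[!ok, ] <- 0
  }
  rpk
}

#' Add TPM to a function profile
#'
#' Function RPK is aggregated reads divided by the assembly-wide average
#' gene length in kb; TPM then normalises RPK per sample over all rows of
#' the profile (including Unclassified), times one million.
#'
#' @param profile A `function_profile` from [aggregate_functions()].
#' @return The profile with a `tpm` matrix added.
#' @export
compute_function_tpm <- function(profile) {
  profile$tpm <- compute_tpm(.profile_rpk(profile))
  profile
}

#' Marker coverage per sample for copy-number normalisation
#'
#' In `recA` mode the marker coverage is the aggregated coverage of COG0468
#' (the RecA/RadA recombinase, a universal single-copy gene) in the COG
#' profile of the same universe. In `usicg_median` mode it is the per-sample
#' median of the coverages of a configured set of universal single-copy
#' genes (default [default_usicgs()]).
#'
#' @param cog_profile The COG `function_profile` of the universe.
#' @param mode `"recA"` or `"usicg_median"`.
#' @param usicg_list COG identifiers for `usicg_median` mode.
#' @return Named numeric vector of marker coverage per sample, with
#'   attribute `"usicg_used"` listing the genes used (usicg mode).
#' @export
marker_coverage <- function(cog_profile, mode = c("recA", "usicg_median"),
                            usicg_list = default_usicgs()) {
  mode <- match.arg(mode)
  cov <- cog_profile$cov
  if (mode == "recA") {
    abort_if(!("COG0468" %in% rownames(cov)), "marker gene absent")
    mc <- cov["COG0468", ]
  } else {
    present <- intersect(usicg_list, rownames(cov))
    abort_if(length(present) == 0L, "marker gene absent")
    missing <- setdiff(usicg_list, present)
    if (length(missing)) {
      warning("USiCGs absent from this universe (ignored): ",
              paste(missing, collapse = ", "), call. = FALSE)
    }
    mc <- apply(cov[present, , drop = FALSE], 2, stats::median)
    attr(mc, "usicg_used") <- present
  }
  mc
}

#' Add copy numbers to a function profile
#'
#' Copy number of a function is its aggregated coverage divided by the
#' marker coverage of the same sample and universe:
#' `copy_number[f, s] = cov[f, s] / marker_cov[s]`. The marker is COG0468
#' (RecA/RadA) by default, or the median of a configured USiCG list.
#' Samples whose marker coverage is zero get `NA` copy numbers and a
#' warning.
#'
#' @param profile Profile to annotate (any database).
#' @param cog_profile COG profile of the same universe carrying the marker
#'   gene(s); defaults to `profile` itself (the COG-on-COG case).
#' @param mode,usicg_list See [marker_coverage()].
#' @return The profile with a `copy_number` matrix and a
#'   `marker` record (`mode`, `coverage`, `usicg_used`) added.
#' @export
compute_copy_number <- function(profile, cog_profile = profile,
                                mode = c("recA", "usicg_median"),
                                usicg_list = default_usicgs()) {
  mode <- match.arg(mode)
  mc <- marker_coverage(cog_profile, mode, usicg_list)
  zero <- !is.na(mc) & mc == 0
  if (any(zero)) {
    warning("marker coverage is zero in sample(s): ",
            paste(names(mc)[zero], collapse = ", "),
            "; copy numbers set to NA", call. = FALSE)
    mc[zero] <- NA_real_
  }
  profile$copy_number <- sweep(profile$cov, 2, mc, "/")
  profile$marker <- list(mode = mode, coverage = mc,
                         usicg_used = attr(mc, "usicg_used"))
  profile
}

#' Aggregate ORF reads into a taxonomy profile at one rank
#'
#' Sums ORF read counts by the taxon named at `rank` in each ORF's lineage
#' (or, with `source = "contig"`, in its host contig's lineage). ORFs with
#' no assignment at the rank accumulate into `"Unclassified"`; the
#' difference between total sequenced reads and mapped ORF reads is carried
#' by an explicit `"Unmapped"` row, so that percentages
#' (`100 * reads / total_reads`) sum to 100 per sample.
#'
#' @param orf_table ORF data frame with a `tax` lineage column (and
#'   `contig_id` when `source = "contig"`).
#' @param reads ORF x sample read-count matrix.
#' @param rank One of [mg_ranks()].
#' @param total_reads Named vector of total sequenced reads per sample.
#' @param contig_tax Optional named lineage vector by contig id, required
#'   for `source = "contig"`.
#' @param source Take lineages from the ORFs themselves (default) or from
#'   their host contigs.
#' @return A `taxonomy_profile` list: `rank`, matrices `reads` and
#'   `percent` (taxa + Unclassified + Unmapped rows).
#' @export
aggregate_taxonomy <- function(orf_table, reads, rank, total_reads,
                               contig_tax = NULL,
                               source = c("orf", "contig")) {
  rank <- match.arg(rank, mg_ranks())
  source <- match.arg(source)
  samples <- colnames(reads)
  total_reads <- total_reads[samples]
  lin <- if (source == "orf") orf_table$tax else {
    abort_if(is.null(contig_tax), "contig_tax required for source='contig'")
    as.character(contig_tax[orf_table$contig_id])
  }
  taxon <- lineage_at(lin, rank)
  taxon[is.na(taxon)] <- .UNCLASSIFIED
  if (nrow(reads)) {
    m <- rowsum(reads, taxon)
  } else {
    m <- zero_matrix(character(0), samples)
  }
  if (!(.UNCLASSIFIED %in% rownames(m))) {
    m <- rbind(m, zero_matrix(.UNCLASSIFIED, samples))
  }
  mapped <- colSums(m)
  unmapped <- total_reads - mapped
  abort_if(any(unmapped < -1e-6),
           "mapped ORF reads exceed total_reads in sample(s): %s",
           paste(samples[unmapped < -1e-6], collapse = ", "))
  m <- rbind(m, matrix(pmax(unmapped, 0), nrow = 1,
                       dimnames = list(.UNMAPPED, samples)))
  m <- m[order_rows(rownames(m)), , drop = FALSE]
  percent <- sweep(m, 2, total_reads, "/") * 100
  structure(list(rank = rank, reads = m, percent = percent),
            class = "taxonomy_profile")
}
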