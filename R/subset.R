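## Taxonomy / bin / function subsetting and combination, with explicit
## rescaling semantics:
##
##   metric        subset_tax / subset_bins      subset_fun
##   reads/bases   re-aggregated (counts)        re-aggregated (counts)
##   TPM           rescaled by default           never rescaled (copied)
##   copy number   rescaled by default           never rescaled (copied)
##   percent       never rescaled                recomputed over the reads
##                 (parent total_reads)          of the matched ORFs, over
##                                               parent total_reads
##
## "Rescaled" means the denominators (total RPK per sample; marker
## coverage) are recomputed inside the subset universe, so TPM columns sum
## to 1e6 and the marker's copy number is 1 within the subset. "Copied"
## means retained rows keep the parent's values verbatim, so they still
## refer to the whole metagenome.

## Row subset of the ORF universe plus its host contigs, re-profiled.
## `orf_keep` is a logical vector over the parent ORF table; `contig_keep`
## over the contig table.
.subset_project <- function(project, orf_keep, contig_keep,
                            rescale_tpm, rescale_copy_number,
                            origin, description,
                            keep_parent_taxa = FALSE) {
  ot <- project$orfs$table[orf_keep, , drop = FALSE]
  rownames(ot) <- NULL
  orfs <- list(table = ot,
               reads = project$orfs$reads[orf_keep, , drop = FALSE],
               bases = project$orfs$bases[orf_keep, , drop = FALSE],
               cov = project$orfs$cov[orf_keep, , drop = FALSE])
  ct <- project$contigs$table[contig_keep, , drop = FALSE]
  rownames(ct) <- NULL
  contigs <- list(table = ct,
                  reads = project$contigs$reads[contig_keep, , drop = FALSE],
                  bases = project$contigs$bases[contig_keep, , drop = FALSE],
                  cov = project$contigs$cov[contig_keep, , drop = FALSE])
  bins <- NULL
  if (!is.null(project$bins) && nrow(project$bins$table)) {
    members <- lapply(project$bins$members, intersect, ct$contig_id)
    keep_bin <- lengths(members) > 0
    if (any(keep_bin)) {
      bt <- project$bins$table[keep_bin, , drop = FALSE]
      rownames(bt) <- NULL
      bins <- list(table = bt, members = members[keep_bin])
    }
  }
  child <- suppressWarnings(build_project(
    project_name = project$project_name,
    samples = project$samples, total_reads = project$total_reads,
    orfs = orfs, contigs = contigs, bins = bins,
    fun_info = project$fun_info, config = project$config,
    provenance = list(origin = origin, rescaled_tpm = rescale_tpm,
                      rescaled_copy_number = rescale_copy_number,
                      description = description)))

  if (!rescale_tpm) {
    child$orfs$tpm <- project$orfs$tpm[ot$orf_id, , drop = FALSE]
    child$contigs$tpm <- project$contigs$tpm[ct$contig_id, , drop = FALSE]
  }
  for (db in names(child$functions)) {
    par <- project$functions[[db]]
    ids <- rownames(child$functions[[db]]$reads)
    if (!rescale_tpm) {
      child$functions[[db]]$tpm <- par$tpm[ids, , drop = FALSE]
    }
    if (!rescale_copy_number) {
      child$functions[[db]]$copy_number <-
        par$copy_number[ids, , drop = FALSE]
      child$functions[[db]]$marker <- par$marker
    }
  }
  if (keep_parent_taxa) {
    child$taxonomy <- lapply(stats::setNames(nm = names(child$taxonomy)),
                             function(rk) {
      expand_taxonomy_rows(child$taxonomy[[rk]],
                           rownames(project$taxonomy[[rk]]$reads))
    })
  }
  child
}

## Zero-fill a taxonomy profile up to a parent row set (keeping the child's
## Unclassified/Unmapped accounting), rows ordered as the parent.
expand_taxonomy_rows <- function(tp, parent_rows) {
  samples <- colnames(tp$reads)
  rows <- union(parent_rows, rownames(tp$reads))
  rows <- c(setdiff(rows, c(.UNCLASSIFIED, .UNMAPPED)), .UNCLASSIFIED,
            .UNMAPPED)
  pad <- function(m) {
    out <- zero_matrix(rows, samples)
    out[rownames(m), ] <- m
    out
  }
  tp$reads <- pad(tp$reads)
  tp$percent <- pad(tp$percent)
  tp
}

#' Subset a project to one taxon
#'
#' Selects the contigs whose lineage at `rank` names `taxon`, together with
#' every ORF on those contigs (an ORF is kept even when its own lineage
#' disagrees with its host contig's consensus). Reads, bases and coverage
#' are re-aggregated over the retained ORFs. With `rescale_tpm` the TPM
#' denominators are recomputed inside the subset (columns sum to 1e6);
#' otherwise retained rows keep the parent's TPM values. With
#' `rescale_copy_number` the marker coverage is recomputed from the
#' retained ORFs (so copy numbers read "per genome of the selected taxon");
#' otherwise parent copy numbers are kept. Taxonomic percentages are never
#' rescaled: they keep the parent's total-sequenced-reads denominator, so a
#' retained taxon's percentage still refers to the whole metagenome.
#'
#' @param project An `mg_project`.
#' @param rank One of [mg_ranks()].
#' @param taxon Taxon name; exact string match at `rank`.
#' @param rescale_tpm,rescale_copy_number Rescale inside the subset
#'   (default `TRUE`).
#' @return A child `mg_project`.
#' @export
subset_tax <- function(project, rank, taxon, rescale_tpm = TRUE,
                       rescale_copy_number = TRUE) {
  rank <- match.arg(rank, mg_ranks())
  at_rank <- lineage_at(project$contigs$table$tax, rank)
  contig_keep <- !is.na(at_rank) & at_rank == taxon
  if (!any(contig_keep)) {
    present <- unique(at_rank[!is.na(at_rank)])
    near <- present[agrepl(taxon, present, ignore.case = TRUE)]
    stop(sprintf("taxon '%s' not found at rank %s%s", taxon, rank,
                 if (length(near)) paste0("; did you mean: ",
                                          paste(near, collapse = ", "))
                 else ""), call. = FALSE)
  }
  keep_ids <- project$contigs$table$contig_id[contig_keep]
  orf_keep <- project$orfs$table$contig_id %in% keep_ids
  abort_if(!any(orf_keep), "no ORFs on the selected contigs")
  .subset_project(project, orf_keep, contig_keep,
                  rescale_tpm, rescale_copy_number,
                  origin = "tax",
                  description = sprintf("tax subset: %s == '%s'", rank,
                                        taxon))
}

#' Subset a project to one or more bins
#'
#' The contig universe is the union of the requested bins' member contigs;
#' semantics otherwise as in [subset_tax()] (TPM and copy numbers rescaled
#' to the bin universe by default; percentages never rescaled).
#'
#' @param project An `mg_project`.
#' @param bin_ids Character vector of bin identifiers.
#' @inheritParams subset_tax
#' @return A child `mg_project`.
#' @export
subset_bins <- function(project, bin_ids, rescale_tpm = TRUE,
                        rescale_copy_number = TRUE) {
  abort_if(is.null(project$bins) || !nrow(project$bins$table),
           "project has no bins")
  unknown <- setdiff(bin_ids, project$bins$table$bin_id)
  abort_if(length(unknown) > 0, "unknown bin id(s): %s",
           paste(unknown, collapse = ", "))
  keep_ids <- unique(unlist(project$bins$members[bin_ids]))
  contig_keep <- project$contigs$table$contig_id %in% keep_ids
  orf_keep <- project$orfs$table$contig_id %in% keep_ids
  abort_if(!any(orf_keep), "no ORFs on the selected contigs")
  .subset_project(project, orf_keep, contig_keep,
                  rescale_tpm, rescale_copy_number,
                  origin = "bin",
                  description = sprintf("bin subset: %s",
                                        paste(bin_ids, collapse = ", ")))
}

## Which function ids of a database match any pattern, by case-insensitive
## substring (or regex) against the id, the name and, optionally, every
## level of the hierarchy path.
match_function_ids <- function(profile, patterns, use_regex = FALSE,
                               search_hierarchy = TRUE) {
  info <- profile$info
  info <- info[info$id != .UNCLASSIFIED, , drop = FALSE]
  hay <- paste(info$id, info$name,
               if (search_hierarchy) info$hierarchy else "")
  hit <- rep(FALSE, nrow(info))
  for (p in patterns) {
    h <- if (use_regex) {
      tryCatch(suppressWarnings(grepl(p, hay, ignore.case = TRUE)),
               error = function(e) stop(sprintf("invalid regex: '%s'", p),
                                        call. = FALSE))
    } else {
      grepl(tolower(p), tolower(hay), fixed = TRUE)
    }
    hit <- hit | h
  }
  info$id[hit]
}

## Logical vector over ORFs: does any annotation match the patterns?
match_orfs_by_function <- function(project, patterns, use_regex = FALSE,
                                   search_hierarchy = TRUE,
                                   databases = NULL) {
  databases <- databases %||% project$databases
  keep <- rep(FALSE, nrow(project$orfs$table))
  for (db in databases) {
    ids <- match_function_ids(project$functions[[db]], patterns,
                              use_regex, search_hierarchy)
    if (!length(ids)) next
    ann <- split_annotations(project$orfs$table[[db]])
    keep <- keep | vapply(ann, function(a) any(a %in% ids), logical(1))
  }
  keep
}

#' Subset a project to the ORFs carrying selected functions
#'
#' Selects the ORFs whose annotations match any pattern — by
#' case-insensitive substring against function identifiers and names and
#' (with `search_hierarchy`) every level of the functional hierarchy, or by
#' regular expression with `use_regex = TRUE` — plus the contigs hosting
#' them. Profiles are computed from the matching ORFs only (other ORFs on
#' the retained contigs are excluded). TPM and copy numbers are never
#' rescaled: retained rows keep the parent's values, so they still refer to
#' the whole metagenome. Taxonomic percentages are recomputed counting only
#' the reads of the matched ORFs, over the parent's total sequenced reads;
#' all parent taxa rows are kept, zero-filled where the subset has no
#' reads.
#'
#' @param project An `mg_project`.
#' @param patterns Character vector of patterns (at least one).
#' @param use_regex Interpret patterns as regular expressions (POSIX
#'   extended, as [grepl()]) instead of fixed substrings.
#' @param search_hierarchy Also match against hierarchy path levels.
#' @param databases Restrict matching to these annotation databases
#'   (default: all).
#' @return A child `mg_project`.
#' @export
subset_fun <- function(project, patterns, use_regex = FALSE,
                       search_hierarchy = TRUE, databases = NULL) {
  abort_if(length(patterns) == 0, "need at least one pattern")
  orf_keep <- match_orfs_by_function(project, patterns, use_regex,
                                     search_hierarchy, databases)
  abort_if(!any(orf_keep), "no function matches pattern(s): %s",
           paste(patterns, collapse = ", "))
  host <- unique(project$orfs$table$contig_id[orf_keep])
  contig_keep <- project$contigs$table$contig_id %in% host
  .subset_project(project, orf_keep, contig_keep,
                  rescale_tpm = FALSE, rescale_copy_number = FALSE,
                  origin = "fun",
                  description = sprintf("fun subset: %s",
                                        paste(patterns, collapse = " | ")),
                  keep_parent_taxa = TRUE)
}

#' Combine projects that share a parent
#'
#' Unions the ORF, contig and bin rows of several child projects of the
#' same parent (identical sample lists and total read counts required).
#' Duplicate identifiers are counted once; their rows must agree exactly.
#' Profiles are re-aggregated over the union; with the rescale flags set,
#' denominators are recomputed inside the combined universe, otherwise
#' retained rows keep the values they had in the inputs (which must agree
#' across inputs).
#'
#' @param projects A list of `mg_project`s (or several passed via `...`).
#' @param rescale_tpm,rescale_copy_number Recompute denominators inside the
#'   combined universe (default `FALSE`: values are carried over).
#' @return An `mg_project` with `provenance$origin == "combined"`.
#' @export
combine_projects <- function(projects, rescale_tpm = FALSE,
                             rescale_copy_number = FALSE) {
  if (inherits(projects, "mg_project")) projects <- list(projects)
  abort_if(length(projects) < 1, "need at least one project")
  p1 <- projects[[1]]
  for (p in projects[-1]) {
    abort_if(!identical(p$samples, p1$samples) ||
               !isTRUE(all.equal(p$total_reads, p1$total_reads)),
             "sample mismatch: projects do not share a parent")
  }
  if (length(projects) == 1L) return(p1)

  merge_rows <- function(tabs, mats, idcol) {
    tab <- do.call(rbind, tabs)
    ids <- tab[[idcol]]
    first <- !duplicated(ids)
    ## duplicate ids must carry identical rows everywhere
    for (id in unique(ids[duplicated(ids)])) {
      w <- which(ids == id)
      for (j in w[-1]) {
        abort_if(!isTRUE(all.equal(tab[w[1], ], tab[j, ],
                                   check.attributes = FALSE)),
                 "conflicting duplicate rows for id %s", id)
      }
    }
    out_tab <- tab[first, , drop = FALSE]
    rownames(out_tab) <- NULL
    out_mats <- lapply(mats, function(ms) {
      m <- do.call(rbind, ms)
      for (id in unique(ids[duplicated(ids)])) {
        w <- which(ids == id)
        abort_if(max(abs(sweep(m[w, , drop = FALSE], 2, m[w[1], ]))) > 1e-9,
                 "conflicting duplicate matrix rows for id %s", id)
      }
      m[first, , drop = FALSE]
    })
    c(list(table = out_tab), out_mats)
  }

  orfs <- merge_rows(lapply(projects, function(p) p$orfs$table),
                     list(reads = lapply(projects, function(p) p$orfs$reads),
                          bases = lapply(projects, function(p) p$orfs$bases),
                          cov = lapply(projects, function(p) p$orfs$cov)),
                     "orf_id")
  contigs <- merge_rows(
    lapply(projects, function(p) p$contigs$table),
    list(reads = lapply(projects, function(p) p$contigs$reads),
         bases = lapply(projects, function(p) p$contigs$bases),
         cov = lapply(projects, function(p) p$contigs$cov)),
    "contig_id")

  bins <- NULL
  bin_tabs <- lapply(projects, function(p) {
    if (is.null(p$bins)) NULL else p$bins$table
  })
  if (any(!vapply(bin_tabs, is.null, logical(1)))) {
    bt <- do.call(rbind, bin_tabs)
    members <- list()
    for (p in projects) {
      if (is.null(p$bins)) next
      for (b in names(p$bins$members)) {
        members[[b]] <- union(members[[b]] %||% character(0),
                              p$bins$members[[b]])
      }
    }
    bt <- bt[!duplicated(bt$bin_id), , drop = FALSE]
    rownames(bt) <- NULL
    bins <- list(table = bt, members = members[bt$bin_id])
  }

  child <- suppressWarnings(build_project(
    project_name = p1$project_name,
    samples = p1$samples, total_reads = p1$total_reads,
    orfs = orfs, contigs = contigs, bins = bins,
    fun_info = p1$fun_info, config = p1$config,
    provenance = list(origin = "combined",
                      rescaled_tpm = rescale_tpm,
                      rescaled_copy_number = rescale_copy_number,
                      description = sprintf("combination of %d projects",
                                            length(projects)))))

  ## carried-over (non-rescaled) values: take each row from the first input
  ## that has it; inputs holding the same row must agree
  carry <- function(get_matrix) {
    function(ids, db = NULL) {
      out <- NULL
      for (p in projects) {
        m <- get_matrix(p, db)
        if (is.null(m)) next
        have <- intersect(ids, rownames(m))
        if (is.null(out)) {
          out <- matrix(NA_real_, length(ids), ncol(m),
                        dimnames = list(ids, colnames(m)))
        }
        new <- have[is.na(out[have, 1])]
        out[new, ] <- m[new, , drop = FALSE]
        old <- setdiff(have, new)
        if (length(old)) {
          abort_if(max(abs(out[old, , drop = FALSE] -
                             m[old, , drop = FALSE]), 0) > 1e-9,
                   "conflicting carried-over values%s",
                   if (is.null(db)) "" else paste0(" in ", db))
        }
      }
      out
    }
  }
  if (!rescale_tpm) {
    child$orfs$tpm <- carry(function(p, db) p$orfs$tpm)(
      child$orfs$table$orf_id)
    child$contigs$tpm <- carry(function(p, db) p$contigs$tpm)(
      child$contigs$table$contig_id)
    for (db in names(child$functions)) {
      child$functions[[db]]$tpm <- carry(
        function(p, d) p$functions[[d]]$tpm)(
          rownames(child$functions[[db]]$reads), db)
    }
  }
  if (!rescale_copy_number) {
    for (db in names(child$functions)) {
      child$functions[[db]]$copy_number <- carry(
        function(p, d) p$functions[[d]]$copy_number)(
          rownames(child$functions[[db]]$reads), db)
      child$functions[[db]]$marker <- p1$functions[[db]]$marker
    }
  }
  child
}
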