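## Reading and writing the project directory dialect.
##
## A project directory holds TAB-separated, LF-terminated, UTF-8 tables with
## header rows; missing values are "NA" or empty; annotation lists are
## "|"-joined:
##
##   samples.tsv   Sample, Total_reads                         (required)
##   orfs.tsv      ORF_ID, Contig_ID, Start, Stop, Strand, Length_bp, Tax,
##                 <one column per annotation database>,
##                 then per sample: Reads_<s>, Bases_<s>, Coverage_<s>
##                                                             (required)
##   contigs.tsv   Contig_ID, Length_bp, Tax, Bin_ID,
##                 then per sample Reads_<s>, Bases_<s>, Coverage_<s>
##                                                             (optional)
##   bins.tsv      Bin_ID, Method, Tax, Completeness, Contamination,
##                 Contigs ("|"-joined)                        (optional)
##   functions.tsv DB, ID, Name, Hierarchy                     (optional)
##
## Aggregate profiles are never read from disk: they are recomputed from the
## ORF rows on every load, so the ORF table is the single source of truth.

read_dialect_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

## Strict numeric conversion: any cell that is not empty/"NA" and does not
## parse as a number is an error naming file, line and column.
parse_numeric_col <- function(x, file, column) {
  x <- trimws(x)
  is_na <- !nzchar(x) | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is_na & is.na(out))
  abort_if(length(bad) > 0,
           "malformed numeric cell in %s, line %d, column %s: '%s'",
           file, bad[1] + 1L, column, x[bad[1]])
  out
}

sample_matrix <- function(df, prefix, samples, file) {
  cols <- paste0(prefix, "_", samples)
  abort_if(!all(cols %in% colnames(df)),
           "sample mismatch: %s lacks column(s) %s", file,
           paste(setdiff(cols, colnames(df)), collapse = ", "))
  m <- vapply(seq_along(samples), function(i) {
    parse_numeric_col(df[[cols[i]]], file, cols[i])
  }, numeric(nrow(df)))
  if (nrow(df) == 0L) m <- matrix(numeric(0), nrow = 0, ncol = length(samples))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  dimnames(m) <- list(NULL, samples)
  m
}

#' Load a project directory
#'
#' Parses the dialect files of `dir` into an [validate_project()]-clean
#' project object. All aggregate profiles (taxonomy at all seven ranks,
#' one function profile per annotation database found in `orfs.tsv`, with
#' TPM and copy numbers) are recomputed from the ORF rows; pre-aggregated
#' contig counts, when `contigs.tsv` is present, are cross-checked against
#' the ORF sums and a warning is issued on discrepancies above 0.5%.
#'
#' @param dir Path to a project directory.
#' @param config Optional configuration: a named list or the path of a YAML
#'   file with keys `marker_mode` (`"recA"` or `"usicg_median"`),
#'   `usicg_list` and `taxonomy_source` (`"orf"` or `"contig"`).
#' @return An `mg_project` with `provenance$origin == "full"`.
#' @export
#' @seealso [write_project()], [generate_project()]
load_project <- function(dir, config = NULL) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  f <- function(name) file.path(dir, name)
  for (req in c("samples.tsv", "orfs.tsv")) {
    abort_if(!file.exists(f(req)), "missing file: %s", f(req))
  }

  sdf <- read_dialect_file(f("samples.tsv"))
  samples <- sdf$Sample
  total_reads <- stats::setNames(
    parse_numeric_col(sdf$Total_reads, "samples.tsv", "Total_reads"),
    samples)

  odf <- read_dialect_file(f("orfs.tsv"))
  fixed <- c("ORF_ID", "Contig_ID", "Start", "Stop", "Strand", "Length_bp",
             "Tax")
  abort_if(!all(fixed %in% colnames(odf)),
           "orfs.tsv lacks required column(s): %s",
           paste(setdiff(fixed, colnames(odf)), collapse = ", "))
  percol <- grep("^(Reads|Bases|Coverage)_", colnames(odf), value = TRUE)
  file_samples <- unique(sub("^(Reads|Bases|Coverage)_", "", percol))
  abort_if(!setequal(file_samples, samples),
           "sample mismatch between samples.tsv and orfs.tsv (%s vs %s)",
           paste(samples, collapse = ","),
           paste(file_samples, collapse = ","))
  db_cols <- setdiff(colnames(odf), c(fixed, percol))

  orf_table <- data.frame(
    orf_id = odf$ORF_ID,
    contig_id = odf$Contig_ID,
    start = as.integer(parse_numeric_col(odf$Start, "orfs.tsv", "Start")),
    stop = as.integer(parse_numeric_col(odf$Stop, "orfs.tsv", "Stop")),
    strand = odf$Strand,
    length_bp = parse_numeric_col(odf$Length_bp, "orfs.tsv", "Length_bp"),
    tax = odf$Tax,
    stringsAsFactors = FALSE)
  for (db in db_cols) orf_table[[db]] <- odf[[db]]
  orfs <- list(table = orf_table,
               reads = sample_matrix(odf, "Reads", samples, "orfs.tsv"),
               bases = sample_matrix(odf, "Bases", samples, "orfs.tsv"),
               cov = sample_matrix(odf, "Coverage", samples, "orfs.tsv"))
  rn <- orf_table$orf_id
  rownames(orfs$reads) <- rownames(orfs$bases) <- rownames(orfs$cov) <- rn

  contigs <- if (file.exists(f("contigs.tsv"))) {
    load_contigs(f("contigs.tsv"), samples, orfs)
  } else {
    derive_contigs(orfs, samples)
  }

  bins <- if (file.exists(f("bins.tsv"))) load_bins(f("bins.tsv")) else NULL
  fun_info <- if (file.exists(f("functions.tsv"))) {
    fi <- read_dialect_file(f("functions.tsv"))
    data.frame(db = fi$DB, id = fi$ID, name = fi$Name,
               hierarchy = fi$Hierarchy, stringsAsFactors = FALSE)
  } else NULL

  p <- build_project(project_name = basename(normalizePath(dir)),
                     samples = samples, total_reads = total_reads,
                     orfs = orfs, contigs = contigs, bins = bins,
                     fun_info = fun_info, config = config)
  p
}

load_contigs <- function(path, samples, orfs) {
  cdf <- read_dialect_file(path)
  tab <- data.frame(
    contig_id = cdf$Contig_ID,
    length_bp = parse_numeric_col(cdf$Length_bp, "contigs.tsv", "Length_bp"),
    tax = cdf$Tax,
    bin_id = if ("Bin_ID" %in% colnames(cdf)) cdf$Bin_ID else
      rep(NA_character_, nrow(cdf)),
    stringsAsFactors = FALSE)
  have_counts <- any(grepl("^Reads_", colnames(cdf)))
  if (have_counts) {
    reads <- sample_matrix(cdf, "Reads", samples, "contigs.tsv")
    bases <- sample_matrix(cdf, "Bases", samples, "contigs.tsv")
    if (any(grepl("^Coverage_", colnames(cdf)))) {
      cov <- sample_matrix(cdf, "Coverage", samples, "contigs.tsv")
    } else {
      message("contigs.tsv has no Coverage columns; deriving as bases/length")
      cov <- bases / tab$length_bp
    }
  } else {
    message("contigs.tsv has no per-sample counts; deriving from ORF sums ",
            "(intergenic reads unrepresented)")
    d <- derive_contig_counts(orfs, tab$contig_id, samples, tab$length_bp)
    reads <- d$reads; bases <- d$bases; cov <- d$cov
  }
  rownames(reads) <- rownames(bases) <- rownames(cov) <- tab$contig_id
  ## cross-check against ORF sums (single source of truth is the ORF table)
  d <- derive_contig_counts(orfs, tab$contig_id, samples, tab$length_bp)
  rel <- abs(reads - d$reads) / pmax(reads, 1)
  if (any(rel > 0.005 & d$reads > reads)) {
    warning("contigs.tsv read counts deviate >0.5% below the ORF sums",
            call. = FALSE)
  }
  list(table = tab, reads = reads, bases = bases, cov = cov)
}

derive_contig_counts <- function(orfs, contig_ids, samples, length_bp) {
  fac <- factor(orfs$table$contig_id, levels = contig_ids)
  agg <- function(m) {
    out <- zero_matrix(contig_ids, samples)
    if (nrow(m)) {
      r <- rowsum(m, fac)
      out[rownames(r), ] <- r
    }
    out
  }
  reads <- agg(orfs$reads)
  bases <- agg(orfs$bases)
  list(reads = reads, bases = bases, cov = bases / length_bp)
}

## No contigs.tsv: derive the contig table from the ORF rows. Contig length
## is taken as the rightmost ORF stop (true length unknown); the consensus
## lineage is the most common ORF lineage on the contig.
derive_contigs <- function(orfs, samples) {
  ot <- orfs$table
  contig_ids <- unique(ot$contig_id)
  length_bp <- vapply(split(ot$stop, ot$contig_id)[contig_ids], max,
                      numeric(1))
  tax <- vapply(split(ot$tax, ot$contig_id)[contig_ids], function(x) {
    x <- x[nzchar(x) & !is.na(x)]
    if (!length(x)) "" else names(sort(table(x), decreasing = TRUE))[1]
  }, character(1))
  tab <- data.frame(contig_id = contig_ids, length_bp = length_bp,
                    tax = tax, bin_id = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  d <- derive_contig_counts(orfs, contig_ids, samples, length_bp)
  message("contigs.tsv absent; contig table derived from ORF rows")
  list(table = tab, reads = d$reads, bases = d$bases, cov = d$cov)
}

load_bins <- function(path) {
  bdf <- read_dialect_file(path)
  tab <- data.frame(
    bin_id = bdf$Bin_ID,
    method = bdf$Method,
    tax = bdf$Tax,
    completeness = parse_numeric_col(bdf$Completeness, "bins.tsv",
                                     "Completeness"),
    contamination = parse_numeric_col(bdf$Contamination, "bins.tsv",
                                      "Contamination"),
    stringsAsFactors = FALSE)
  members <- split_annotations(bdf$Contigs)
  names(members) <- tab$bin_id
  list(table = tab, members = members)
}

fmt_num <- function(x) {
  ## enough significant digits that doubles survive a write/read round trip
  ## well within 1e-9 relative tolerance; integers print without exponent
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%.0f", x), sprintf("%.13g", x)))
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")  # LF line endings on every platform
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n",
             useBytes = TRUE)
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) fmt_num(col) else {
        col <- as.character(col)
        col[is.na(col)] <- "NA"
        col
      }
    }, character(nrow(df)))
    if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(df))
    writeLines(apply(cells, 1, paste, collapse = "\t"), con, sep = "\n",
               useBytes = TRUE)
  }
  invisible(path)
}

#' Write a project as a dialect directory
#'
#' Emits `samples.tsv`, `orfs.tsv`, `contigs.tsv`, and, when present,
#' `bins.tsv` and `functions.tsv`, such that [load_project()] on the result
#' reproduces the feature tables exactly and all profiles within 1e-9
#' relative tolerance. Output is deterministic (no timestamps).
#'
#' @param project An `mg_project`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_project <- function(project, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(dir), "cannot create directory %s", dir)
  samples <- project$samples

  write_tsv(data.frame(Sample = samples,
                       Total_reads = unname(project$total_reads)),
            file.path(dir, "samples.tsv"))

  ot <- project$orfs$table
  odf <- data.frame(ORF_ID = ot$orf_id, Contig_ID = ot$contig_id,
                    Start = ot$start, Stop = ot$stop, Strand = ot$strand,
                    Length_bp = ot$length_bp, Tax = ot$tax,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (db in annotation_databases(ot)) odf[[db]] <- ot[[db]]
  for (s in samples) {
    odf[[paste0("Reads_", s)]] <- project$orfs$reads[, s]
    odf[[paste0("Bases_", s)]] <- project$orfs$bases[, s]
    odf[[paste0("Coverage_", s)]] <- project$orfs$cov[, s]
  }
  write_tsv(odf, file.path(dir, "orfs.tsv"))

  ct <- project$contigs$table
  cdf <- data.frame(Contig_ID = ct$contig_id, Length_bp = ct$length_bp,
                    Tax = ct$tax, Bin_ID = ct$bin_id,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in samples) {
    cdf[[paste0("Reads_", s)]] <- project$contigs$reads[, s]
    cdf[[paste0("Bases_", s)]] <- project$contigs$bases[, s]
    cdf[[paste0("Coverage_", s)]] <- project$contigs$cov[, s]
  }
  write_tsv(cdf, file.path(dir, "contigs.tsv"))

  if (!is.null(project$bins) && nrow(project$bins$table)) {
    bt <- project$bins$table
    write_tsv(data.frame(
      Bin_ID = bt$bin_id, Method = bt$method, Tax = bt$tax,
      Completeness = bt$completeness, Contamination = bt$contamination,
      Contigs = vapply(project$bins$members[bt$bin_id], paste,
                       character(1), collapse = "|"),
      stringsAsFactors = FALSE), file.path(dir, "bins.tsv"))
  }
  if (!is.null(project$fun_info) && nrow(project$fun_info)) {
    fi <- project$fun_info
    write_tsv(data.frame(DB = fi$db, ID = fi$id, Name = fi$name,
                         Hierarchy = fi$hierarchy, stringsAsFactors = FALSE),
              file.path(dir, "functions.tsv"))
  }
  invisible(dir)
}
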