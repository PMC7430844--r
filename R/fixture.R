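## Synthetic project generator with known ground truth.
##
## Emulates the count tables of an assembly-based metagenomic pipeline:
## a community of genomes with log-normal relative abundances, each genome
## split into contigs carrying ORFs, function annotations with known
## per-genome copy counts, exactly one COG0468 (RecA/RadA) marker per
## genome, and per-sample ORF read counts drawn multinomially with
## probability proportional to genome abundance x ORF length. No sequences
## are simulated: every metric in scope consumes counts and coverages.

#' Generate a synthetic project with known ground truth
#'
#' Builds a community of `n_genomes` genomes whose per-sample relative
#' abundances are drawn log-normal and normalised to sum to 1. Each genome
#' carries an integer number of copies of each of `n_functions` functions
#' (one ORF per copy, annotated with a KEGG ortholog, a COG and a PFAM
#' identifier), exactly one copy of the COG0468 single-copy marker, two
#' unannotated filler ORFs and one taxonomically unclassified ORF. ORF
#' lengths are uniform in 300–3000 bp; ORFs are packed onto contigs (3–6
#' ORFs per contig with fixed intergenic gaps). Per sample,
#' `round(depth * mapped_fraction)` reads are assigned to ORFs by a
#' multinomial draw with probability proportional to abundance x ORF
#' length; bases are `reads * read_length` and coverage `bases / length`.
#' The remaining `1 - mapped_fraction` of reads exercises the Unmapped
#' accounting path. Output is deterministic given `seed` (byte-identical
#' directories).
#'
#' @param n_genomes,n_samples,n_functions Community dimensions (all >= 1).
#' @param depth Total sequenced reads per sample (>= 1).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param out_dir Optional directory; when given, the dialect files plus a
#'   `truth.json` ground-truth record are written there.
#' @param mapped_fraction Fraction of reads mapping to ORFs (default 0.9).
#' @param read_length Read length in bp used to convert reads to bases.
#' @param abundance_sdlog Log-normal sd of genome abundances (meanlog 0).
#' @param copies_prob Probabilities of 0, 1, 2, 3 copies per genome per
#'   function.
#' @return Invisibly, a list with `truth` (a `mg_ground_truth`), `project`
#'   (the in-memory `mg_project`) and `dir` (`NULL` unless written).
#' @export
#' @examples
#' gp <- generate_project(3, 2, 12, depth = 1e4, seed = 42)
#' summary(gp$project)
generate_project <- function(n_genomes, n_samples, n_functions, depth = 1e5,
                             seed = 1, out_dir = NULL,
                             mapped_fraction = 0.9, read_length = 150,
                             abundance_sdlog = 1,
                             copies_prob = c(0.3, 0.4, 0.2, 0.1)) {
  abort_if(n_genomes < 1 || n_samples < 1 || n_functions < 1 || depth < 1,
           "all counts and depth must be >= 1")
  abort_if(mapped_fraction <= 0 || mapped_fraction > 1,
           "mapped_fraction must be in (0, 1]")
  with_seed(seed, {
    truth <- .draw_truth(n_genomes, n_samples, n_functions, depth, seed,
                         mapped_fraction, read_length, abundance_sdlog,
                         copies_prob)
    layout <- .layout_genomes(truth)
    truth <- .record_lengths(truth, layout)
    project <- .sample_reads(truth, layout)
  })
  if (!is.null(out_dir)) {
    write_project(project, out_dir)
    jsonlite::write_json(unclass(truth), file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(truth = truth, project = project, dir = out_dir))
}

.draw_truth <- function(n_genomes, n_samples, n_functions, depth, seed,
                        mapped_fraction, read_length, abundance_sdlog,
                        copies_prob) {
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  samples <- sprintf("S%d", seq_len(n_samples))
  funs <- sprintf("K%05d", seq_len(n_functions))

  lineages <- vapply(seq_len(n_genomes), function(g) {
    paste0("k_Bacteria",
           ";p_Phylum", ceiling(g / 2),
           ";c_Class", g, ";o_Order", g, ";f_Family", g,
           ";g_Genus", g, ";s_Genus", g, " species", g)
  }, character(1))

  ab <- matrix(stats::rlnorm(n_genomes * n_samples, 0, abundance_sdlog),
               nrow = n_genomes, dimnames = list(genomes, samples))
  ab <- sweep(ab, 2, colSums(ab), "/")

  copies <- matrix(sample(0:3, n_genomes * n_functions, replace = TRUE,
                          prob = copies_prob),
                   nrow = n_genomes, dimnames = list(genomes, funs))
  ## every function present in at least one genome
  absent <- colSums(copies) == 0
  copies[cbind(sample(seq_len(n_genomes), sum(absent), replace = TRUE),
               which(absent))] <- 1L

  structure(list(genomes = genomes, samples = samples, functions = funs,
                 lineages = stats::setNames(as.list(lineages), genomes),
                 abundances = ab, function_copies = copies,
                 depth = depth, mapped_fraction = mapped_fraction,
                 read_length = read_length, seed = seed),
            class = "mg_ground_truth")
}

## Build the ORF/contig/bin layout implied by the truth record: one ORF per
## function copy, one COG0468 marker, two unannotated fillers and one
## taxonomically unclassified ORF per genome, packed onto contigs.
.layout_genomes <- function(truth) {
  orf_rows <- list()
  contig_rows <- list()
  bin_rows <- list()
  members <- list()
  for (g in truth$genomes) {
    copies <- truth$function_copies[g, ]
    kegg <- rep(names(copies), copies)
    n_fun_orfs <- length(kegg)
    ann <- data.frame(
      KEGG = c(kegg, "", "", "", ""),
      COG = c(sprintf("COG%04d", 1000 + match(kegg, truth$functions)),
              "COG0468", "", "", ""),
      PFAM = c(sprintf("PF%05d", match(kegg, truth$functions)),
               "", "", "", ""),
      stringsAsFactors = FALSE)
    ## one fixed ORF carries a second PFAM annotation ("|"-joined lists)
    if (n_fun_orfs >= 1) {
      ann$PFAM[1] <- paste(ann$PFAM[1], "PF09999", sep = "|")
    }
    n_orfs <- nrow(ann)  # marker + 2 fillers + 1 tax-unclassified filler
    lens <- floor(stats::runif(n_orfs, 300, 3001))
    tax <- c(rep(truth$lineages[[g]], n_orfs - 1L), "")

    ## pack ORFs onto contigs, 3-6 per contig, 50 bp intergenic gaps
    per_contig <- integer(0)
    left <- n_orfs
    while (left > 0) {
      k <- min(left, sample(3:6, 1))
      per_contig <- c(per_contig, k)
      left <- left - k
    }
    contig_of <- rep(seq_along(per_contig), per_contig)
    contig_ids <- sprintf("%s_C%03d", g, seq_along(per_contig))
    start <- integer(n_orfs); stop <- integer(n_orfs)
    pos <- stats::setNames(rep(1L, length(per_contig)), contig_ids)
    for (i in seq_len(n_orfs)) {
      cid <- contig_ids[contig_of[i]]
      start[i] <- pos[[cid]] + 50L
      stop[i] <- start[i] + lens[i] - 1L
      pos[[cid]] <- stop[i]
    }
    contig_len <- pos + 50L

    orf_rows[[g]] <- data.frame(
      orf_id = sprintf("%s_ORF%04d", g, seq_len(n_orfs)),
      contig_id = contig_ids[contig_of],
      start = start, stop = stop,
      strand = rep_len(c("+", "-"), n_orfs),
      length_bp = lens, tax = tax,
      KEGG = ann$KEGG, COG = ann$COG, PFAM = ann$PFAM,
      genome = g, stringsAsFactors = FALSE)
    contig_rows[[g]] <- data.frame(
      contig_id = contig_ids, length_bp = as.numeric(contig_len),
      tax = truth$lineages[[g]], bin_id = paste0("bin_", g),
      stringsAsFactors = FALSE)
    bin_rows[[g]] <- data.frame(
      bin_id = paste0("bin_", g), method = "synthetic",
      tax = truth$lineages[[g]],
      completeness = round(stats::runif(1, 90, 100), 2),
      contamination = round(stats::runif(1, 0, 5), 2),
      stringsAsFactors = FALSE)
    members[[paste0("bin_", g)]] <- contig_ids
  }
  list(orfs = do.call(rbind, orf_rows),
       contigs = do.call(rbind, contig_rows),
       bins = do.call(rbind, bin_rows),
       members = members)
}

## Record the ORF-length sums the closed-form expectations need, so that
## truth_report() is pure arithmetic on the truth record.
.record_lengths <- function(truth, layout) {
  ot <- layout$orfs
  gfac <- factor(ot$genome, levels = truth$genomes)
  truth$genome_length_bp <- as.numeric(tapply(ot$length_bp, gfac, sum))
  names(truth$genome_length_bp) <- truth$genomes
  truth$classified_length_bp <- as.numeric(
    tapply(ot$length_bp * nzchar(ot$tax), gfac, sum))
  names(truth$classified_length_bp) <- truth$genomes
  Lf <- vapply(truth$functions, function(f) {
    idx <- ot$KEGG == f
    v <- tapply(ot$length_bp[idx], factor(ot$genome[idx],
                                          levels = truth$genomes), sum)
    v[is.na(v)] <- 0
    as.numeric(v)
  }, numeric(length(truth$genomes)))
  Lf <- matrix(Lf, nrow = length(truth$genomes),
               ncol = length(truth$functions))
  dimnames(Lf) <- list(truth$genomes, truth$functions)
  truth$function_length_bp <- Lf
  truth
}

.sample_reads <- function(truth, layout) {
  samples <- truth$samples
  ot <- layout$orfs
  n <- nrow(ot)
  mapped <- round(truth$depth * truth$mapped_fraction)
  reads <- zero_matrix(ot$orf_id, samples)
  for (s in samples) {
    prob <- truth$abundances[ot$genome, s] * ot$length_bp
    reads[, s] <- stats::rmultinom(1, mapped, prob)[, 1]
  }
  bases <- reads * truth$read_length
  cov <- bases / ot$length_bp
  ot$genome <- NULL
  rownames(ot) <- NULL
  orfs <- list(table = ot, reads = reads, bases = bases, cov = cov)

  ctab <- layout$contigs
  rownames(ctab) <- NULL
  d <- derive_contig_counts(orfs, ctab$contig_id, samples, ctab$length_bp)
  contigs <- list(table = ctab, reads = d$reads, bases = d$bases,
                  cov = d$cov)
  btab <- layout$bins
  rownames(btab) <- NULL
  bins <- list(table = btab, members = layout$members)

  fun_info <- rbind(
    data.frame(db = "KEGG", id = truth$functions,
               name = paste("Synthetic enzyme", seq_along(truth$functions)),
               hierarchy = paste0("Metabolism;",
                                  c("Amino acid metabolism",
                                    "Carbohydrate metabolism",
                                    "Energy metabolism")[
                                      (seq_along(truth$functions) - 1L) %/%
                                        4L %% 3L + 1L]),
               stringsAsFactors = FALSE),
    data.frame(db = "COG", id = "COG0468",
               name = "RecA/RadA recombinase",
               hierarchy = "Information storage;Replication and repair",
               stringsAsFactors = FALSE))

  build_project(project_name = paste0("synthetic_seed", truth$seed),
                samples = samples,
                total_reads = stats::setNames(rep(truth$depth,
                                                  length(samples)), samples),
                orfs = orfs, contigs = contigs, bins = bins,
                fun_info = fun_info)
}

#' Closed-form expectations from a ground-truth record
#'
#' Computes, without touching the sampled counts, the expected value of
#' every recoverable quantity:
#' \itemize{
#'   \item `copy_number`: the abundance-weighted mean copy count
#'     `sum_g a[g,s] * copies[g,f] / sum_g a[g,s]` — the value the
#'     coverage-ratio estimator converges to as depth grows;
#'   \item `percent`: the expected genus-level percentage of total reads,
#'     `100 * mapped_fraction * a[g,s] * Lc[g] / sum_g' a[g',s] * L[g']`,
#'     where `L` is total ORF length and `Lc` the taxonomically classified
#'     part of it;
#'   \item `function_reads_prop`: each function's expected share of mapped
#'     reads.
#' }
#'
#' @param truth A `mg_ground_truth` from [generate_project()].
#' @return A long data frame with columns `quantity`, `feature`, `sample`,
#'   `expected`.
#' @export
truth_report <- function(truth) {
  ab <- truth$abundances
  copies <- truth$function_copies
  rows <- list()

  ## expected copy numbers: abundance-weighted mean (marker is 1/genome)
  for (f in truth$functions) {
    ecn <- colSums(ab * copies[, f]) / colSums(ab)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "copy_number", feature = f, sample = truth$samples,
      expected = unname(ecn), stringsAsFactors = FALSE)
  }

  L <- truth$genome_length_bp
  Lc <- truth$classified_length_bp
  denom <- colSums(ab * as.numeric(L))
  for (g in truth$genomes) {
    genus <- lineage_at(truth$lineages[[g]], "genus")
    ep <- 100 * truth$mapped_fraction * ab[g, ] * Lc[[g]] / denom
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "percent", feature = genus, sample = truth$samples,
      expected = unname(ep), stringsAsFactors = FALSE)
  }

  ## expected share of mapped reads per function
  Lf <- truth$function_length_bp
  for (f in truth$functions) {
    share <- colSums(ab * Lf[, f]) / denom
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = "function_reads_prop", feature = f,
      sample = truth$samples, expected = unname(share),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
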