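# Hand-built two-genus toy project with numbers small enough to verify by
# hand, written in the loader dialect so tests exercise the full load path.
#
# Genus A (contig c1, 3000 bp): a1 900 bp K00001|COG0001, a2 1100 bp K00001,
#   a3 1000 bp unannotated and taxonomically unclassified, am 1000 bp
#   COG0468 marker.  Genus B (contig c2, 2000 bp): b1 1000 bp K00002|COG0002,
#   bm 500 bp COG0468.
# Reads (S1): a1 5, a2 15, a3 10, am 10, b1 30, bm 5 (75 mapped of 100
# total); S2 doubles everything (150 of 200).  Bases = reads * 100.
toy_lineage <- function(genus) {
  sprintf("k_Bacteria;p_P1;c_C1;o_O1;f_F1;g_%s;s_%s sp", genus, genus)
}

write_toy_dir <- function(dir = tempfile("toy")) {
  dir.create(dir, recursive = TRUE)
  writeLines(c("Sample\tTotal_reads", "S1\t100", "S2\t200"),
             file.path(dir, "samples.tsv"))
  orf <- data.frame(
    ORF_ID = c("a1", "a2", "a3", "am", "b1", "bm"),
    Contig_ID = c("c1", "c1", "c1", "c1", "c2", "c2"),
    Start = c(1, 1001, 2101, 3201, 1, 1101),
    Stop = c(900, 2100, 3100, 4200, 1000, 1600),
    Strand = c("+", "-", "+", "+", "+", "-"),
    Length_bp = c(900, 1100, 1000, 1000, 1000, 500),
    Tax = c(toy_lineage("A"), toy_lineage("A"), "", toy_lineage("A"),
            toy_lineage("B"), toy_lineage("B")),
    KEGG = c("K00001", "K00001", "", "", "K00002", ""),
    COG = c("COG0001", "", "", "COG0468", "COG0002", "COG0468"),
    PFAM = c("PF00001|PF00002", "", "", "", "", ""),
    stringsAsFactors = FALSE)
  reads <- c(5, 15, 10, 10, 30, 5)
  orf$Reads_S1 <- reads
  orf$Bases_S1 <- reads * 100
  orf$Coverage_S1 <- reads * 100 / orf$Length_bp
  orf$Reads_S2 <- reads * 2
  orf$Bases_S2 <- reads * 200
  orf$Coverage_S2 <- reads * 200 / orf$Length_bp
  write.table(orf, file.path(dir, "orfs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ctg <- data.frame(
    Contig_ID = c("c1", "c2"), Length_bp = c(4200, 2000),
    Tax = c(toy_lineage("A"), toy_lineage("B")),
    Bin_ID = c("binA", "binB"),
    Reads_S1 = c(40, 35), Bases_S1 = c(4000, 3500),
    Coverage_S1 = c(4000 / 4200, 3500 / 2000),
    Reads_S2 = c(80, 70), Bases_S2 = c(8000, 7000),
    Coverage_S2 = c(8000 / 4200, 7000 / 2000),
    stringsAsFactors = FALSE)
  write.table(ctg, file.path(dir, "contigs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c("Bin_ID\tMethod\tTax\tCompleteness\tContamination\tContigs",
               paste0("binA\tsynthetic\t", toy_lineage("A"), "\t95\t1\tc1"),
               paste0("binB\tsynthetic\t", toy_lineage("B"), "\t90\t2\tc2")),
             file.path(dir, "bins.tsv"))
  writeLines(c("DB\tID\tName\tHierarchy",
               "KEGG\tK00001\tAlcohol dehydrogenase\tMetabolism;Amino acid transport and metabolism",
               "KEGG\tK00002\tAldehyde reductase\tMetabolism;Carbohydrate metabolism",
               "COG\tCOG0468\tRecA/RadA recombinase\tInformation;Replication"),
             file.path(dir, "functions.tsv"))
  dir
}

load_toy <- function() {
  suppressMessages(load_project(write_toy_dir()))
}

# Random query-AST generator over a project's schema, plus an independent
# brute-force evaluator used as the oracle for the query engine.
rand_pred <- function(project) {
  kind <- sample(c("tax", "fun", "metric"), 1)
  if (kind == "tax") {
    rank <- sample(mg_ranks(), 1)
    vals <- lineage_at(project$contigs$table$tax, rank)
    vals <- vals[!is.na(vals)]
    value <- if (length(vals)) sample(vals, 1) else "Nothing"
    list(op = "pred", field = list(kind = "tax", rank = rank),
         cmp = sample(c("=", "!=", "contains", "matches"), 1),
         value = value)
  } else if (kind == "fun") {
    ids <- unlist(lapply(project$databases, function(db) {
      setdiff(rownames(project$functions[[db]]$reads), "Unclassified")
    }))
    value <- sample(ids, 1)
    cmp <- sample(c("=", "contains"), 1)
    if (runif(1) < 0.3) value <- substr(value, 1, nchar(value) - 1L)
    list(op = "pred", field = list(kind = "fun", db = NULL),
         cmp = cmp, value = value)
  } else {
    metric <- sample(c("cov", "tpm", "reads"), 1)
    s <- sample(project$samples, 1)
    m <- switch(metric, cov = project$contigs$cov,
                tpm = project$contigs$tpm, reads = project$contigs$reads)
    value <- as.numeric(quantile(m[, s], runif(1)))
    list(op = "pred",
         field = list(kind = "metric", metric = metric, sample = s),
         cmp = sample(c(">", ">=", "<", "<=", "=", "!="), 1),
         value = value)
  }
}

rand_ast <- function(project, depth = 3) {
  if (depth <= 0 || runif(1) < 0.35) return(rand_pred(project))
  op <- sample(c("AND", "OR", "NOT"), 1)
  if (op == "NOT") {
    list(op = "NOT", arg = rand_ast(project, depth - 1))
  } else {
    list(op = op, lhs = rand_ast(project, depth - 1),
         rhs = rand_ast(project, depth - 1))
  }
}

# Brute force: evaluate the tree for ONE contig at a time, straight from
# the raw tables, with no set algebra.
brute_contig_match <- function(project, node, cid) {
  if (node$op == "NOT") {
    return(!brute_contig_match(project, node$arg, cid))
  }
  if (node$op == "AND") {
    return(brute_contig_match(project, node$lhs, cid) &&
             brute_contig_match(project, node$rhs, cid))
  }
  if (node$op == "OR") {
    return(brute_contig_match(project, node$lhs, cid) ||
             brute_contig_match(project, node$rhs, cid))
  }
  f <- node$field
  ct <- project$contigs$table
  row <- which(ct$contig_id == cid)
  if (f$kind == "tax") {
    comp <- NA_character_
    for (part in strsplit(ct$tax[row], ";", fixed = TRUE)[[1]]) {
      pre <- c(k = "superkingdom", p = "phylum", c = "class", o = "order",
               f = "family", g = "genus", s = "species")[substr(part, 1, 1)]
      if (!is.na(pre) && pre == f$rank) comp <- substring(part, 3)
    }
    return(switch(node$cmp,
                  "=" = !is.na(comp) && tolower(comp) == tolower(node$value),
                  "!=" = !(!is.na(comp) &&
                             tolower(comp) == tolower(node$value)),
                  "contains" = !is.na(comp) &&
                    grepl(tolower(node$value), tolower(comp), fixed = TRUE),
                  "matches" = !is.na(comp) &&
                    grepl(node$value, comp, ignore.case = TRUE)))
  }
  if (f$kind == "metric") {
    m <- switch(f$metric, cov = project$contigs$cov,
                tpm = project$contigs$tpm, reads = project$contigs$reads)
    v <- m[cid, f$sample]
    return(switch(node$cmp, ">" = v > node$value, ">=" = v >= node$value,
                  "<" = v < node$value, "<=" = v <= node$value,
                  "=" = v == node$value, "!=" = v != node$value))
  }
  # fun predicate: loop over the contig's ORFs and their annotations
  orfs <- which(project$orfs$table$contig_id == cid)
  dbs <- if (is.null(f$db)) project$databases else f$db
  for (i in orfs) {
    for (db in dbs) {
      ids <- strsplit(project$orfs$table[[db]][i], "|", fixed = TRUE)[[1]]
      ids <- ids[nzchar(ids)]
      for (id in ids) {
        if (node$cmp == "=") {
          if (tolower(id) == tolower(node$value)) return(TRUE)
        } else {
          info <- project$functions[[db]]$info
          j <- which(info$id == id)
          hay <- paste(info$id[j], info$name[j], info$hierarchy[j])
          ok <- if (node$cmp == "matches") {
            grepl(node$value, hay, ignore.case = TRUE)
          } else {
            grepl(tolower(node$value), tolower(hay), fixed = TRUE)
          }
          if (ok) return(TRUE)
        }
      }
    }
  }
  FALSE
}

brute_evaluate <- function(project, ast) {
  ids <- project$contigs$table$contig_id
  sort(ids[vapply(ids, function(cid) {
    brute_contig_match(project, ast, cid)
  }, logical(1))])
}

quiet_generate <- function(...) {
  suppressWarnings(generate_project(...))
}
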