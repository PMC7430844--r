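# Metric definitions: RPK, the two-step TPM, function aggregation with
# assembly-wide average gene lengths, single-copy-gene copy numbers, and
# taxonomy percentages with Unclassified/Unmapped accounting.

test_that("RPK divides reads by feature length in kilobases", {
  reads <- matrix(c(10, 10, 0, 20), nrow = 2,
                  dimnames = list(c("f1", "f2"), c("S1", "S2")))
  rpk <- compute_rpk(reads, c(f1 = 1000, f2 = 2000))
  expect_equal(rpk["f1", "S1"], 10)
  expect_equal(rpk["f2", "S1"], 5)
  expect_equal(rpk["f1", "S2"], 0)
  expect_error(compute_rpk(reads, c(f1 = 0, f2 = 2000)), "length")
})

test_that("TPM normalises RPK per sample to one million", {
  rpk <- matrix(c(10, 5), nrow = 2, dimnames = list(c("f1", "f2"), "S1"))
  tpm <- compute_tpm(rpk)
  expect_equal(tpm["f1", "S1"], 666666.67, tolerance = 1e-8)
  expect_equal(tpm["f2", "S1"], 333333.33, tolerance = 1e-8)
  # a lone feature takes the whole million
  expect_equal(compute_tpm(matrix(3, 1, 1, dimnames = list("x", "S1")))[1],
               1e6)
  # all-zero sample: zero column plus a warning, not an error
  z <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "S1"))
  expect_warning(res <- compute_tpm(z), "all-zero")
  expect_equal(unname(res[, 1]), c(0, 0))
})

make_orf_frame <- function() {
  data.frame(
    orf_id = c("o1", "o2", "o3"),
    length_bp = c(900, 1100, 1000),
    KEGG = c("K00001", "K00001", ""),
    PFAM = c("PF00001|PF00002", "", ""),
    stringsAsFactors = FALSE)
}

test_that("function aggregation sums reads and averages gene length", {
  ot <- make_orf_frame()
  reads <- matrix(c(5, 15, 10), 3, dimnames = list(ot$orf_id, "S1"))
  bases <- reads * 100
  cov <- bases / ot$length_bp
  prof <- aggregate_functions(ot, reads, bases, cov, "KEGG")
  expect_equal(prof$reads["K00001", "S1"], 20)
  expect_equal(unname(prof$avg_length["K00001"]), 1000)
  expect_equal(prof$reads["Unclassified", "S1"], 10)
  # function RPK = 20 reads / 1 kb; with Unclassified RPK 10 -> TPM split
  prof <- compute_function_tpm(prof)
  expect_equal(prof$tpm["K00001", "S1"], 666666.67, tolerance = 1e-8)
  expect_equal(prof$tpm["Unclassified", "S1"], 333333.33, tolerance = 1e-8)
  expect_equal(colSums(prof$tpm), c(S1 = 1e6), tolerance = 1e-9)
})

test_that("an ORF with several annotations counts fully toward each", {
  ot <- make_orf_frame()
  reads <- matrix(c(5, 15, 10), 3, dimnames = list(ot$orf_id, "S1"))
  prof <- aggregate_functions(ot, reads, reads * 100,
                              reads * 100 / ot$length_bp, "PFAM")
  expect_equal(prof$reads["PF00001", "S1"], 5)
  expect_equal(prof$reads["PF00002", "S1"], 5)
  # fully counted in both rows: function reads are non-additive to totals
  expect_gt(sum(prof$reads[, "S1"]), sum(reads))
})

test_that("all-unannotated ORFs collapse into a lone Unclassified row", {
  ot <- make_orf_frame()
  ot$KEGG <- ""
  reads <- matrix(c(5, 15, 10), 3, dimnames = list(ot$orf_id, "S1"))
  prof <- aggregate_functions(ot, reads, reads * 100,
                              reads * 100 / ot$length_bp, "KEGG")
  expect_identical(rownames(prof$reads), "Unclassified")
  expect_equal(prof$reads["Unclassified", "S1"], 30)
})

test_that("copy number is coverage over marker coverage", {
  cov <- matrix(c(6, 3, 2, 3, 10), 5, 1,
                dimnames = list(c("COG0001", "COG0468", "COG0012",
                                  "COG0016", "COG0018"), "S1"))
  prof <- structure(list(cov = cov,
                         reads = cov, bases = cov,
                         info = data.frame(id = rownames(cov), name = "",
                                           hierarchy = "")),
                    class = "function_profile")
  out <- compute_copy_number(prof)
  expect_equal(out$copy_number["COG0001", "S1"], 2)
  expect_equal(out$copy_number["COG0468", "S1"], 1)  # ratio with itself
  # usicg_median: median of {2, 3, 10} = 3
  out2 <- suppressWarnings(compute_copy_number(
    prof, mode = "usicg_median",
    usicg_list = c("COG0012", "COG0016", "COG0018")))
  expect_equal(out2$copy_number["COG0001", "S1"], 2)
  expect_equal(out2$marker$coverage[["S1"]], 3)
  # marker absent from the universe entirely
  prof2 <- prof
  rownames(prof2$cov) <- sub("COG0468", "COG9999", rownames(prof2$cov))
  expect_error(compute_copy_number(prof2), "marker gene absent")
})

test_that("taxonomy percent uses total reads and an Unmapped row", {
  ot <- data.frame(orf_id = c("o1", "o2"), contig_id = c("c1", "c2"),
                   tax = c(toy_lineage("A"), toy_lineage("B")),
                   length_bp = c(1000, 1000), stringsAsFactors = FALSE)
  reads <- matrix(c(30, 70), 2, dimnames = list(ot$orf_id, "S1"))
  tp <- aggregate_taxonomy(ot, reads, "genus", c(S1 = 100))
  expect_equal(tp$percent["A", "S1"], 30)
  expect_equal(tp$percent["B", "S1"], 70)
  expect_equal(tp$percent["Unmapped", "S1"], 0)
  # total 200 with the same 100 mapped: 15 / 35 / Unmapped 50
  tp2 <- aggregate_taxonomy(ot, reads, "genus", c(S1 = 200))
  expect_equal(tp2$percent["A", "S1"], 15)
  expect_equal(tp2$percent["B", "S1"], 35)
  expect_equal(tp2$reads["Unmapped", "S1"], 100)
  expect_equal(tp2$percent["Unmapped", "S1"], 50)
  expect_equal(colSums(tp2$percent), c(S1 = 100))
  expect_error(aggregate_taxonomy(ot, reads, "tribe", c(S1 = 100)))
})

test_that("TPM, copy numbers and percents are depth-scale equivariant", {
  dir <- write_toy_dir()
  p <- suppressMessages(load_project(dir))
  # scale sample S1 by k = 3: reads, bases and total reads
  k <- 3
  odf <- read.delim(file.path(dir, "orfs.tsv"), check.names = FALSE)
  odf$Reads_S1 <- odf$Reads_S1 * k
  odf$Bases_S1 <- odf$Bases_S1 * k
  odf$Coverage_S1 <- odf$Coverage_S1 * k
  write.table(odf, file.path(dir, "orfs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cdf <- read.delim(file.path(dir, "contigs.tsv"), check.names = FALSE)
  for (col in c("Reads_S1", "Bases_S1", "Coverage_S1")) {
    cdf[[col]] <- cdf[[col]] * k
  }
  write.table(cdf, file.path(dir, "contigs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sdf <- read.delim(file.path(dir, "samples.tsv"))
  sdf$Total_reads[sdf$Sample == "S1"] <- 100 * k
  write.table(sdf, file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  p2 <- suppressMessages(load_project(dir))
  expect_equal(p2$orfs$tpm[, "S1"], p$orfs$tpm[, "S1"])
  expect_equal(p2$functions$KEGG$tpm[, "S1"], p$functions$KEGG$tpm[, "S1"])
  expect_equal(p2$functions$KEGG$copy_number[, "S1"],
               p$functions$KEGG$copy_number[, "S1"])
  expect_equal(p2$taxonomy$genus$percent[, "S1"],
               p$taxonomy$genus$percent[, "S1"])
})

test_that("permuting function rows leaves TPM values unchanged", {
  p <- load_toy()
  prof <- p$functions$KEGG
  perm <- rev(seq_len(nrow(prof$reads)))
  prof2 <- prof
  for (m in c("reads", "bases", "cov")) {
    prof2[[m]] <- prof[[m]][perm, , drop = FALSE]
  }
  prof2$avg_length <- prof$avg_length[perm]
  tpm2 <- compute_function_tpm(prof2)$tpm
  expect_equal(tpm2[rownames(prof$tpm), ], prof$tpm)
})
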