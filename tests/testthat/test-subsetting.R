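# Subsetting semantics: universe selection, rescaling vs carrying parent
# values, percent accounting, combination.

test_that("tax subset selects contigs by lineage plus all their ORFs", {
  p <- load_toy()
  s <- subset_tax(p, "genus", "A")
  expect_setequal(s$contigs$table$contig_id, "c1")
  # a3 is taxonomically unclassified but sits on c1: kept
  expect_setequal(s$orfs$table$orf_id, c("a1", "a2", "a3", "am"))
  expect_error(subset_tax(p, "genus", "Z"), "not found")
  # near-match listed for typos
  expect_error(subset_tax(p, "species", "A spp"), "did you mean")
})

test_that("subset of the whole universe reproduces the parent profiles", {
  p <- load_toy()
  s <- subset_tax(p, "superkingdom", "Bacteria")
  expect_equal(s$functions$KEGG$tpm, p$functions$KEGG$tpm)
  expect_equal(s$functions$COG$copy_number, p$functions$COG$copy_number)
  expect_equal(s$taxonomy$genus$percent, p$taxonomy$genus$percent)
})

test_that("rescaled tax subset renormalises TPM and marker copy number", {
  p <- load_toy()
  s <- subset_tax(p, "genus", "A")
  expect_equal(colSums(s$functions$KEGG$tpm), c(S1 = 1e6, S2 = 1e6),
               tolerance = 1e-9)
  # parent-restricted rows sum to less than a million
  ids <- rownames(s$functions$KEGG$tpm)
  expect_lt(sum(p$functions$KEGG$tpm[ids, "S1"]), 1e6)
  expect_equal(unname(s$functions$COG$copy_number["COG0468", ]), c(1, 1))
  # marker coverage is now genus A's marker alone (am: cov 1.0 in S1)
  expect_equal(s$functions$COG$marker$coverage[["S1"]], 1.0)
})

test_that("non-rescaled tax subset copies parent values row-for-row", {
  p <- load_toy()
  s <- subset_tax(p, "genus", "A", rescale_tpm = FALSE,
                  rescale_copy_number = FALSE)
  for (db in p$databases) {
    ids <- rownames(s$functions[[db]]$tpm)
    expect_identical(s$functions[[db]]$tpm, p$functions[[db]]$tpm[ids, ])
    expect_identical(s$functions[[db]]$copy_number,
                     p$functions[[db]]$copy_number[ids, ])
  }
  expect_identical(s$orfs$tpm, p$orfs$tpm[s$orfs$table$orf_id, ])
})

test_that("taxonomy percent is never rescaled in tax/bin subsets", {
  p <- load_toy()
  s <- subset_tax(p, "genus", "A")
  expect_equal(s$taxonomy$genus$percent["A", ],
               p$taxonomy$genus$percent["A", ])
  # the non-selected reads fall into Unmapped, keeping columns at 100
  expect_equal(colSums(s$taxonomy$genus$percent), c(S1 = 100, S2 = 100))
})

test_that("a bin that equals a taxon gives the same subset", {
  p <- load_toy()
  st <- subset_tax(p, "genus", "A")
  sb <- subset_bins(p, "binA")
  expect_equal(sb$functions$KEGG$tpm, st$functions$KEGG$tpm)
  expect_equal(sb$functions$COG$copy_number, st$functions$COG$copy_number)
  expect_equal(sb$taxonomy$genus$percent, st$taxonomy$genus$percent)
  expect_equal(sb$orfs$table, st$orfs$table)
  expect_error(subset_bins(p, "nope"), "unknown bin")
})

test_that("fun subset keeps parent normalisations and reweights percent", {
  p <- load_toy()
  s <- subset_fun(p, "K00001")
  expect_setequal(s$orfs$table$orf_id, c("a1", "a2"))
  expect_setequal(s$contigs$table$contig_id, "c1")
  # TPM / copy number carried from the parent, not rescaled
  ids <- rownames(s$functions$KEGG$tpm)
  expect_identical(s$functions$KEGG$tpm, p$functions$KEGG$tpm[ids, ])
  expect_false(isTRUE(all.equal(colSums(s$functions$KEGG$tpm),
                                c(S1 = 1e6, S2 = 1e6))))
  # percent: only the matched ORFs' reads count, parent denominator
  expect_equal(s$taxonomy$genus$percent["A", "S1"], 100 * 20 / 100)
  expect_equal(s$taxonomy$genus$percent["B", "S1"], 0)
  # all parent taxa rows kept, zero-filled
  expect_setequal(rownames(s$taxonomy$genus$percent),
                  rownames(p$taxonomy$genus$percent))
  expect_equal(colSums(s$taxonomy$genus$percent), c(S1 = 100, S2 = 100))
})

test_that("fun subset matches names, hierarchy and regex", {
  p <- load_toy()
  # name match (functions.tsv carries "Alcohol dehydrogenase")
  s <- subset_fun(p, "alcohol dehydro")
  expect_setequal(s$orfs$table$orf_id, c("a1", "a2"))
  # hierarchy match selects everything under the category
  s2 <- subset_fun(p, "Amino acid transport")
  expect_setequal(s2$orfs$table$orf_id, c("a1", "a2"))
  expect_error(subset_fun(p, "Amino acid transport",
                          search_hierarchy = FALSE), "no function matches")
  # regex bracket class
  s3 <- subset_fun(p, "K0000[12]", use_regex = TRUE)
  expect_setequal(s3$orfs$table$orf_id, c("a1", "a2", "b1"))
  expect_error(subset_fun(p, "K0000[", use_regex = TRUE), "invalid regex")
  expect_error(subset_fun(p, character(0)), "at least one pattern")
  # a pattern matching every annotation returns the parent universe
  s4 <- subset_fun(p, c("K", "COG", "PF"))
  expect_setequal(s4$orfs$table$orf_id,
                  c("a1", "a2", "am", "b1", "bm"))
})

test_that("subsetting is idempotent and monotone", {
  gp <- quiet_generate(3, 2, 10, depth = 5000, seed = 21)
  p <- gp$project
  s1 <- subset_tax(p, "genus", "Genus2")
  s2 <- subset_tax(s1, "genus", "Genus2")
  expect_equal(s2$orfs$table, s1$orfs$table)
  expect_equal(s2$functions$KEGG$tpm, s1$functions$KEGG$tpm)
  expect_true(all(s1$orfs$table$orf_id %in% p$orfs$table$orf_id))
  expect_true(all(s1$contigs$table$contig_id %in%
                    p$contigs$table$contig_id))
})

test_that("genus subsets partition the function reads of the parent", {
  gp <- quiet_generate(3, 2, 10, depth = 5000, seed = 31)
  p <- gp$project
  genera <- paste0("Genus", 1:3)
  acc <- NULL
  for (g in genera) {
    s <- subset_tax(p, "genus", g)
    m <- s$functions$KEGG$reads
    full <- metaprof:::zero_matrix(rownames(p$functions$KEGG$reads),
                                   p$samples)
    full[rownames(m), ] <- m
    acc <- if (is.null(acc)) full else acc + full
  }
  expect_equal(acc, p$functions$KEGG$reads)
})

test_that("combining complementary subsets restores the full project", {
  p <- load_toy()
  cmb <- combine_projects(list(subset_tax(p, "genus", "A"),
                               subset_tax(p, "genus", "B")),
                          rescale_tpm = TRUE, rescale_copy_number = TRUE)
  expect_setequal(cmb$orfs$table$orf_id, p$orfs$table$orf_id)
  ids <- rownames(p$functions$KEGG$tpm)
  expect_equal(cmb$functions$KEGG$tpm[ids, ], p$functions$KEGG$tpm)
  expect_equal(cmb$functions$COG$copy_number[rownames(p$functions$COG$cov), ],
               p$functions$COG$copy_number)
  expect_equal(cmb$taxonomy$genus$percent[rownames(p$taxonomy$genus$percent), ],
               p$taxonomy$genus$percent)
})

test_that("combine deduplicates shared rows and rejects mismatches", {
  p <- load_toy()
  a <- subset_fun(p, "K00001")
  b <- subset_fun(p, "COG0001")   # shares ORF a1 / contig c1 with a
  cmb <- combine_projects(list(a, b))
  expect_equal(sum(cmb$orfs$table$orf_id == "a1"), 1L)
  # carried-over values agree, so non-rescaled combination succeeds
  expect_identical(cmb$functions$KEGG$tpm["K00001", ],
                   p$functions$KEGG$tpm["K00001", ])
  # identity: combine of a single project is that project
  expect_identical(combine_projects(list(p)), p)
  # different parents are refused
  gp <- quiet_generate(2, 2, 6, depth = 5000, seed = 2)
  expect_error(combine_projects(list(p, gp$project)), "sample mismatch")
})
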