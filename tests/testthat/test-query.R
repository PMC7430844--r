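# Query language: grammar, precedence, evaluation semantics, oracle
# equivalence and boolean laws, display filtering.

test_that("single predicates parse into the expected tree", {
  q <- parse_query("tax:genus = 'Prevotella'")
  expect_s3_class(q, "query_ast")
  expect_identical(q$op, "pred")
  expect_identical(q$field, list(kind = "tax", rank = "genus"))
  expect_identical(q$cmp, "=")
  expect_identical(q$value, "Prevotella")

  q2 <- parse_query(
    "fun contains 'Tryptophan biosynthesis' AND (cov['S1'] > 5 OR cov['S2'] > 5)")
  expect_identical(q2$op, "AND")
  expect_identical(q2$lhs$op, "pred")
  expect_identical(q2$rhs$op, "OR")
  expect_identical(q2$rhs$lhs$field$metric, "cov")

  expect_error(parse_query("tax:tribe = 'x'"), "unknown rank")
  expect_error(parse_query("tax:genus ="), "unexpected end")
  expect_error(parse_query("cov['S1'] > "), "unexpected end")
  expect_error(parse_query("tax:genus = 'A' extra"), "trailing input")
  expect_error(parse_query(""), "empty query")
})

test_that("schema checking rejects unknown samples and databases", {
  p <- load_toy()
  expect_error(parse_query("cov['S9'] > 1", p), "unknown sample")
  expect_error(parse_query("fun:tigrfam contains 'x'", p),
               "unknown annotation database")
  expect_silent(parse_query("fun:kegg contains 'x'", p))
})

test_that("render/parse round trip preserves the tree", {
  p <- load_toy()
  set.seed(17)
  for (i in 1:25) {
    ast <- rand_ast(p, depth = 3)
    text <- render_query(structure(ast, class = "query_ast"))
    expect_identical(unclass(parse_query(text)), ast, label = text)
  }
})

test_that("AND binds tighter than OR", {
  p <- load_toy()
  # a AND b OR c === (a AND b) OR c, checked by evaluation equality
  a <- "tax:genus = 'A'"; b <- "cov['S1'] > 1"; c <- "fun = 'K00002'"
  lhs <- evaluate_query(p, sprintf("%s AND %s OR %s", a, b, c))
  rhs <- evaluate_query(p, sprintf("(%s AND %s) OR %s", a, b, c))
  other <- evaluate_query(p, sprintf("%s AND (%s OR %s)", a, b, c))
  expect_identical(lhs, rhs)
  expect_false(identical(lhs, other))  # grouping matters on this fixture
})

test_that("predicate families behave on the toy fixture", {
  p <- load_toy()
  expect_identical(evaluate_query(p, "tax:superkingdom = 'Bacteria'"),
                   c("c1", "c2"))
  expect_identical(evaluate_query(p, "tax:genus = 'a'"), "c1")  # case-insens
  expect_identical(evaluate_query(p, "fun = 'K00002'"), "c2")
  expect_identical(evaluate_query(p, "fun contains 'recombinase'"),
                   c("c1", "c2"))
  expect_identical(evaluate_query(p, "fun:pfam contains 'PF00002'"), "c1")
  expect_identical(evaluate_query(p, "reads['S1'] > 38"), "c1")
  expect_identical(evaluate_query(p, "cov['S2'] >= 3.5"), "c2")
  # complement law within the contig universe
  inner <- evaluate_query(p, "fun contains 'K00001'")
  comp <- evaluate_query(p, "NOT fun contains 'K00001'")
  expect_length(intersect(inner, comp), 0)
  expect_setequal(union(inner, comp), p$contigs$table$contig_id)
})

test_that("evaluation equals per-contig brute force on random cases", {
  set.seed(4242)
  n_cases <- 120
  fixtures <- lapply(1:6, function(i) {
    quiet_generate(sample(2:4, 1), 2, sample(5:10, 1), depth = 3000,
                   seed = 1000 + i)$project
  })
  for (i in seq_len(n_cases)) {
    p <- fixtures[[(i %% length(fixtures)) + 1L]]
    ast <- rand_ast(p, depth = 4)
    got <- evaluate_query(p, structure(ast, class = "query_ast"))
    want <- brute_evaluate(p, ast)
    expect_identical(got, want,
                     label = render_query(structure(ast,
                                                    class = "query_ast")))
  }
})

test_that("De Morgan transforms select identical contig sets", {
  set.seed(77)
  p <- quiet_generate(3, 2, 8, depth = 3000, seed = 55)$project
  for (i in 1:40) {
    a <- rand_ast(p, depth = 2)
    b <- rand_ast(p, depth = 2)
    nand <- list(op = "NOT", arg = list(op = "AND", lhs = a, rhs = b))
    dm_and <- list(op = "OR", lhs = list(op = "NOT", arg = a),
                   rhs = list(op = "NOT", arg = b))
    expect_identical(evaluate_query(p, structure(nand, class = "query_ast")),
                     evaluate_query(p, structure(dm_and,
                                                 class = "query_ast")))
    nor <- list(op = "NOT", arg = list(op = "OR", lhs = a, rhs = b))
    dm_or <- list(op = "AND", lhs = list(op = "NOT", arg = a),
                  rhs = list(op = "NOT", arg = b))
    expect_identical(evaluate_query(p, structure(nor, class = "query_ast")),
                     evaluate_query(p, structure(dm_or,
                                                 class = "query_ast")))
  }
})

test_that("AND never enlarges and OR never shrinks a selection", {
  set.seed(88)
  p <- quiet_generate(3, 2, 8, depth = 3000, seed = 56)$project
  for (i in 1:30) {
    a <- rand_ast(p, depth = 2)
    b <- rand_pred(p)
    base <- evaluate_query(p, structure(a, class = "query_ast"))
    anded <- evaluate_query(p, structure(list(op = "AND", lhs = a, rhs = b),
                                         class = "query_ast"))
    ored <- evaluate_query(p, structure(list(op = "OR", lhs = a, rhs = b),
                                        class = "query_ast"))
    expect_true(all(anded %in% base))
    expect_true(all(base %in% ored))
  }
})

test_that("filter_for_display caps, subsets and reports metadata", {
  p <- load_toy()
  expect_error(filter_for_display(p, "tax:genus = 'Z'"), "no contigs")
  expect_error(filter_for_display(p, "tax:superkingdom = 'Bacteria'",
                                  max_contigs = 1),
               "selected 2 contigs.*cap of 1")
  fd <- filter_for_display(p, "fun contains 'K00001' AND cov['S1'] > 0.5")
  expect_identical(fd$metadata$contig_id, "c1")
  expect_equal(nrow(fd$metadata), nrow(fd$project$contigs$table))
  expect_true(grepl("K00001", fd$metadata$matched_annotations[1]))
  # TPM not rescaled in the display subset
  ids <- rownames(fd$project$functions$KEGG$tpm)
  expect_identical(fd$project$functions$KEGG$tpm,
                   p$functions$KEGG$tpm[ids, ])
  # fixed point: re-filtering the subset with the same query keeps all
  fd2 <- filter_for_display(fd$project,
                            "fun contains 'K00001' AND cov['S1'] > 0.5")
  expect_setequal(fd2$metadata$contig_id, fd$metadata$contig_id)
})
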