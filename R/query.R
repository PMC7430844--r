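## Boolean query language over contigs, for prefiltering large assemblies
## before visualization. Grammar (keywords case-insensitive; string
## literals single-quoted; precedence NOT > AND > OR; parentheses group):
##
##   query     := or
##   or        := and ( OR and )*
##   and       := not ( AND not )*
##   not       := NOT not | '(' or ')' | predicate
##   predicate := 'tax' ':' rank strop string
##              | 'fun' [ ':' db ] strop string
##              | metric '[' string ']' cmpop number
##   strop     := '=' | '!=' | 'contains' | 'matches'
##   cmpop     := '>' | '>=' | '<' | '<=' | '=' | '!='
##   metric    := 'cov' | 'tpm' | 'reads'
##
## Predicate semantics over a contig:
##   tax:<rank> tests the contig lineage component at that rank ('='
##     case-insensitive equality; 'contains' substring; 'matches' regex;
##     an unassigned rank satisfies only '!=').
##   fun is true iff at least one ORF on the contig carries a matching
##     annotation ('=' exact id; 'contains'/'matches' also search function
##     names and hierarchy levels). 'fun:kegg' restricts to one database.
##   cov/tpm/reads['<sample>'] compare the contig's per-sample value.

.tokenize_query <- function(text) {
  tokens <- list()
  i <- 1L; n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    rest <- substring(text, i)
    if (grepl("^\\s", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (ch == "[") { push("lbracket", "[", i); i <- i + 1L; next }
    if (ch == "]") { push("rbracket", "]", i); i <- i + 1L; next }
    if (ch == ":") { push("colon", ":", i); i <- i + 1L; next }
    if (ch == "'") {
      m <- regmatches(rest, regexpr("^'[^']*'", rest))
      abort_if(length(m) == 0, "query syntax error at position %d: %s",
               i, "unterminated string literal")
      push("string", substr(m, 2, nchar(m) - 1L), i)
      i <- i + nchar(m); next
    }
    op <- regmatches(rest, regexpr("^(!=|>=|<=|=|>|<|≠|≥|≤)",
                                   rest))
    if (length(op)) {
      val <- unname(c("≠" = "!=", "≥" = ">=", "≤" = "<=")[op])
      push("op", if (is.na(val)) op else val, i)
      i <- i + nchar(op); next
    }
    num <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
                                    rest))
    if (length(num)) {
      push("number", as.numeric(num), i)
      i <- i + nchar(num); next
    }
    wd <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(wd)) {
      lw <- tolower(wd)
      type <- if (lw %in% c("and", "or", "not")) lw
      else if (lw %in% c("contains", "matches")) "op"
      else "word"
      push(type, if (type == "op") lw else wd, i)
      i <- i + nchar(wd); next
    }
    stop(sprintf("query syntax error at position %d: unexpected '%s'",
                 i, ch), call. = FALSE)
  }
  tokens
}

#' Parse a contig query into an expression tree
#'
#' See the package vignette for the grammar: boolean combinations
#' (`NOT` > `AND` > `OR`, parentheses allowed) of taxonomy predicates
#' (`tax:genus = 'Prevotella'`), function predicates
#' (`fun contains 'tryptophan'`, optionally `fun:kegg`) and per-sample
#' abundance predicates (`cov['S1'] > 5`, also `tpm[...]`, `reads[...]`).
#' Rendering the tree with [render_query()] and reparsing yields an equal
#' tree.
#'
#' @param text Query text.
#' @param project Optional `mg_project`; when given, sample names and
#'   database names are checked at parse time.
#' @return A `query_ast` list.
#' @export
parse_query <- function(text, project = NULL) {
  abort_if(!is.character(text) || !nzchar(trimws(text)), "empty query")
  tokens <- .tokenize_query(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function(type = NULL) {
    tk <- peek()
    abort_if(is.null(tk), "query syntax error: unexpected end of query")
    abort_if(!is.null(type) && tk$type != type,
             "query syntax error at position %d: expected %s, got '%s'",
             tk$pos, type, as.character(tk$value))
    pos <<- pos + 1L
    tk
  }

  parse_or <- function() {
    node <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      take("or")
      node <- list(op = "OR", lhs = node, rhs = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_not()
    while (!is.null(peek()) && peek()$type == "and") {
      take("and")
      node <- list(op = "AND", lhs = node, rhs = parse_not())
    }
    node
  }
  parse_not <- function() {
    tk <- peek()
    abort_if(is.null(tk), "query syntax error: unexpected end of query")
    if (tk$type == "not") {
      take("not")
      return(list(op = "NOT", arg = parse_not()))
    }
    if (tk$type == "lparen") {
      take("lparen")
      node <- parse_or()
      take("rparen")
      return(node)
    }
    parse_predicate()
  }
  parse_predicate <- function() {
    tk <- take("word")
    w <- tolower(tk$value)
    if (w == "tax") {
      take("colon")
      rk <- take("word")
      rank <- tolower(rk$value)
      abort_if(!(rank %in% mg_ranks()),
               "unknown rank '%s' at position %d", rk$value, rk$pos)
      op <- take("op")
      abort_if(!(op$value %in% c("=", "!=", "contains", "matches")),
               "operator '%s' not valid for tax predicates", op$value)
      val <- take("string")
      field <- list(kind = "tax", rank = rank)
    } else if (w == "fun") {
      db <- NULL
      if (!is.null(peek()) && peek()$type == "colon") {
        take("colon")
        db <- take("word")$value
      }
      op <- take("op")
      abort_if(!(op$value %in% c("=", "contains", "matches")),
               "operator '%s' not valid for fun predicates", op$value)
      val <- take("string")
      field <- list(kind = "fun", db = db)
    } else if (w %in% c("cov", "tpm", "reads")) {
      take("lbracket")
      smp <- take("string")
      take("rbracket")
      op <- take("op")
      abort_if(!(op$value %in% c(">", ">=", "<", "<=", "=", "!=")),
               "operator '%s' not valid for abundance predicates",
               op$value)
      val <- take("number")
      field <- list(kind = "metric", metric = w, sample = smp$value)
    } else {
      stop(sprintf(
        "query syntax error at position %d: unknown predicate '%s'",
        tk$pos, tk$value), call. = FALSE)
    }
    list(op = "pred", field = field, cmp = op$value, value = val$value)
  }

  ast <- parse_or()
  tk <- peek()
  abort_if(!is.null(tk),
           "query syntax error at position %d: trailing input '%s'",
           tk$pos, as.character(tk$value))
  if (!is.null(project)) .check_query_schema(ast, project)
  structure(ast, class = "query_ast")
}

.check_query_schema <- function(node, project) {
  if (node$op == "pred") {
    f <- node$field
    if (f$kind == "metric") {
      abort_if(!(f$sample %in% project$samples),
               "unknown sample '%s' in query", f$sample)
    }
    if (f$kind == "fun" && !is.null(f$db)) {
      abort_if(!(tolower(f$db) %in% tolower(project$databases)),
               "unknown annotation database '%s' in query", f$db)
    }
  } else if (node$op == "NOT") {
    .check_query_schema(node$arg, project)
  } else {
    .check_query_schema(node$lhs, project)
    .check_query_schema(node$rhs, project)
  }
  invisible(TRUE)
}

#' Render a query tree back to query text
#'
#' Produces a fully parenthesised text form; `parse_query(render_query(x))`
#' equals `x`.
#'
#' @param ast A `query_ast`.
#' @return Query text.
#' @export
render_query <- function(ast) {
  node <- unclass(ast)
  if (node$op == "pred") {
    f <- node$field
    lhs <- switch(f$kind,
                  tax = paste0("tax:", f$rank),
                  fun = if (is.null(f$db)) "fun" else paste0("fun:", f$db),
                  metric = sprintf("%s['%s']", f$metric, f$sample))
    val <- if (is.numeric(node$value)) sprintf("%.17g", node$value)
    else sprintf("'%s'", node$value)
    return(paste(lhs, node$cmp, val))
  }
  if (node$op == "NOT") return(paste0("NOT (", render_query(node$arg), ")"))
  paste0("(", render_query(node$lhs), " ", node$op, " ",
         render_query(node$rhs), ")")
}

#' @export
print.query_ast <- function(x, ...) {
  cat(render_query(x), "\n")
  invisible(x)
}

## Logical vector over contigs for one predicate.
.eval_predicate <- function(project, pred) {
  ct <- project$contigs$table
  f <- pred$field
  if (f$kind == "tax") {
    comp <- lineage_at(ct$tax, f$rank)
    hit <- switch(pred$cmp,
      "=" = !is.na(comp) & tolower(comp) == tolower(pred$value),
      "!=" = !(!is.na(comp) & tolower(comp) == tolower(pred$value)),
      "contains" = !is.na(comp) &
        grepl(tolower(pred$value), tolower(comp), fixed = TRUE),
      "matches" = !is.na(comp) & grepl(pred$value, comp,
                                       ignore.case = TRUE))
    return(stats::setNames(hit, ct$contig_id))
  }
  if (f$kind == "metric") {
    m <- switch(f$metric, cov = project$contigs$cov,
                tpm = project$contigs$tpm, reads = project$contigs$reads)
    abort_if(!(f$sample %in% colnames(m)),
             "unknown sample '%s' in query", f$sample)
    v <- m[ct$contig_id, f$sample]
    hit <- switch(pred$cmp,
                  ">" = v > pred$value, ">=" = v >= pred$value,
                  "<" = v < pred$value, "<=" = v <= pred$value,
                  "=" = v == pred$value, "!=" = v != pred$value)
    return(stats::setNames(hit, ct$contig_id))
  }
  ## fun predicate: a contig qualifies iff >= 1 of its ORFs matches
  dbs <- if (is.null(f$db)) project$databases else {
    project$databases[tolower(project$databases) == tolower(f$db)]
  }
  abort_if(length(dbs) == 0, "unknown annotation database '%s' in query",
           f$db %||% "")
  orf_hit <- rep(FALSE, nrow(project$orfs$table))
  for (db in dbs) {
    ann <- split_annotations(project$orfs$table[[db]])
    if (pred$cmp == "=") {
      orf_hit <- orf_hit | vapply(ann, function(a) {
        any(tolower(a) == tolower(pred$value))
      }, logical(1))
    } else {
      ids <- match_function_ids(project$functions[[db]], pred$value,
                                use_regex = (pred$cmp == "matches"),
                                search_hierarchy = TRUE)
      if (length(ids)) {
        orf_hit <- orf_hit | vapply(ann, function(a) any(a %in% ids),
                                    logical(1))
      }
    }
  }
  with_hit <- unique(project$orfs$table$contig_id[orf_hit])
  stats::setNames(ct$contig_id %in% with_hit, ct$contig_id)
}

.eval_node <- function(project, node) {
  switch(node$op,
         pred = .eval_predicate(project, node),
         NOT = !.eval_node(project, node$arg),
         AND = .eval_node(project, node$lhs) & .eval_node(project,
                                                          node$rhs),
         OR = .eval_node(project, node$lhs) | .eval_node(project,
                                                         node$rhs))
}

#' Evaluate a query against a project
#'
#' @param project An `mg_project`.
#' @param ast A `query_ast` from [parse_query()], or query text (parsed on
#'   the fly).
#' @return Sorted character vector of the contig identifiers selected.
#' @export
evaluate_query <- function(project, ast) {
  if (is.character(ast)) ast <- parse_query(ast, project)
  hit <- .eval_node(project, unclass(ast))
  sort(names(hit)[hit])
}

## Collect the fun predicates of a tree (for display metadata).
.collect_fun_preds <- function(node) {
  if (node$op == "pred") {
    if (node$field$kind == "fun") return(list(node)) else return(list())
  }
  if (node$op == "NOT") return(.collect_fun_preds(node$arg))
  c(.collect_fun_preds(node$lhs), .collect_fun_preds(node$rhs))
}

#' Filter a project down to a displayable contig selection
#'
#' Evaluates a query and, when the selection is within `max_contigs`,
#' returns the selected contigs as a non-rescaled child project together
#' with a per-contig metadata table (lineage, bin, per-sample coverage and
#' the annotations of ORFs matched by the query's function predicates)
#' suitable for import into external visualization tools. Large assemblies
#' choke interactive displays; selections beyond the cap are refused with
#' the count, so the query can be tightened.
#'
#' @param project An `mg_project`.
#' @param query_text Query text (see [parse_query()]).
#' @param max_contigs Refuse selections larger than this (default 20000).
#' @return A list with `project` (the contig subset, TPM and copy numbers
#'   kept from the parent) and `metadata` (one row per selected contig).
#' @export
filter_for_display <- function(project, query_text, max_contigs = 20000) {
  ast <- parse_query(query_text, project)
  sel <- evaluate_query(project, ast)
  abort_if(length(sel) == 0, "query selected no contigs")
  abort_if(length(sel) > max_contigs,
           paste0("query selected %d contigs, above the display cap of ",
                  "%d; tighten the query"),
           length(sel), max_contigs)

  contig_keep <- project$contigs$table$contig_id %in% sel
  orf_keep <- project$orfs$table$contig_id %in% sel
  sub <- .subset_project(project, orf_keep, contig_keep,
                         rescale_tpm = FALSE, rescale_copy_number = FALSE,
                         origin = "query",
                         description = paste("query:", render_query(ast)))

  fun_preds <- .collect_fun_preds(unclass(ast))
  matched_ann <- stats::setNames(rep("", length(sel)), sel)
  if (length(fun_preds)) {
    ot <- project$orfs$table
    orf_hit <- rep(FALSE, nrow(ot))
    for (fp in fun_preds) {
      hitc <- .eval_predicate(project, fp)  # contig level
      dbs <- if (is.null(fp$field$db)) project$databases else {
        project$databases[tolower(project$databases) ==
                            tolower(fp$field$db)]
      }
      for (db in dbs) {
        ann <- split_annotations(ot[[db]])
        ids <- if (fp$cmp == "=") {
          ids_all <- rownames(project$functions[[db]]$reads)
          ids_all[tolower(ids_all) == tolower(fp$value)]
        } else {
          match_function_ids(project$functions[[db]], fp$value,
                             use_regex = (fp$cmp == "matches"))
        }
        orf_hit <- orf_hit | vapply(ann, function(a) any(a %in% ids),
                                    logical(1))
      }
    }
    ann_all <- apply(
      ot[orf_hit, project$databases, drop = FALSE], 1,
      function(r) paste(r[nzchar(r)], collapse = "|"))
    by_contig <- tapply(ann_all, ot$contig_id[orf_hit], function(x) {
      paste(unique(unlist(strsplit(x, "|", fixed = TRUE))), collapse = "|")
    })
    hitids <- intersect(sel, names(by_contig))
    matched_ann[hitids] <- by_contig[hitids]
  }

  ct <- project$contigs$table[contig_keep, , drop = FALSE]
  md <- data.frame(contig_id = ct$contig_id, length_bp = ct$length_bp,
                   tax = ct$tax, bin_id = ct$bin_id,
                   stringsAsFactors = FALSE)
  for (s in project$samples) {
    md[[paste0("Coverage_", s)]] <- project$contigs$cov[ct$contig_id, s]
  }
  md$matched_annotations <- matched_ann[ct$contig_id]
  rownames(md) <- NULL
  list(project = sub, metadata = md)
}
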