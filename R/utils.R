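## Shared constants and small helpers.

#' Canonical taxonomic ranks
#'
#' The seven ranks handled by taxonomy profiles, ordered from superkingdom to
#' species. Lineage strings use single-letter prefixes (`k_`, `p_`, `c_`,
#' `o_`, `f_`, `g_`, `s_`) joined by `";"`; a missing rank terminates the
#' lineage.
#'
#' @return Character vector of rank names.
#' @export
#' @examples
#' mg_ranks()
mg_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

.RANK_PREFIX <- c(superkingdom = "k", phylum = "p", class = "c",
                  order = "o", family = "f", genus = "g", species = "s")

.UNCLASSIFIED <- "Unclassified"
.UNMAPPED <- "Unmapped"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the taxon name at a rank from lineage strings
#'
#' Lineages are rank-prefixed, semicolon-joined strings such as
#' `"k_Bacteria;p_Bacteroidetes;...;g_Prevotella"`. Matching at a rank is
#' exact string equality of the prefixed component; a rank not present in
#' the string yields `NA`.
#'
#' @param lineage Character vector of lineage strings (`NA` or `""` allowed).
#' @param rank One of [mg_ranks()].
#' @return Character vector of taxon names (`NA` where unassigned).
#' @export
#' @examples
#' lineage_at(c("k_Bacteria;p_Firmicutes", "k_Bacteria", ""), "phylum")
lineage_at <- function(lineage, rank) {
  rank <- match.arg(rank, mg_ranks())
  prefix <- .RANK_PREFIX[[rank]]
  lineage <- as.character(lineage)
  lineage[is.na(lineage)] <- ""
  out <- rep(NA_character_, length(lineage))
  pat <- paste0("(?:^|;)", prefix, "_([^;]*)")
  m <- regexpr(pat, lineage, perl = TRUE)
  matched <- m != -1L
  if (any(matched)) {
    out[matched] <- sub(paste0("^;?", prefix, "_"), "",
                        regmatches(lineage, m))
  }
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

## Split lineage into a named vector over the canonical ranks (NA when absent).
split_lineage <- function(lin) {
  out <- stats::setNames(rep(NA_character_, length(mg_ranks())), mg_ranks())
  if (is.na(lin) || !nzchar(lin)) return(out)
  parts <- strsplit(lin, ";", fixed = TRUE)[[1]]
  for (p in parts) {
    pre <- substr(p, 1, 2)
    rk <- names(.RANK_PREFIX)[match(substr(pre, 1, 1), .RANK_PREFIX)]
    if (!is.na(rk) && substr(p, 2, 2) == "_") {
      val <- substring(p, 3)
      if (nzchar(val)) out[[rk]] <- val
    }
  }
  out
}

## Split "|"-joined annotation strings into a list of character vectors.
## "", NA -> character(0).
split_annotations <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- strsplit(x, "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

## An all-zero features x samples matrix with dimnames.
zero_matrix <- function(features, samples) {
  matrix(0, nrow = length(features), ncol = length(samples),
         dimnames = list(features, samples))
}

## Order rows: regular labels alphabetically, then the special labels
## (Unclassified / Unmapped) last, in the given order.
order_rows <- function(labels, special = c(.UNCLASSIFIED, .UNMAPPED)) {
  reg <- sort(setdiff(labels, special))
  c(reg, intersect(special, labels))
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## stopifnot with a formatted message.
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}
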