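#' @name lineage
#' @title GreenGenes-style taxonomic lineages
#'
#' @description
#' A lineage is a named character vector over the seven canonical ranks
#' (kingdom, phylum, class, order, family, genus, species). An empty string
#' means "unassigned at this rank". [parse_lineage()] reads the GreenGenes
#' prefix form (`"k__Bacteria; p__Firmicutes; ..."`); [format_lineage()] is
#' its inverse, so parse -> format -> parse is the identity on any valid
#' string.
#'
#' @param s A single lineage string in GreenGenes prefix form. Tokens may be
#'   missing from the right; an empty suffix (`"s__"`) gives an empty label.
#' @return `parse_lineage()`: a named character vector of length 7 with
#'   class `"lineage"`. `format_lineage()`: a single string.
#' @examples
#' l <- parse_lineage("k__Bacteria; p__Firmicutes")
#' l[["phylum"]]
#' format_lineage(l)
NULL

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
RANK_PREFIX <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                 family = "f", genus = "g", species = "s")

new_lineage <- function(labels = character()) {
  out <- setNames(rep("", 7L), TAX_RANKS)
  if (length(labels)) out[names(labels)] <- labels
  structure(out, class = "lineage")
}

#' @rdname lineage
#' @export
parse_lineage <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  out <- new_lineage()
  toks <- strsplit(s, ";", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  for (tok in toks) {
    if (!grepl("^[a-z]__", tok)) {
      stop("malformed lineage token (expected <rank>__<label>): '", tok, "'")
    }
    pre <- substr(tok, 1L, 1L)
    rank <- names(RANK_PREFIX)[match(pre, RANK_PREFIX)]
    if (is.na(rank)) stop("unknown rank prefix '", pre, "__' in token '", tok, "'")
    out[[rank]] <- trimws(substring(tok, 4L))
  }
  out
}

#' @rdname lineage
#' @param l A lineage (as returned by [parse_lineage()]).
#' @export
format_lineage <- function(l) {
  paste0(RANK_PREFIX, "__", unclass(l)[TAX_RANKS], collapse = "; ")
}

#' Depth, truncation and lowest common ancestor of lineages
#'
#' `lineage_depth()` returns the deepest rank carrying a non-empty label (or
#' `NA` for a fully empty lineage). `lineage_truncate()` blanks every rank
#' below `rank`. `lineage_lca()` keeps the leading ranks on which all input
#' lineages agree exactly (case-sensitive) and blanks the rest -- the rule
#' used to resolve equal-scoring classification ties conservatively.
#'
#' @param l,lins A lineage / a list of lineages.
#' @param rank One of `"kingdom" ... "species"`.
#' @return A lineage (or, for `lineage_depth()`, a rank name or `NA`).
#' @export
lineage_truncate <- function(l, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  i <- match(rank, TAX_RANKS)
  out <- unclass(l)
  if (i < 7L) out[(i + 1L):7L] <- ""
  structure(out, class = "lineage")
}

#' @rdname lineage_truncate
#' @export
lineage_depth <- function(l) {
  nz <- which(nzchar(unclass(l)))
  if (!length(nz)) return(NA_character_)
  TAX_RANKS[max(nz)]
}

#' @rdname lineage_truncate
#' @export
lineage_lca <- function(lins) {
  stopifnot(length(lins) >= 1L)
  m <- do.call(rbind, lapply(lins, unclass))
  out <- new_lineage()
  for (i in seq_along(TAX_RANKS)) {
    lab <- unique(m[, i])
    if (length(lab) == 1L && nzchar(lab)) out[[i]] <- lab else break
  }
  out
}

#' @export
print.lineage <- function(x, ...) {
  cat(format_lineage(x), "\n")
  invisible(x)
}

# label of `l` at `rank` ("" when unassigned)
rank_label <- function(l, rank) unclass(l)[[rank]]
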