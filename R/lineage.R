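#' Taxonomic ranks used throughout the package
#'
#' Ordered from broadest to most specific. Lineages are stored in tables as
#' semicolon-joined strings over a prefix of these ranks; an absent rank
#' implies all lower ranks are absent (no gaps).
#'
#' @return Character vector of the eight rank names.
#' @export
lineage_ranks <- function() {
  c("domain", "kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Split a semicolon-joined lineage string into rank labels
#'
#' @param x Character vector of lineage strings (e.g.
#'   `"Bacteria;Terrabacteria;Firmicutes"`). `NA` or `""` yields an empty
#'   lineage.
#' @return A list of character vectors, one per input, each of length <= 8.
#' @export
lineage_split <- function(x) {
  out <- lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    parts <- stringr::str_trim(stringr::str_split_1(s, ";"))
    parts <- parts[nzchar(parts)]
    if (length(parts) > length(lineage_ranks())) {
      stop("lineage has more labels than ranks: ", s, call. = FALSE)
    }
    parts
  })
  out
}

#' Join rank labels back into a lineage string
#'
#' @param parts Character vector of rank labels, broadest first.
#' @return A single semicolon-joined string (`""` for an empty lineage).
#' @export
lineage_join <- function(parts) {
  paste(parts, collapse = ";")
}

#' Extract one rank from lineage strings
#'
#' @param x Character vector of lineage strings.
#' @param rank One of [lineage_ranks()].
#' @return Character vector; `NA` where the lineage does not reach that rank.
#' @export
lineage_at_rank <- function(x, rank) {
  rank <- match.arg(rank, lineage_ranks())
  i <- match(rank, lineage_ranks())
  vapply(lineage_split(x), function(p) if (length(p) >= i) p[[i]] else NA_character_,
         character(1))
}

#' Truncate lineage strings to a rank
#'
#' @inheritParams lineage_at_rank
#' @return Character vector of lineages truncated at `rank`.
#' @export
lineage_truncate <- function(x, rank) {
  rank <- match.arg(rank, lineage_ranks())
  i <- match(rank, lineage_ranks())
  vapply(lineage_split(x), function(p) lineage_join(utils::head(p, i)), character(1))
}

#' Lowest common ancestor of a set of lineages
#'
#' The deepest prefix shared by all lineages: ranks are intersected from the
#' domain downward and the walk stops at the first disagreement or at the end
#' of the shortest lineage.
#'
#' @param x Character vector of lineage strings (at least one).
#' @return A single lineage string, possibly `""` when not even the domain is
#'   shared.
#' @export
lineage_lca <- function(x) {
  parts <- lineage_split(x)
  if (length(parts) == 0L) return("")
  depth <- min(lengths(parts))
  shared <- character(0)
  for (i in seq_len(depth)) {
    labels <- vapply(parts, `[[`, character(1), i)
    if (length(unique(labels)) > 1L) break
    shared <- c(shared, labels[[1]])
  }
  lineage_join(shared)
}
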