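# Readers/writers for every table the pipeline touches. All tables are
# UTF-8 TSV with a header row; '#'-prefixed lines are comments. Coordinates
# are 1-based inclusive everywhere.

read_tsv_quiet <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, show_col_types = FALSE)
}

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    rlang::abort(paste0(what, " file '", path, "' is missing required column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "bintrans_schema_error")
  }
  invisible(df)
}

#' Read gene models from a GFF3 file
#'
#' Consumes the GFF3 produced by a gene caller (one CDS feature per gene,
#' with an `ID` attribute). Coordinates are kept 1-based inclusive and the
#' gene length is `end - start + 1` bp.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `scaffold_id`, `start`, `end`,
#'   `strand`, `length`.
#' @export
read_gff <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  empty <- tibble::tibble(gene_id = character(0), scaffold_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), length = integer(0))
  if (!any(keep)) {
    warning("GFF file '", path, "' contains no features", call. = FALSE)
    return(empty)
  }
  lineno <- which(keep)
  fields <- stringr::str_split(lines[keep], "\t")
  bad <- lengths(fields) != 9L
  if (any(bad)) {
    stop("malformed GFF line ", lineno[which(bad)[1]], " in '", path,
         "': expected 9 tab-separated columns", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  is_cds <- m[, 3] == "CDS"
  if (!any(is_cds)) {
    warning("GFF file '", path, "' contains no CDS features", call. = FALSE)
    return(empty)
  }
  m <- m[is_cds, , drop = FALSE]
  lineno <- lineno[is_cds]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("non-numeric coordinate on GFF line ", lineno[which(bad)[1]],
         " in '", path, "'", call. = FALSE)
  }
  bad <- end < start
  if (any(bad)) {
    stop("end < start on GFF line ", lineno[which(bad)[1]], " in '", path,
         "'", call. = FALSE)
  }
  id <- stringr::str_match(m[, 9], "(?:^|;)ID=([^;]+)")[, 2]
  bad <- is.na(id)
  if (any(bad)) {
    stop("missing ID attribute on GFF line ", lineno[which(bad)[1]],
         " in '", path, "'", call. = FALSE)
  }
  dup <- duplicated(id)
  if (any(dup)) {
    stop("duplicate gene ID '", id[which(dup)[1]], "' on GFF line ",
         lineno[which(dup)[1]], " in '", path, "'", call. = FALSE)
  }
  tibble::tibble(gene_id = id, scaffold_id = m[, 1], start = start, end = end,
                 strand = m[, 7], length = end - start + 1L)
}

#' Write gene models as GFF3
#'
#' @param genes Tibble as returned by [read_gff()].
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path, source = "bintrans") {
  header <- "##gff-version 3"
  rows <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                  genes$scaffold_id, source, genes$start, genes$end,
                  genes$strand, genes$gene_id)
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' Read a best-hit table
#'
#' Tabular homology-search results (BLAST outfmt-6-like) augmented with a
#' semicolon-joined lineage column for the subject. Multiple hits per gene
#' are allowed; see [best_hits()] for the closest-hit reduction.
#'
#' @param path Path to a TSV with columns `gene_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `evalue`, `query_coverage`, `lineage`.
#' @return Tibble with those columns.
#' @export
read_hits <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_guess()))
  check_columns(df, c("gene_id", "subject_id", "pct_identity", "aln_len",
                      "evalue", "query_coverage", "lineage"), "hit", path)
  df <- dplyr::mutate(df,
    gene_id = as.character(.data$gene_id),
    subject_id = as.character(.data$subject_id),
    pct_identity = as.double(.data$pct_identity),
    aln_len = as.integer(.data$aln_len),
    evalue = as.double(.data$evalue),
    query_coverage = as.double(.data$query_coverage),
    lineage = dplyr::coalesce(as.character(.data$lineage), ""))
  validate_hits(df)
  df
}

validate_hits <- function(df) {
  if (any(df$evalue < 0, na.rm = TRUE)) {
    stop("negative E-value in hit table", call. = FALSE)
  }
  pct_bad <- df$pct_identity < 0 | df$pct_identity > 100 |
    df$query_coverage < 0 | df$query_coverage > 100
  if (any(pct_bad, na.rm = TRUE)) {
    stop("percent identity/coverage outside [0, 100] in hit table", call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_hits
#' @param hits Hit tibble to write.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}

#' Reduce a hit table to one closest hit per gene
#'
#' The closest hit is the lowest E-value; ties are broken by higher percent
#' identity, then by lexicographic subject id, so the reduction is
#' deterministic and order-independent.
#'
#' @param hits Tibble as returned by [read_hits()].
#' @return Tibble with one row per `gene_id`.
#' @export
best_hits <- function(hits) {
  hits |>
    dplyr::arrange(.data$gene_id, .data$evalue, dplyr::desc(.data$pct_identity),
                   .data$subject_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
}

#' Read a gene-by-sample count table
#'
#' @param path TSV with a `gene_id` column and one integer column per sample.
#' @return Tibble; all count columns are non-negative integers.
#' @export
read_counts <- function(path) {
  df <- read_tsv_quiet(path)
  check_columns(df, "gene_id", "count", path)
  samples <- setdiff(names(df), "gene_id")
  if (length(samples) == 0L) {
    stop("count file '", path, "' has no sample columns", call. = FALSE)
  }
  for (s in samples) {
    v <- df[[s]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("count column '", s, "' in '", path,
           "' must be non-negative integers", call. = FALSE)
    }
    df[[s]] <- as.integer(v)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in count file '", path, "'", call. = FALSE)
  }
  df
}

#' @rdname read_counts
#' @param counts Count tibble to write.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a scaffold-to-bin membership table
#'
#' @param path TSV with columns `scaffold_id`, `bin_id`. Scaffolds absent
#'   from this table are treated as unbinned downstream.
#' @return Tibble with those two character columns.
#' @export
read_bin_map <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  check_columns(df, c("scaffold_id", "bin_id"), "bin membership", path)
  if (anyDuplicated(df$scaffold_id)) {
    stop("scaffold assigned to more than one bin in '", path, "'", call. = FALSE)
  }
  df
}

#' @rdname read_bin_map
#' @param bin_map Membership tibble to write.
#' @export
write_bin_map <- function(bin_map, path) {
  readr::write_tsv(bin_map, path, progress = FALSE)
  invisible(path)
}

#' Read an abundance table (OTU counts or bin coverages)
#'
#' @param path TSV with an id column (first column) and one numeric column
#'   per sample.
#' @param id Name of the id column; defaults to the first column.
#' @return Tibble with non-negative numeric sample columns.
#' @export
read_abundance <- function(path, id = NULL) {
  df <- read_tsv_quiet(path)
  if (is.null(id)) id <- names(df)[1]
  check_columns(df, id, "abundance", path)
  samples <- setdiff(names(df), id)
  for (s in samples) {
    if (!is.numeric(df[[s]]) || any(df[[s]] < 0, na.rm = TRUE)) {
      stop("abundance column '", s, "' in '", path,
           "' must be non-negative numeric", call. = FALSE)
    }
  }
  df
}

#' Write a phylogenetic or distance tree to newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
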