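#' Read / write gene sets in GMT format
#'
#' One set per line: `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return [read_gmt()] returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a gene-set collection against a background universe
#'
#' Set members outside the universe are dropped; empty sets are removed.
#'
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe background protein set (defaults to the union of all
#'   sets; in the pipeline, the interactome node set).
#' @return list with `sets` and `universe`, class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  structure(list(sets = sets, universe = unique(universe)),
            class = "gene_set_collection")
}

#' Hypergeometric pathway enrichment of a protein set
#'
#' One-sided (upper-tail, inclusive) hypergeometric test of the overlap of
#' the query with each gene set, against the collection's universe. Query
#' members outside the universe are dropped and counted. No multiple-testing
#' correction is applied; the significance flag is the raw `p < alpha`.
#'
#' @param query character vector of proteins (e.g. network nodes).
#' @param gsc a [gene_set_collection()].
#' @param alpha significance level for the flag (default 0.05).
#' @return data frame with `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `significant`, sorted by ascending p
#'   (ties by set name). Attribute `n_dropped` counts out-of-universe
#'   query members.
#' @export
enrich <- function(query, gsc, alpha = 0.05) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  query <- unique(query)
  q <- intersect(query, gsc$universe)
  dropped <- length(query) - length(q)
  if (!length(q)) {
    warning("empty query after restriction to the universe")
    out <- data.frame(set = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- dropped
    return(out)
  }
  N <- length(gsc$universe)
  res <- data.frame(
    set = names(gsc$sets),
    overlap = vapply(gsc$sets, function(s) length(intersect(s, q)), integer(1)),
    set_size = lengths(gsc$sets),
    query_size = length(q),
    universe_size = N, stringsAsFactors = FALSE, row.names = NULL)
  res$p_value <- stats::phyper(res$overlap - 1, res$set_size,
                               N - res$set_size, length(q), lower.tail = FALSE)
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- dropped
  res
}

#' Shared significantly enriched signaling pathways
#'
#' Intersection of the significant pathway names of two enrichment results,
#' restricted to signaling pathways by a configurable name predicate
#' (default: name contains "signaling", case-insensitive).
#'
#' @param records_a,records_b enrichment data frames from [enrich()].
#' @param signaling_filter substring the pathway name must contain, or a
#'   predicate function on names. Use `NULL` to keep all pathways.
#' @return character vector of shared significant pathway names.
#' @export
shared_pathways <- function(records_a, records_b, signaling_filter = "signaling") {
  shared <- intersect(records_a$set[records_a$significant],
                      records_b$set[records_b$significant])
  if (is.null(signaling_filter)) return(shared)
  keep <- if (is.function(signaling_filter)) signaling_filter(shared)
  else grepl(signaling_filter, shared, ignore.case = TRUE)
  shared[keep]
}
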