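# Hypergeometric gene-set enrichment of a topic's genes against a
# user-supplied GMT collection, with Benjamini-Hochberg adjustment.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member symbols).
#' @param universe Background gene universe; defaults to the union of all
#'   sets. Every set member must be in the universe.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(toupper(universe))
    stray <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(stray) > 0L)
      stop_bad("set members outside the universe: ",
               paste(head(stray, 5L), collapse = ", "))
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @param universe Optional background; defaults to the union of the sets.
#' @return A `gene_set_collection` with a `descriptions` attribute.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_bad("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) stop_bad("GMT rows must have name, description and >=1 member")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  col <- gene_set_collection(sets, universe = universe)
  attr(col, "descriptions") <- setNames(
    vapply(fields, `[[`, character(1L), 2L), names(sets))
  col
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the overlap between the query and the set, drawing `|query|` genes
#' from the universe. One-sided over-representation only. P-values are
#' Benjamini-Hochberg adjusted; rows with adjusted p below `alpha_adj` are
#' flagged enriched. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query Character vector of gene symbols.
#' @param collection A `gene_set_collection`.
#' @param alpha_adj Enrichment cutoff on the adjusted p-value (default 0.01).
#' @return Data frame sorted by p ascending: `set`, `set_size`, `overlap`,
#'   `ratio` (overlap / set size), `p`, `p_adjusted`, `enriched`,
#'   `molecules` (comma-joined overlapping genes).
#' @export
enrich <- function(query, collection, alpha_adj = 0.01) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(query) == 0L) stop_bad("query must be non-empty")
  query <- unique(toupper(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L) stop_bad("no query genes left inside the universe")
  N <- length(collection$universe)
  n_query <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    ov <- intersect(query, s)
    k <- length(ov)
    # P(X >= k), X ~ Hypergeometric(N, |s|, n_query)
    p <- phyper(k - 1L, length(s), N - length(s), n_query, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k,
               ratio = k / length(s), p = p,
               molecules = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out$enriched <- out$p_adjusted < alpha_adj
  out <- out[order(out$p, out$set), c("set", "set_size", "overlap", "ratio",
                                      "p", "p_adjusted", "enriched",
                                      "molecules")]
  rownames(out) <- NULL
  out
}

#' Write an enrichment report as CSV
#'
#' Mirrors the standard pathway-report layout: pathway, -log10(p adjusted),
#' ratio, molecules.
#'
#' @param result Output of [enrich()].
#' @param path CSV path.
#' @export
write_enrichment_report <- function(result, path) {
  rep <- data.frame(pathway = result$set,
                    minus_log10_p = -log10(result$p_adjusted),
                    ratio = result$ratio,
                    molecules = result$molecules)
  write.csv(rep, path, row.names = FALSE)
  invisible(path)
}
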