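# Reading predication records, semantic filtering, and corpus construction.
#
# Predication tables are SemMedDB-style rows of
#   subject_name, subject_semtype, predicate, object_name, object_semtype[, citation_id]
# Diseases are identified by the UMLS semantic types "dsyn" (Disease or
# Syndrome) and "neop" (Neoplastic Process); genes by membership of an
# approved-symbol list. Each retained disease becomes a document whose tokens
# are its associated gene symbols.

DISEASE_SEMTYPES <- c("dsyn", "neop")

#' Read a predication table
#'
#' Parses a delimited predication file into a data frame of predication
#' records. A valid row has at least five fields:
#' subject name, subject semantic type, predicate, object name, object
#' semantic type, and optionally a citation id. Malformed rows (fewer than
#' five fields) are counted and reported via a warning and the
#' `n_malformed` attribute rather than silently dropped.
#'
#' @param path Path to the predication file.
#' @param sep Field delimiter (default tab).
#' @param header Logical; does the file carry a header row naming the
#'   columns (`subject_name`, `subject_semtype`, `predicate`,
#'   `object_name`, `object_semtype`, `citation_id`)? Default `FALSE`
#'   (positional columns).
#' @return A data frame with columns `subject_name`, `subject_semtype`,
#'   `predicate`, `object_name`, `object_semtype`, `citation_id`
#'   (`NA` when absent), with attribute `n_malformed`.
#' @export
read_predications <- function(path, sep = "\t", header = FALSE) {
  if (!file.exists(path)) stop_bad("predication file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- c("subject_name", "subject_semtype", "predicate",
            "object_name", "object_semtype", "citation_id")
  idx <- seq_len(6L)
  if (header && length(lines) > 0L) {
    hdr <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
    idx <- match(cols, hdr)
    if (anyNA(idx[1:5])) stop_bad("header must name the five predication columns")
    lines <- lines[-1L]
  }
  if (length(lines) == 0L) stop_bad("no predication rows in ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  ok <- vapply(fields, length, 1L) >= 5L
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    warning(sprintf("%d malformed predication row(s) skipped", n_malformed),
            call. = FALSE)
  }
  fields <- fields[ok]
  if (length(fields) == 0L) stop_bad("no valid predication rows in ", path)
  grab <- function(j) vapply(fields, function(f) {
    i <- idx[j]
    if (!is.na(i) && i <= length(f)) f[[i]] else NA_character_
  }, character(1L))
  out <- data.frame(
    subject_name    = grab(1L),
    subject_semtype = tolower(grab(2L)),
    predicate       = grab(3L),
    object_name     = grab(4L),
    object_semtype  = tolower(grab(5L)),
    citation_id     = grab(6L),
    stringsAsFactors = FALSE
  )
  bad <- !nzchar(out$subject_name) | !nzchar(out$object_name)
  if (any(bad)) {
    n_malformed <- n_malformed + sum(bad)
    warning(sprintf("%d row(s) with empty concept names skipped", sum(bad)),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop_bad("no valid predication rows in ", path)
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Read an approved gene-symbol list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored.
#' Symbols are uppercase-normalized.
#'
#' @param path Path to the symbol file.
#' @return Character vector of unique uppercase symbols.
#' @export
read_gene_symbols <- function(path) {
  if (!file.exists(path)) stop_bad("gene symbol file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}

# Normalized disease identity: lowercased, whitespace collapsed.
normalize_disease_id <- function(name) gsub("\\s+", " ", tolower(trimws(name)))

#' Filter predications down to disease-gene association records
#'
#' Keeps predications in which one side carries a disease semantic type
#' (`dsyn` or `neop`) and the other side's uppercase-normalized name is an
#' approved gene symbol. The filter is direction-agnostic: the disease may be
#' either subject or object. Duplicate predications are retained as repeated
#' tokens (de-duplication, if wanted, happens in [build_corpus()]).
#'
#' @param records Data frame as returned by [read_predications()].
#' @param gene_symbols Character vector of approved symbols (any case).
#' @return Data frame with columns `disease_id`, `disease_name`,
#'   `disease_semtype`, `gene_symbol`.
#' @export
filter_associations <- function(records, gene_symbols) {
  if (length(gene_symbols) == 0L) stop_bad("gene_symbols must be non-empty")
  symbols <- unique(toupper(gene_symbols))
  # records may already be association records (idempotence)
  if (all(c("disease_id", "gene_symbol", "disease_semtype") %in% names(records))) {
    keep <- records$disease_semtype %in% DISEASE_SEMTYPES &
      records$gene_symbol %in% symbols
    out <- records[keep, c("disease_id", "disease_name", "disease_semtype",
                           "gene_symbol"), drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  sub_dis <- records$subject_semtype %in% DISEASE_SEMTYPES &
    toupper(records$object_name) %in% symbols
  obj_dis <- records$object_semtype %in% DISEASE_SEMTYPES &
    toupper(records$subject_name) %in% symbols & !sub_dis
  mk <- function(dname, dsem, gname) data.frame(
    disease_id      = normalize_disease_id(dname),
    disease_name    = dname,
    disease_semtype = dsem,
    gene_symbol     = toupper(gname),
    stringsAsFactors = FALSE
  )
  out <- rbind(
    mk(records$subject_name[sub_dis], records$subject_semtype[sub_dis],
       records$object_name[sub_dis]),
    mk(records$object_name[obj_dis], records$object_semtype[obj_dis],
       records$subject_name[obj_dis])
  )
  rownames(out) <- NULL
  out
}

#' Build a disease-as-document corpus
#'
#' Tallies association records into a diseases-by-genes count matrix: each
#' disease is a document whose tokens are its associated gene symbols,
#' repeated once per association record (or once per unique pair when
#' `dedupe = TRUE`).
#'
#' @param associations Data frame from [filter_associations()] (needs
#'   `disease_id` and `gene_symbol`).
#' @param min_doc_tokens Diseases with fewer total tokens are removed
#'   (default 1, i.e. no floor beyond non-emptiness).
#' @param dedupe Collapse repeated disease-gene pairs to a single token?
#' @return An object of class `corpus`: list with `documents` (disease ids),
#'   `vocabulary` (gene tokens) and `counts` (documents x vocabulary integer
#'   matrix).
#' @export
build_corpus <- function(associations, min_doc_tokens = 1L, dedupe = FALSE) {
  if (is.null(associations) || nrow(associations) == 0L)
    stop_bad("associations must be non-empty")
  df <- associations[, c("disease_id", "gene_symbol")]
  if (dedupe) df <- unique(df)
  docs <- sort(unique(df$disease_id))
  vocab <- sort(unique(df$gene_symbol))
  counts <- matrix(0L, nrow = length(docs), ncol = length(vocab),
                   dimnames = list(docs, vocab))
  tab <- table(factor(df$disease_id, levels = docs),
               factor(df$gene_symbol, levels = vocab))
  counts[] <- as.integer(tab)
  keep <- rowSums(counts) >= min_doc_tokens
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) stop_bad("empty corpus: every document fell below min_doc_tokens")
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]
  new_corpus(counts)
}

#' Construct a corpus from a count matrix
#'
#' @param counts Non-negative integer matrix with row names (documents /
#'   disease ids) and column names (vocabulary / gene tokens).
#' @return A `corpus` object.
#' @export
new_corpus <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  obj <- structure(list(
    documents  = rownames(counts),
    vocabulary = colnames(counts),
    counts     = counts
  ), class = "corpus")
  validate_corpus(obj)
  obj
}

#' Validate corpus invariants
#'
#' Checks: unique non-empty document ids and vocabulary entries, non-negative
#' integer counts, no empty document, no all-zero vocabulary column.
#'
#' @param x A `corpus` object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_corpus <- function(x) {
  stopifnot(inherits(x, "corpus"))
  cts <- x$counts
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    stop_bad("corpus counts must carry document and vocabulary names")
  if (anyDuplicated(colnames(cts))) stop_bad("vocabulary entries must be unique")
  if (anyDuplicated(rownames(cts))) stop_bad("document ids must be unique")
  if (any(cts < 0)) stop_bad("counts must be non-negative")
  if (any(rowSums(cts) < 1)) stop_bad("corpus has an empty document")
  if (any(colSums(cts) < 1)) stop_bad("corpus has an all-zero vocabulary column")
  invisible(x)
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("corpus: %d documents, %d vocabulary tokens, %d total tokens\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Write / read a corpus as plain text
#'
#' Serializes to three files under `dir`: `documents.tsv`, `vocabulary.tsv`
#' and `counts.tsv` (triplet format: 1-based row index, column index, count).
#'
#' @param corpus A `corpus` object.
#' @param dir Directory (created if needed).
#' @return `write_corpus`: the directory, invisibly. `read_corpus`: a
#'   `corpus`.
#' @export
write_corpus <- function(corpus, dir) {
  validate_corpus(corpus)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(corpus$documents, file.path(dir, "documents.tsv"))
  writeLines(corpus$vocabulary, file.path(dir, "vocabulary.tsv"))
  nz <- which(corpus$counts > 0L, arr.ind = TRUE)
  trip <- data.frame(row = nz[, 1L], col = nz[, 2L],
                     count = corpus$counts[nz])
  trip <- trip[order(trip$row, trip$col), ]
  write.table(trip, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  docs <- readLines(file.path(dir, "documents.tsv"))
  vocab <- readLines(file.path(dir, "vocabulary.tsv"))
  trip <- read.delim(file.path(dir, "counts.tsv"))
  counts <- matrix(0L, length(docs), length(vocab),
                   dimnames = list(docs, vocab))
  counts[cbind(trip$row, trip$col)] <- as.integer(trip$count)
  new_corpus(counts)
}
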