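# Ontology-anchored coherence evaluation. A disease ontology is a rooted DAG
# of terms; diseases are annotated to terms, and two diseases count as
# related when some pair of their terms shares an ancestor within a fixed
# number of levels (default 3). Topic coherence is summarized as a
# precision-recall curve over cumulative rank folds and its trapezoidal AUC.

#' Construct a disease ontology DAG
#'
#' @param edges Data frame with columns `child`, `parent` (term ids); terms
#'   mentioned only as parents are included automatically.
#' @param annotations Optional data frame with columns `disease`, `term`.
#' @return Object of class `ontology_dag`: `terms` (character),
#'   `parents` (named list term -> character vector of parents),
#'   `annotations` (named list disease -> character vector of terms).
#' @export
ontology_dag <- function(edges, annotations = NULL) {
  stopifnot(all(c("child", "parent") %in% names(edges)))
  terms <- sort(unique(c(edges$child, edges$parent)))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  parents <- lapply(parents, unique)
  dag <- structure(list(terms = terms, parents = parents,
                        annotations = list()),
                   class = "ontology_dag")
  assert_acyclic(dag)
  if (!is.null(annotations)) dag <- annotate_diseases(dag, annotations)
  dag
}

assert_acyclic <- function(dag) {
  # Kahn-style peel: repeatedly remove terms all of whose parents are removed.
  remaining <- dag$terms
  repeat {
    removable <- remaining[vapply(remaining, function(t) {
      all(!dag$parents[[t]] %in% remaining)
    }, logical(1))]
    if (length(removable) == 0L) break
    remaining <- setdiff(remaining, removable)
  }
  if (length(remaining) > 0L)
    stop_bad("ontology contains a cycle involving: ",
             paste(head(remaining, 5L), collapse = ", "))
  invisible(dag)
}

#' Attach disease annotations to an ontology
#'
#' @param dag An `ontology_dag`.
#' @param annotations Data frame with columns `disease`, `term`; every term
#'   must exist in the ontology.
#' @return The updated `ontology_dag`.
#' @export
annotate_diseases <- function(dag, annotations) {
  stopifnot(inherits(dag, "ontology_dag"),
            all(c("disease", "term") %in% names(annotations)))
  bad <- setdiff(annotations$term, dag$terms)
  if (length(bad) > 0L)
    stop_bad("annotation terms not in ontology: ", paste(head(bad, 5L), collapse = ", "))
  ann <- lapply(split(annotations$term, annotations$disease), unique)
  dag$annotations <- ann
  dag
}

#' Read an ontology from a parent-child edge TSV
#'
#' Two columns, child then parent (header optional and auto-detected when it
#' reads `child<TAB>parent`).
#'
#' @param path Edge file path.
#' @return An `ontology_dag` (without annotations).
#' @export
read_ontology_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- identical(tolower(trimws(strsplit(first, "\t")[[1]]))[1:2], c("child", "parent"))
  df <- read.delim(path, header = hdr, colClasses = "character")
  names(df)[1:2] <- c("child", "parent")
  ontology_dag(df)
}

#' Read a minimal OBO subset
#'
#' Parses only `[Term]` stanzas and their `id`, `name`, `is_a` and `synonym`
#' tags; everything else is ignored.
#'
#' @param path OBO file path.
#' @return List with `dag` (an `ontology_dag`) and `names` (named character
#'   vector id -> primary name) and `synonyms` (named list).
#' @export
read_obo_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  edges <- list(); nm <- character(); syn <- list()
  cur <- NULL; in_term <- FALSE
  flush <- function() {}
  for (ln in c(lines, "[Term]")) {
    ln <- trimws(ln)
    if (ln == "[Term]" || startsWith(ln, "[")) {
      in_term <- ln == "[Term]"
      cur <- NULL
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (!is.null(cur) && startsWith(ln, "name:")) {
      nm[cur] <- trimws(sub("^name:", "", ln))
    } else if (!is.null(cur) && startsWith(ln, "is_a:")) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- c(cur, parent)
    } else if (!is.null(cur) && startsWith(ln, "synonym:")) {
      s <- sub('^synonym:\\s*"([^"]*)".*$', "\\1", ln)
      syn[[cur]] <- c(syn[[cur]], s)
    }
  }
  ids <- unique(c(names(nm), unlist(edges)))
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    df <- data.frame(child = em[, 1L], parent = em[, 2L], stringsAsFactors = FALSE)
  } else {
    df <- data.frame(child = character(), parent = character())
  }
  dag <- ontology_dag(df)
  dag$terms <- sort(unique(c(dag$terms, ids)))
  list(dag = dag, names = nm, synonyms = syn)
}

#' Read disease annotations (disease TAB term)
#'
#' @param path Two-column TSV; header auto-detected when the first row reads
#'   `disease<TAB>term`.
#' @return Data frame with columns `disease`, `term`.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- identical(tolower(trimws(strsplit(first, "\t")[[1]]))[1:2], c("disease", "term"))
  df <- read.delim(path, header = hdr, colClasses = "character")
  names(df)[1:2] <- c("disease", "term")
  df
}

#' Ancestors of a term within a bounded number of levels
#'
#' Breadth-first walk up the parent edges: all terms reachable in at most
#' `levels` steps, excluding the term itself.
#'
#' @param dag An `ontology_dag`.
#' @param term Term id.
#' @param levels Positive integer bound on path length.
#' @return Character vector of ancestor term ids.
#' @export
ancestors_within <- function(dag, term, levels = 3L) {
  stopifnot(inherits(dag, "ontology_dag"), levels >= 1L)
  if (!term %in% dag$terms) stop_bad("unknown term: ", term)
  frontier <- term
  seen <- character()
  for (i in seq_len(levels)) {
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, seen)
    if (length(frontier) == 0L) break
    seen <- c(seen, frontier)
  }
  seen
}

#' Are two diseases ontology-similar?
#'
#' TRUE when some annotation term of one disease and some term of the other
#' share a common node among themselves or their ancestors within `levels`
#' levels. Symmetric and reflexive on annotated diseases. Returns `NA` when
#' either disease is unannotated (distinguished from FALSE).
#'
#' @param dag An annotated `ontology_dag`.
#' @param d1,d2 Disease ids.
#' @param levels Ancestor level bound (default 3).
#' @return `TRUE`, `FALSE`, or `NA` (unannotated).
#' @export
diseases_similar <- function(dag, d1, d2, levels = 3L) {
  a1 <- dag$annotations[[d1]]
  a2 <- dag$annotations[[d2]]
  if (is.null(a1) || is.null(a2)) return(NA)
  s1 <- unique(c(a1, unlist(lapply(a1, ancestors_within, dag = dag, levels = levels))))
  s2 <- unique(c(a2, unlist(lapply(a2, ancestors_within, dag = dag, levels = levels))))
  length(intersect(s1, s2)) > 0L
}

# Closure sets (term + bounded ancestors) for a vector of diseases; NULL for
# unannotated ones. Shared across the per-fold computations.
disease_closures <- function(dag, diseases, levels) {
  lapply(setNames(diseases, diseases), function(d) {
    a <- dag$annotations[[d]]
    if (is.null(a)) return(NULL)
    unique(c(a, unlist(lapply(a, ancestors_within, dag = dag, levels = levels))))
  })
}

#' Precision-recall curve of a ranked topic against an ontology
#'
#' Fold f extracts the top `ceiling(f * n / folds)` ranked diseases.
#' Within a fold, the numerator counts annotated extracted diseases having at
#' least one ontology-similar partner among the extracted diseases;
#' precision divides by the number of extracted diseases, recall by the
#' number of gold-standard diseases (annotated diseases of the full topic
#' with at least one similar partner in the topic). Unannotated diseases
#' count in precision's denominator but can never enter the numerator.
#' `mode = "partition"` instead scores each disjoint rank decile cumulatively
#' merged is the default ("cumulative"), matching a curve whose recall runs
#' from 0 to 1.
#'
#' @param topic_diseases Character vector of disease ids, ranked by topic
#'   probability (descending).
#' @param dag An annotated `ontology_dag`.
#' @param folds Number of folds (default 10).
#' @param levels Ancestor level bound (default 3).
#' @param mode `"cumulative"` (default) or `"partition"` (each fold scored
#'   on its own disjoint rank slice).
#' @return Data frame of class `pr_points`: `fold`, `n_extracted`,
#'   `precision`, `recall` (`NA` when there are no gold-standard diseases),
#'   with attributes `n_gold` and `mode`.
#' @export
precision_recall <- function(topic_diseases, dag, folds = 10L, levels = 3L,
                             mode = c("cumulative", "partition")) {
  stopifnot(length(topic_diseases) > 0L, folds >= 1L)
  mode <- match.arg(mode)
  n <- length(topic_diseases)
  clos <- disease_closures(dag, topic_diseases, levels)

  has_partner <- function(ids) {
    # for each id in ids: annotated and shares closure with another member
    sets <- clos[ids]
    vapply(seq_along(ids), function(i) {
      si <- sets[[i]]
      if (is.null(si)) return(FALSE)
      for (j in seq_along(ids)) {
        if (j == i) next
        sj <- sets[[j]]
        if (!is.null(sj) && length(intersect(si, sj)) > 0L) return(TRUE)
      }
      FALSE
    }, logical(1))
  }

  n_gold <- sum(has_partner(topic_diseases))
  rows <- lapply(seq_len(folds), function(f) {
    if (mode == "cumulative") {
      ext <- topic_diseases[seq_len(ceiling(f * n / folds))]
    } else {
      lo <- ceiling((f - 1L) * n / folds) + 1L
      hi <- ceiling(f * n / folds)
      if (lo > hi) return(NULL)
      ext <- topic_diseases[lo:hi]
    }
    num <- sum(has_partner(ext))
    data.frame(fold = f, n_extracted = length(ext),
               precision = num / length(ext),
               recall = if (n_gold > 0L) num / n_gold else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_gold") <- n_gold
  attr(out, "mode") <- mode
  class(out) <- c("pr_points", class(out))
  out
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integral over recall after sorting the points by recall and
#' collapsing duplicate recall values to their maximum precision; clipped to
#' `[0, 1]`. Order-invariant in the input. With `anchor = TRUE` (default)
#' and no point at recall 0, the curve is anchored by extending the
#' lowest-recall precision flat to recall 0 (the usual precision-recall
#' convention); explicit recall-0 points are never altered.
#'
#' @param points A `pr_points` data frame (or any data frame with
#'   `precision` and `recall` columns); needs >= 2 points with defined
#'   recall.
#' @param anchor Extend the first precision to recall 0 when absent?
#' @return Scalar AUC in `[0, 1]`.
#' @export
pr_auc <- function(points, anchor = TRUE) {
  ok <- is.finite(points$recall) & is.finite(points$precision)
  if (!any(ok)) stop_bad("no measurable recall")
  r <- points$recall[ok]; p <- points$precision[ok]
  if (length(r) < 2L) stop_bad("need at least 2 points with defined recall")
  # collapse duplicate recalls by max precision
  pm <- vapply(split(p, r), max, numeric(1))
  r <- as.numeric(names(pm)); p <- unname(pm)
  ord <- order(r)
  r <- r[ord]; p <- p[ord]
  if (length(r) < 2L) stop_bad("need at least 2 distinct recall values")
  if (anchor && r[1L] > 0) {
    r <- c(0, r)
    p <- c(p[1L], p)
  }
  auc <- sum(diff(r) * (head(p, -1L) + p[-1L]) / 2)
  min(max(auc, 0), 1)
}
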