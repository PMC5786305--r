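# Similarity and coverage statistics over fitted topics: symmetric KL
# divergence between genes' topic distributions (LDAKL), cosine similarity
# between topics, and disease-gene association coverage (DGAC).

#' Symmetric Kullback-Leibler divergence (LDAKL)
#'
#' `KL(p || q) + KL(q || p)` with natural logarithms. Inputs are probability
#' vectors over topics; add-epsilon smoothing followed by renormalization
#' guards against zero entries on raw empirical input (Dirichlet-smoothed
#' posteriors never trigger it).
#'
#' @param p,q Probability vectors of equal length (each sums to 1 within
#'   1e-9 before smoothing).
#' @param eps Smoothing constant (default 1e-12).
#' @return Non-negative scalar; 0 iff `p == q` (after smoothing).
#' @export
ldakl <- function(p, q, eps = 1e-12) {
  if (length(p) != length(q)) stop_bad("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop_bad("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop_bad("p and q must each sum to 1")
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

#' A gene's distribution over topics
#'
#' Extracts the topic vector used by [ldakl()]: with
#' `conditioning = "gene_given_topic"` (default) the vector of p(gene | t)
#' across topics, renormalized to sum to one; with `"topic_given_gene"` the
#' gene's expected counts across topics normalized to p(t | gene).
#'
#' @param model A `topic_model`.
#' @param gene Gene id (vocabulary entry).
#' @param conditioning Which reading of the topic vector to use.
#' @return Probability vector over the model's topics.
#' @export
gene_topic_distribution <- function(model, gene,
                                    conditioning = c("gene_given_topic",
                                                     "topic_given_gene")) {
  stopifnot(inherits(model, "topic_model"))
  conditioning <- match.arg(conditioning)
  if (!gene %in% colnames(model$phi_hat)) stop_bad("unknown gene: ", gene)
  v <- switch(conditioning,
              gene_given_topic = model$phi_hat[, gene],
              topic_given_gene = model$n_ck[, gene] + model$hyper$beta)
  v / sum(v)
}

#' Cosine similarity between two non-negative vectors
#'
#' `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`; lies in `[0, 1]` for
#' non-negative inputs and is invariant under positive rescaling.
#'
#' @param x,y Aligned non-negative numeric vectors; neither all-zero.
#' @return Scalar in `[0, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop_bad("x and y must have the same length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0) stop_bad("x is a zero vector")
  if (ny == 0) stop_bad("y is a zero vector")
  sum(x * y) / (nx * ny)
}

#' Pairwise topic similarity matrix and histogram
#'
#' Cosine similarity between every pair of topics, at gene level (rows of
#' `phi_hat`) or disease level (per-topic disease-mass vectors: columns of
#' `n_pk`, normalized). With `binary = TRUE` the vectors are replaced by
#' 0/1 membership indicators (expected count > `epsilon`). The histogram
#' counts unordered off-diagonal pairs over ten equal intervals
#' partitioning `[0, 1]`.
#'
#' @param model A `topic_model`.
#' @param level `"gene"` or `"disease"`.
#' @param binary Use binary membership vectors instead of probabilities?
#' @param epsilon Membership threshold for the binary mode.
#' @return List with `matrix` (K x K, unit diagonal) and `histogram`
#'   (named integer vector over the ten intervals).
#' @export
topic_similarity_matrix <- function(model, level = c("gene", "disease"),
                                    binary = FALSE, epsilon = 1e-6) {
  stopifnot(inherits(model, "topic_model"))
  level <- match.arg(level)
  vecs <- switch(level,
    gene    = model$phi_hat,
    disease = t(sweep(model$n_pk, 2L,
                      pmax(colSums(model$n_pk), .Machine$double.eps), "/")))
  if (binary) {
    raw <- switch(level, gene = model$n_ck, disease = t(model$n_pk))
    vecs <- (raw > epsilon) * 1
  }
  K <- nrow(vecs)
  sim <- matrix(1, K, K, dimnames = list(rownames(model$n_ck), rownames(model$n_ck)))
  if (K > 1L) {
    for (i in seq_len(K - 1L)) {
      for (j in seq((i + 1L), K)) {
        s <- min(max(cosine_similarity(vecs[i, ], vecs[j, ]), 0), 1)
        sim[i, j] <- s
        sim[j, i] <- s
      }
    }
  }
  breaks <- seq(0, 1, by = 0.1)
  off <- sim[upper.tri(sim)]
  h <- table(cut(off, breaks = breaks, include.lowest = TRUE, right = TRUE))
  list(matrix = sim, histogram = setNames(as.integer(h), names(h)))
}

#' Disease-gene association coverage (DGAC)
#'
#' The fraction of association set A confirmed by association set B:
#' `|A intersect B| / |A|`.
#'
#' @param a,b Association sets: data frames with columns `disease` and
#'   `gene` (duplicates ignored).
#' @return Scalar in `[0, 1]`.
#' @export
dgac <- function(a, b) {
  ka <- unique(pair_keys(a$disease, a$gene))
  kb <- unique(pair_keys(b$disease, b$gene))
  if (length(ka) == 0L) stop_bad("association set A must be non-empty")
  sum(ka %in% kb) / length(ka)
}

#' Build an association set
#'
#' @param disease,gene Parallel vectors of disease and gene ids.
#' @return Data frame of unique (disease, gene) pairs, class
#'   `association_set`.
#' @export
association_set <- function(disease, gene) {
  out <- unique(data.frame(disease = as.character(disease),
                           gene = as.character(gene),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("association_set", class(out))
  out
}

#' Read / write an association set as two-column TSV
#'
#' @param path File path; columns `disease`, `gene` (header included on
#'   write, tolerated on read).
#' @param x Association set to write.
#' @return `read_association_set`: an `association_set`.
#' @export
read_association_set <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  names(df)[1:2] <- c("disease", "gene")
  association_set(df$disease, df$gene)
}

#' @rdname read_association_set
#' @export
write_association_set <- function(x, path) {
  write.table(x[, c("disease", "gene")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Top-probability entities of a topic
#'
#' The `n` highest-probability genes (row of `phi_hat`) or diseases
#' (column-normalized `n_pk`) of one topic, ties broken lexicographically.
#'
#' @param model A `topic_model`.
#' @param topic Topic index (1-based) or topic name.
#' @param n Number of entities (truncated to availability).
#' @param level `"gene"` or `"disease"`.
#' @return Data frame with columns `id`, `probability`.
#' @export
top_entities <- function(model, topic, n = 5L, level = c("gene", "disease")) {
  stopifnot(inherits(model, "topic_model"), n >= 1L)
  level <- match.arg(level)
  K <- model$hyper$k
  if (is.character(topic)) topic <- match(topic, rownames(model$n_ck))
  if (is.na(topic) || topic < 1L || topic > K)
    stop_bad("topic index out of range")
  v <- switch(level,
    gene    = setNames(model$phi_hat[topic, ], colnames(model$phi_hat)),
    disease = {
      col <- model$n_pk[, topic]
      setNames(col / max(sum(col), .Machine$double.eps), rownames(model$n_pk))
    })
  ord <- order(-v, names(v))
  sel <- head(ord, n)
  data.frame(id = names(v)[sel], probability = unname(v[sel]),
             stringsAsFactors = FALSE)
}
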