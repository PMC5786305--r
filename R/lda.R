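# Latent Dirichlet allocation over disease documents / gene tokens.
#
# Generative model: per-topic gene distributions phi_k ~ Dirichlet(beta),
# per-disease topic mixtures theta_p ~ Dirichlet(alpha), token topics
# z ~ Multinomial(theta_p), tokens c ~ Multinomial(phi_z). Inference is
# collapsed: either zeroth-order collapsed variational Bayes (CVB0,
# deterministic given its seeded initialization) or collapsed Gibbs
# sampling. Posterior point estimates are the smoothed count ratios
#   phi_hat[k, i]   = (n_ck[k, i] + beta)  / (sum_i n_ck[k, i] + C beta)
#   theta_hat[j, k] = (n_pk[j, k] + alpha) / (sum_k n_pk[j, k] + K alpha)
# and the corpus log-likelihood is the Dirichlet-multinomial marginal of the
# token-topic assignment (Griffiths-Steyvers form, evaluated with lgamma).

#' Fit an LDA topic model to a corpus
#'
#' @param corpus A [new_corpus()] object.
#' @param k Number of topics (>= 2).
#' @param alpha Document-topic Dirichlet concentration (default 0.1).
#' @param beta Topic-gene Dirichlet concentration (default 0.01).
#' @param iterations Fixed iteration budget (default 1000).
#' @param seed Integer seed; all randomness (initialization and, for Gibbs,
#'   sampling) flows from it, so runs are exactly reproducible.
#' @param algorithm `"cvb0"` (zeroth-order collapsed variational Bayes,
#'   default) or `"gibbs"` (collapsed Gibbs sampling).
#' @param trace_every Record the log-likelihood every this many iterations.
#' @param early_stop If `TRUE`, stop once |delta LL| < `rel_tol` * |LL| for
#'   `patience` consecutive recorded evaluations (CVB0 only).
#' @param rel_tol,patience Early-stopping controls.
#' @param store_assignments Keep per-token responsibilities (CVB0) or topic
#'   assignments (Gibbs) on the model object.
#' @return An object of class `topic_model` with elements `hyper`
#'   (list alpha, beta, k), `n_ck` (K x C expected counts), `n_pk` (P x K),
#'   `phi_hat`, `theta_hat`, `assignments`, and `trace` (class `fit_trace`:
#'   `iteration`, `log_likelihood`, `converged`, `seed`).
#' @export
lda_fit <- function(corpus, k, alpha = 0.1, beta = 0.01, iterations = 1000L,
                    seed = 1L, algorithm = c("cvb0", "gibbs"),
                    trace_every = 10L, early_stop = FALSE,
                    rel_tol = 1e-4, patience = 10L,
                    store_assignments = TRUE) {
  validate_corpus(corpus)
  algorithm <- match.arg(algorithm)
  stopifnot(k >= 2L, alpha > 0, beta > 0, iterations >= 1L)
  k <- as.integer(k)

  toks <- corpus_tokens(corpus)
  P <- nrow(corpus$counts); C <- ncol(corpus$counts); N <- length(toks$doc)

  if (algorithm == "cvb0") {
    gamma0 <- with_seed(seed, rdirichlet(N, rep(1, k)))
    res <- cvb0_fit_cpp(toks$doc, toks$word, P, C, k, alpha, beta, gamma0,
                        as.integer(iterations), as.integer(trace_every),
                        rel_tol, if (early_stop) as.integer(patience) else 0L)
    assignments <- if (store_assignments) res$gamma else NULL
  } else {
    z0 <- with_seed(seed, sample.int(k, N, replace = TRUE) - 1L)
    res <- gibbs_fit_cpp(toks$doc, toks$word, P, C, k, alpha, beta, z0,
                         as.integer(iterations), as.integer(trace_every),
                         as.integer(seed))
    res$converged <- FALSE
    assignments <- if (store_assignments) res$z + 1L else NULL
  }

  n_ck <- res$n_ck; dimnames(n_ck) <- list(paste0("topic", seq_len(k)), corpus$vocabulary)
  n_pk <- res$n_pk; dimnames(n_pk) <- list(corpus$documents, paste0("topic", seq_len(k)))

  trace <- structure(list(
    iteration      = as.integer(res$trace_iteration),
    log_likelihood = as.numeric(res$trace_ll),
    converged      = isTRUE(res$converged),
    seed           = as.integer(seed)
  ), class = "fit_trace")

  model <- structure(list(
    hyper       = list(alpha = alpha, beta = beta, k = k),
    n_ck        = n_ck,
    n_pk        = n_pk,
    phi_hat     = estimate_phi(n_ck, beta),
    theta_hat   = estimate_theta(n_pk, alpha),
    assignments = assignments,
    algorithm   = algorithm,
    trace       = trace
  ), class = "topic_model")
  model
}

# Token stream (0-based doc and word indices) for the C++ kernels.
corpus_tokens <- function(corpus) {
  nz <- which(corpus$counts > 0L, arr.ind = TRUE)
  reps <- corpus$counts[nz]
  list(doc  = rep.int(nz[, 1L] - 1L, reps),
       word = rep.int(nz[, 2L] - 1L, reps))
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic_model: K=%d topics, %d documents, %d tokens (%s)\n",
              x$hyper$k, nrow(x$n_pk), round(sum(x$n_ck)), x$algorithm))
  cat(sprintf("final log-likelihood: %.4f\n",
              tail(x$trace$log_likelihood, 1L)))
  invisible(x)
}

#' Posterior topic-gene distributions
#'
#' Smoothed point estimate of each topic's gene distribution from the
#' topic-gene pseudo-counts: `(n_ck + beta) / (rowSums(n_ck) + C * beta)`.
#'
#' @param n_ck K x C non-negative matrix of (expected) gene counts per topic.
#' @param beta Topic-gene Dirichlet concentration.
#' @return Row-stochastic K x C matrix.
#' @export
estimate_phi <- function(n_ck, beta) {
  if (any(n_ck < 0)) stop_bad("n_ck must be non-negative")
  stopifnot(beta > 0)
  C <- ncol(n_ck)
  (n_ck + beta) / (rowSums(n_ck) + C * beta)
}

#' Posterior document-topic distributions
#'
#' Smoothed point estimate of each disease's topic mixture:
#' `(n_pk + alpha) / (rowSums(n_pk) + K * alpha)`.
#'
#' @param n_pk P x K non-negative matrix of (expected) topic counts per
#'   document.
#' @param alpha Document-topic Dirichlet concentration.
#' @return Row-stochastic P x K matrix.
#' @export
estimate_theta <- function(n_pk, alpha) {
  if (any(n_pk < 0)) stop_bad("n_pk must be non-negative")
  stopifnot(alpha > 0)
  K <- ncol(n_pk)
  (n_pk + alpha) / (rowSums(n_pk) + K * alpha)
}

#' Corpus log-likelihood of a topic assignment
#'
#' The collapsed Dirichlet-multinomial marginal log p(c | z):
#' `T * (lgamma(C*beta) - C*lgamma(beta)) +
#'  sum_t ( sum_c lgamma(n_tc + beta) - lgamma(n_t. + C*beta) )`,
#' evaluated with log-gamma throughout so it is finite for any non-negative
#' (including fractional CVB0) counts.
#'
#' @param x A `topic_model`, or a K x C matrix of topic-gene counts.
#' @param beta Topic-gene concentration; taken from the model when `x` is a
#'   `topic_model`.
#' @return Scalar log-likelihood.
#' @export
lda_log_likelihood <- function(x, beta = NULL) {
  if (inherits(x, "topic_model")) {
    n_ck <- x$n_ck
    beta <- beta %||% x$hyper$beta
  } else {
    n_ck <- as.matrix(x)
    if (is.null(beta)) stop_bad("beta required when x is a count matrix")
  }
  if (any(n_ck < 0)) stop_bad("counts must be non-negative")
  K <- nrow(n_ck); C <- ncol(n_ck)
  K * (lgamma(C * beta) - C * lgamma(beta)) +
    sum(lgamma(n_ck + beta)) - sum(lgamma(rowSums(n_ck) + C * beta))
}

#' Joint log-likelihood of tokens and topic assignments
#'
#' `log p(c, z) = log p(c | z) + log p(z)`: the token-side
#' Dirichlet-multinomial of [lda_log_likelihood()] plus the document-side
#' term `P * (lgamma(K*alpha) - K*lgamma(alpha)) +
#' sum_p ( sum_k lgamma(n_pk + alpha) - lgamma(n_p. + K*alpha) )`.
#' This is the collection likelihood with all latent variables integrated
#' out given the assignment, and is the default topic-number selection
#' score: unlike p(c | z) alone it charges documents for spreading mass over
#' additional topics, so it peaks rather than growing monotonically in K.
#'
#' @param model A fitted `topic_model`.
#' @return Scalar log-likelihood.
#' @export
lda_joint_log_likelihood <- function(model) {
  stopifnot(inherits(model, "topic_model"))
  n_pk <- model$n_pk
  alpha <- model$hyper$alpha
  K <- ncol(n_pk)
  lda_log_likelihood(model) +
    nrow(n_pk) * (lgamma(K * alpha) - K * lgamma(alpha)) +
    sum(lgamma(n_pk + alpha)) - sum(lgamma(rowSums(n_pk) + K * alpha))
}

#' Select the number of topics by log-likelihood
#'
#' Fits the model at every value of `k_grid` for every seed and returns the
#' grid value with the highest mean log-likelihood (ties go to the smallest
#' K, with a message). The default score is the joint collection likelihood
#' log p(c, z) ([lda_joint_log_likelihood()]); `score = "conditional"` uses
#' the token-side log p(c | z) only.
#'
#' @param corpus A `corpus`.
#' @param k_grid Increasing integer vector of candidate topic numbers
#'   (length >= 2).
#' @param iterations,alpha,beta,algorithm Passed to [lda_fit()].
#' @param seeds Integer vector of seeds averaged over.
#' @param score `"joint"` (default) or `"conditional"`.
#' @return List with `best_k`, `scores` (data frame: k, seed,
#'   log_likelihood), `mean_scores` (data frame: k, mean_log_likelihood) and
#'   `tie` flag.
#' @export
select_topic_number <- function(corpus, k_grid, iterations = 200L,
                                seeds = 1:3, alpha = 0.1, beta = 0.01,
                                algorithm = "cvb0",
                                score = c("joint", "conditional")) {
  if (length(k_grid) < 2L) stop_bad("k_grid must contain at least 2 values")
  if (is.unsorted(k_grid, strictly = TRUE)) stop_bad("k_grid must be strictly increasing")
  score <- match.arg(score)
  rows <- list()
  for (k in k_grid) {
    for (s in seeds) {
      fit <- lda_fit(corpus, k = k, alpha = alpha, beta = beta,
                     iterations = iterations, seed = s,
                     algorithm = algorithm, store_assignments = FALSE)
      ll <- switch(score,
                   joint = lda_joint_log_likelihood(fit),
                   conditional = tail(fit$trace$log_likelihood, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, seed = s, log_likelihood = ll)
    }
  }
  scores <- do.call(rbind, rows)
  mean_ll <- vapply(split(scores$log_likelihood, scores$k), mean, numeric(1))
  ks <- as.integer(names(mean_ll))
  ord <- order(ks)
  ks <- ks[ord]; mean_ll <- mean_ll[ord]
  best <- which(mean_ll == max(mean_ll))
  tie <- length(best) > 1L
  if (tie) message("tie in mean log-likelihood; reporting the smallest K")
  list(best_k = ks[min(best)],
       scores = scores,
       mean_scores = data.frame(k = ks, mean_log_likelihood = unname(mean_ll)),
       tie = tie)
}

#' Topic membership lists
#'
#' A gene belongs to topic k when its expected count in that topic exceeds
#' `epsilon`; a disease belongs when its expected topic count does. (Under
#' Dirichlet smoothing no posterior probability is exactly zero, so
#' membership is thresholded on expected counts.) Lists are ordered by
#' probability, descending, ties broken lexicographically by id.
#'
#' @param model A `topic_model`.
#' @param epsilon Expected-count membership threshold (default 1e-6).
#' @return List with one element per topic, each a list of data frames
#'   `genes` (id, count, probability) and `diseases` (id, count,
#'   probability).
#' @export
topic_memberships <- function(model, epsilon = 1e-6) {
  stopifnot(inherits(model, "topic_model"))
  K <- model$hyper$k
  gene_prob <- model$phi_hat
  # p(disease | topic): per-topic mass over diseases, column-normalized n_pk
  dis_prob <- sweep(model$n_pk, 2L, pmax(colSums(model$n_pk), .Machine$double.eps), "/")
  out <- vector("list", K)
  for (k in seq_len(K)) {
    gsel <- which(model$n_ck[k, ] > epsilon)
    gdf <- data.frame(id = colnames(model$n_ck)[gsel],
                      count = unname(model$n_ck[k, gsel]),
                      probability = unname(gene_prob[k, gsel]),
                      stringsAsFactors = FALSE)
    gdf <- gdf[order(-gdf$probability, gdf$id), , drop = FALSE]
    rownames(gdf) <- NULL
    dsel <- which(model$n_pk[, k] > epsilon)
    ddf <- data.frame(id = rownames(model$n_pk)[dsel],
                      count = unname(model$n_pk[dsel, k]),
                      probability = unname(dis_prob[dsel, k]),
                      stringsAsFactors = FALSE)
    ddf <- ddf[order(-ddf$probability, ddf$id), , drop = FALSE]
    rownames(ddf) <- NULL
    out[[k]] <- list(genes = gdf, diseases = ddf)
  }
  names(out) <- rownames(model$n_ck)
  out
}

#' Rank topics by normalized posterior mass
#'
#' Topic mass is the total expected gene count assigned to the topic;
#' normalized probabilities sum to one. Ordered descending, ties by topic
#' index.
#'
#' @param model A `topic_model`.
#' @return Data frame with columns `topic`, `mass`, `probability`.
#' @export
rank_topics <- function(model) {
  stopifnot(inherits(model, "topic_model"))
  mass <- rowSums(model$n_ck)
  prob <- mass / sum(mass)
  ord <- order(-prob, seq_along(prob))
  out <- data.frame(topic = rownames(model$n_ck)[ord],
                    mass = unname(mass[ord]),
                    probability = unname(prob[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a fitted topic model as plain text
#'
#' Serializes hyperparameters to `hyper.yaml`, the count matrices to triplet
#' TSVs and the fit trace to `trace.csv` under `dir`.
#'
#' @param model A `topic_model`.
#' @param dir Output directory.
#' @return `write_topic_model`: the directory, invisibly;
#'   `read_topic_model`: a `topic_model` (without per-token assignments).
#' @export
write_topic_model <- function(model, dir) {
  stopifnot(inherits(model, "topic_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(c(model$hyper, algorithm = model$algorithm,
                     seed = model$trace$seed,
                     converged = model$trace$converged),
                   file.path(dir, "hyper.yaml"))
  write_triplets <- function(m, path) {
    nz <- which(m > 1e-12, arr.ind = TRUE)
    trip <- data.frame(row = rownames(m)[nz[, 1L]],
                       col = colnames(m)[nz[, 2L]],
                       value = m[nz])
    trip <- trip[order(trip$row, trip$col), ]
    write.table(trip, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_triplets(model$n_ck, file.path(dir, "n_ck.tsv"))
  write_triplets(model$n_pk, file.path(dir, "n_pk.tsv"))
  write.csv(data.frame(iteration = model$trace$iteration,
                       log_likelihood = model$trace$log_likelihood),
            file.path(dir, "trace.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_topic_model
#' @export
read_topic_model <- function(dir) {
  hy <- yaml::read_yaml(file.path(dir, "hyper.yaml"))
  read_triplets <- function(path) {
    trip <- read.delim(path, colClasses = c("character", "character", "numeric"))
    rows <- unique(trip$row); cols <- unique(trip$col)
    m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    m[cbind(match(trip$row, rows), match(trip$col, cols))] <- trip$value
    m
  }
  n_ck <- read_triplets(file.path(dir, "n_ck.tsv"))
  # order topics numerically
  n_ck <- n_ck[order(rownames(n_ck)), , drop = FALSE]
  n_pk <- read_triplets(file.path(dir, "n_pk.tsv"))
  n_pk <- n_pk[, order(colnames(n_pk)), drop = FALSE]
  tr <- read.csv(file.path(dir, "trace.csv"))
  structure(list(
    hyper = list(alpha = hy$alpha, beta = hy$beta, k = hy$k),
    n_ck = n_ck, n_pk = n_pk,
    phi_hat = estimate_phi(n_ck, hy$beta),
    theta_hat = estimate_theta(n_pk, hy$alpha),
    assignments = NULL,
    algorithm = hy$algorithm,
    trace = structure(list(iteration = tr$iteration,
                           log_likelihood = tr$log_likelihood,
                           converged = isTRUE(hy$converged),
                           seed = hy$seed), class = "fit_trace")
  ), class = "topic_model")
}
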