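# Generators for every input the pipeline consumes, with recorded ground
# truth: planted-topic corpora (the model's own generative process), aligned
# or random disease ontologies, gold-standard association sets, and bipartite
# networks. All generators are deterministic per seed.

#' Generate a planted-topic corpus
#'
#' Draws per-topic gene distributions `phi_k ~ Dirichlet(beta)`, per-disease
#' mixtures `theta_p ~ Dirichlet(alpha)`, document lengths
#' `~ Poisson(mean_doc_len)` truncated to >= 1, and tokens via
#' topic-then-gene multinomial draws. Genes never drawn are dropped from the
#' corpus vocabulary (a corpus admits no all-zero column); the recorded
#' `true_phi` is restricted to the observed vocabulary and renormalized
#' (`true_phi_full` keeps the unrestricted draw).
#'
#' @param k Number of topics.
#' @param n_diseases Number of documents (P).
#' @param n_genes Vocabulary size before restriction (C); must be >= `k`.
#' @param alpha,beta Dirichlet concentrations (defaults 0.1, 0.01).
#' @param mean_doc_len Mean document length (default 50).
#' @param seed Integer seed.
#' @return Object of class `planted_corpus`: `corpus`, `true_phi` (k x
#'   observed-C, row-stochastic), `true_theta` (P x k), `true_phi_full`,
#'   `dominant_topic` (per disease), `pair_counts` (true disease-gene token
#'   counts) and `params`.
#' @export
generate_corpus <- function(k, n_diseases, n_genes, alpha = 0.1, beta = 0.01,
                            mean_doc_len = 50, seed = 1L) {
  stopifnot(k >= 1L, n_diseases >= 1L, n_genes >= k,
            alpha > 0, beta > 0, mean_doc_len > 0)
  genes <- sprintf("G%04d", seq_len(n_genes))
  diseases <- sprintf("D%04d", seq_len(n_diseases))
  with_seed(seed, {
    phi <- rdirichlet(k, rep(beta, n_genes))
    theta <- if (k == 1L) matrix(1, n_diseases, 1L)
             else rdirichlet(n_diseases, rep(alpha, k))
    lens <- rpois(n_diseases, mean_doc_len)
    while (any(lens == 0L)) lens[lens == 0L] <- rpois(sum(lens == 0L), mean_doc_len)
    counts <- matrix(0L, n_diseases, n_genes, dimnames = list(diseases, genes))
    for (p in seq_len(n_diseases)) {
      z <- sample.int(k, lens[p], replace = TRUE, prob = theta[p, ])
      for (kk in unique(z)) {
        w <- sample.int(n_genes, sum(z == kk), replace = TRUE, prob = phi[kk, ])
        tw <- tabulate(w, nbins = n_genes)
        counts[p, ] <- counts[p, ] + tw
      }
    }
    dimnames(phi) <- list(paste0("topic", seq_len(k)), genes)
    dimnames(theta) <- list(diseases, paste0("topic", seq_len(k)))
    observed <- colSums(counts) > 0L
    corpus <- new_corpus(counts[, observed, drop = FALSE])
    phi_obs <- phi[, observed, drop = FALSE]
    phi_obs <- phi_obs / rowSums(phi_obs)
    structure(list(
      corpus = corpus,
      true_phi = phi_obs,
      true_theta = theta,
      true_phi_full = phi,
      dominant_topic = setNames(max.col(theta), diseases),
      pair_counts = counts[, observed, drop = FALSE],
      params = list(k = k, n_diseases = n_diseases, n_genes = n_genes,
                    alpha = alpha, beta = beta,
                    mean_doc_len = mean_doc_len, seed = seed)
    ), class = "planted_corpus")
  })
}

#' Generate a disease ontology tree with annotations
#'
#' Builds a complete rooted tree of the given depth and branching factor.
#' In aligned mode (a `planted_corpus` supplied), each planted topic is
#' assigned one depth-1 subtree and every disease is annotated to a leaf of
#' its dominant topic's subtree, so topic membership coincides with subtree
#' membership; otherwise annotations are uniform over leaves.
#'
#' @param depth Tree depth (>= 3; root is depth 0).
#' @param branching Children per internal node.
#' @param n_diseases Number of diseases to annotate (ignored in aligned
#'   mode, where the planted corpus supplies them).
#' @param aligned_topics Optional `planted_corpus` to align with (requires
#'   `branching >= k`).
#' @param seed Integer seed.
#' @return List: `dag` (annotated `ontology_dag`), `annotations` (data
#'   frame disease, term).
#' @export
generate_ontology <- function(depth = 3L, branching = 2L, n_diseases = 50L,
                              aligned_topics = NULL, seed = 1L) {
  stopifnot(depth >= 3L, branching >= 2L)
  # complete tree; term ids encode the path from the root
  edges <- list()
  level_nodes <- list("T")
  for (d in seq_len(depth)) {
    prev <- level_nodes[[d]]
    cur <- unlist(lapply(prev, function(p) paste0(p, ".", seq_len(branching))))
    edges[[d]] <- data.frame(child = cur,
                             parent = rep(prev, each = branching),
                             stringsAsFactors = FALSE)
    level_nodes[[d + 1L]] <- cur
  }
  dag <- ontology_dag(do.call(rbind, edges))
  leaves <- level_nodes[[depth + 1L]]

  with_seed(seed, {
    if (!is.null(aligned_topics)) {
      stopifnot(inherits(aligned_topics, "planted_corpus"))
      k <- aligned_topics$params$k
      if (branching < k)
        stop_bad("aligned mode needs branching >= number of topics")
      dom <- aligned_topics$dominant_topic
      diseases <- names(dom)
      # leaves under depth-1 subtree s have ids starting "T.s."
      subtree_leaves <- lapply(seq_len(branching), function(s)
        leaves[startsWith(leaves, paste0("T.", s, "."))])
      term <- vapply(seq_along(diseases), function(i) {
        pool <- subtree_leaves[[dom[i]]]
        pool[sample.int(length(pool), 1L)]
      }, character(1L))
    } else {
      diseases <- sprintf("D%04d", seq_len(n_diseases))
      if (n_diseases > length(leaves))
        warning("more diseases than leaves; leaves reused", call. = FALSE)
      term <- leaves[sample.int(length(leaves), length(diseases), replace = TRUE)]
    }
    ann <- data.frame(disease = diseases, term = term, stringsAsFactors = FALSE)
    list(dag = annotate_diseases(dag, ann), annotations = ann)
  })
}

#' Generate a gold-standard association set from a planted corpus
#'
#' Samples a `coverage` fraction of the true disease-gene pairs (pairs with
#' generator count >= 1) and adds `round(noise * n_sampled)` never-generated
#' pairs drawn uniformly from the complement.
#'
#' @param planted A `planted_corpus`.
#' @param coverage Fraction of true pairs retained, in (0, 1].
#' @param noise Noise fraction relative to the sampled pairs, in \[0, 1).
#' @param seed Integer seed.
#' @return An `association_set`.
#' @export
generate_gold_associations <- function(planted, coverage = 1, noise = 0,
                                       seed = 1L) {
  stopifnot(inherits(planted, "planted_corpus"),
            coverage > 0, coverage <= 1, noise >= 0, noise < 1)
  cts <- planted$pair_counts
  true_idx <- which(cts >= 1L, arr.ind = TRUE)
  with_seed(seed, {
    n_keep <- max(1L, round(coverage * nrow(true_idx)))
    keep <- true_idx[sample.int(nrow(true_idx), n_keep), , drop = FALSE]
    dis <- rownames(cts)[keep[, 1L]]
    gen <- colnames(cts)[keep[, 2L]]
    n_noise <- round(noise * n_keep)
    if (n_noise > 0L) {
      zero_idx <- which(cts == 0L, arr.ind = TRUE)
      pick <- zero_idx[sample.int(nrow(zero_idx), min(n_noise, nrow(zero_idx))), ,
                       drop = FALSE]
      dis <- c(dis, rownames(cts)[pick[, 1L]])
      gen <- c(gen, colnames(cts)[pick[, 2L]])
    }
    association_set(dis, gen)
  })
}

#' Generate a synthetic bipartite disease-gene network
#'
#' Preferential mode grows the network node by node: after a seed
#' disease-gene pair, the remaining nodes arrive in random interleaved order
#' and each attaches its share of the edge budget to existing nodes of the
#' opposite side with probability proportional to current degree + 1
#' (Barabasi-Albert-style growth, heavy-tailed degrees; any residual edge
#' budget is placed preferentially between existing nodes). Uniform mode
#' samples disease-gene pairs without replacement. Simple and bipartite by
#' construction; deterministic per seed.
#'
#' @param n_disease,n_gene Node counts per side.
#' @param n_edges Number of edges (<= n_disease * n_gene).
#' @param attachment `"preferential"` or `"uniform"`.
#' @param seed Integer seed.
#' @return A `bipartite_network`.
#' @export
generate_bipartite_network <- function(n_disease, n_gene, n_edges,
                                       attachment = c("preferential", "uniform"),
                                       seed = 1L) {
  attachment <- match.arg(attachment)
  stopifnot(n_edges >= 1L, n_edges <= as.double(n_disease) * n_gene)
  diseases <- sprintf("D%04d", seq_len(n_disease))
  genes <- sprintf("G%04d", seq_len(n_gene))
  with_seed(seed, {
    if (attachment == "uniform") {
      cells <- sample.int(as.integer(n_disease) * n_gene, n_edges)
      di <- ((cells - 1L) %% n_disease) + 1L
      gi <- ((cells - 1L) %/% n_disease) + 1L
    } else {
      deg_d <- rep(0L, n_disease)
      deg_g <- rep(0L, n_gene)
      di <- integer(0); gi <- integer(0)
      # seed pair
      deg_d[1L] <- 1L; deg_g[1L] <- 1L
      di <- 1L; gi <- 1L
      nd <- 1L; ng <- 1L
      side <- sample(c(rep(1L, n_disease - 1L), rep(2L, n_gene - 1L)))
      quota <- diff(round(seq(0, n_edges - 1L, length.out = length(side) + 1L)))
      carry <- 0L
      for (i in seq_along(side)) {
        m <- quota[i] + carry
        if (side[i] == 1L) {
          nd <- nd + 1L
          m2 <- min(m, ng)
          if (m2 > 0L) {
            tgt <- sample.int(ng, m2, prob = deg_g[seq_len(ng)] + 1)
            di <- c(di, rep(nd, m2)); gi <- c(gi, tgt)
            deg_d[nd] <- deg_d[nd] + m2
            deg_g[tgt] <- deg_g[tgt] + 1L
          }
        } else {
          ng <- ng + 1L
          m2 <- min(m, nd)
          if (m2 > 0L) {
            tgt <- sample.int(nd, m2, prob = deg_d[seq_len(nd)] + 1)
            di <- c(di, tgt); gi <- c(gi, rep(ng, m2))
            deg_g[ng] <- deg_g[ng] + m2
            deg_d[tgt] <- deg_d[tgt] + 1L
          }
        }
        carry <- m - m2
      }
      # place any residual budget preferentially between existing nodes
      have <- new.env(hash = TRUE, parent = emptyenv())
      for (e in seq_along(di)) have[[paste0(di[e], "_", gi[e])]] <- TRUE
      while (length(di) < n_edges) {
        d <- sample.int(n_disease, 1L, prob = deg_d + 1)
        g <- sample.int(n_gene, 1L, prob = deg_g + 1)
        key <- paste0(d, "_", g)
        if (!is.null(have[[key]])) next
        have[[key]] <- TRUE
        di <- c(di, d); gi <- c(gi, g)
        deg_d[d] <- deg_d[d] + 1L
        deg_g[g] <- deg_g[g] + 1L
      }
    }
    bipartite_network(data.frame(disease = diseases[di], gene = genes[gi],
                                 stringsAsFactors = FALSE),
                      diseases = diseases, genes = genes)
  })
}

#' Match learned topics to planted topics
#'
#' Optimal one-to-one assignment maximizing total row-wise cosine similarity
#' between true and learned topic-gene distributions (Hungarian algorithm).
#'
#' @param true_phi,learned_phi Row-stochastic K x C matrices over the same
#'   vocabulary (columns aligned by name when both are named).
#' @return List: `permutation` (learned topic matched to each true topic)
#'   and `mean_cosine`.
#' @export
match_topics <- function(true_phi, learned_phi) {
  if (nrow(true_phi) != nrow(learned_phi))
    stop_bad("true and learned phi must have the same number of topics")
  if (!is.null(colnames(true_phi)) && !is.null(colnames(learned_phi))) {
    common <- intersect(colnames(true_phi), colnames(learned_phi))
    if (length(common) == 0L) stop_bad("no shared vocabulary columns")
    true_phi <- true_phi[, common, drop = FALSE]
    learned_phi <- learned_phi[, common, drop = FALSE]
  } else if (ncol(true_phi) != ncol(learned_phi)) {
    stop_bad("phi matrices must share their vocabulary")
  }
  K <- nrow(true_phi)
  sim <- matrix(0, K, K)
  for (i in seq_len(K))
    for (j in seq_len(K))
      sim[i, j] <- cosine_similarity(true_phi[i, ], learned_phi[j, ])
  perm <- solve_assignment(1 - sim)
  list(permutation = perm,
       mean_cosine = mean(sim[cbind(seq_len(K), perm)]))
}

#' Write a complete synthetic input bundle
#'
#' Materializes a planted corpus and its companion inputs in the exact
#' formats the pipeline reads: predication TSV (one row per token),
#' gene-symbol list, ontology edge TSV, annotation TSV, gold-standard
#' association TSV, and a GMT collection whose sets are the top genes of
#' each planted topic.
#'
#' @param dir Output directory (created).
#' @param k,n_diseases,n_genes,alpha,beta,mean_doc_len Generator parameters
#'   (see [generate_corpus()]).
#' @param seed Integer seed.
#' @param gmt_top Genes per topic gene set (default 15).
#' @return List of file paths plus the `planted_corpus` and ontology, invisibly.
#' @export
write_demo_inputs <- function(dir, k = 3L, n_diseases = 40L, n_genes = 60L,
                              alpha = 0.1, beta = 0.01, mean_doc_len = 30,
                              seed = 1L, gmt_top = 15L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planted <- generate_corpus(k, n_diseases, n_genes, alpha, beta,
                             mean_doc_len, seed)
  cts <- planted$corpus$counts
  nz <- which(cts > 0L, arr.ind = TRUE)
  pred <- data.frame(
    subject_name = rownames(cts)[rep(nz[, 1L], cts[nz])],
    subject_semtype = "dsyn",
    predicate = "ASSOCIATED_WITH",
    object_name = colnames(cts)[rep(nz[, 2L], cts[nz])],
    object_semtype = "gngm",
    citation_id = seq_len(sum(cts[nz])),
    stringsAsFactors = FALSE
  )
  pred_path <- file.path(dir, "predications.tsv")
  write.table(pred, pred_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  genes_path <- file.path(dir, "gene_symbols.txt")
  writeLines(c("# approved symbols", planted$corpus$vocabulary), genes_path)

  # depth 4 keeps distinct depth-1 subtrees dissimilar at the default
  # three-level ancestor bound (at depth 3 every leaf reaches the root)
  onto <- generate_ontology(depth = 4L, branching = max(2L, k),
                            aligned_topics = planted, seed = seed + 1L)
  onto_path <- file.path(dir, "ontology_edges.tsv")
  withp <- names(onto$dag$parents)[lengths(onto$dag$parents) > 0L]
  edges <- do.call(rbind, lapply(withp, function(ch)
    data.frame(child = ch, parent = onto$dag$parents[[ch]],
               stringsAsFactors = FALSE)))
  write.table(edges[order(edges$child, edges$parent), ], onto_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  ann_path <- file.path(dir, "annotations.tsv")
  # annotations are keyed by normalized disease id, as the corpus documents are
  ann <- onto$annotations
  ann$disease <- normalize_disease_id(ann$disease)
  write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)

  gold <- generate_gold_associations(planted, coverage = 0.8, noise = 0.05,
                                     seed = seed + 2L)
  gold$disease <- normalize_disease_id(gold$disease)
  gold_path <- file.path(dir, "gold_associations.tsv")
  write_association_set(gold, gold_path)

  gmt_path <- file.path(dir, "gene_sets.gmt")
  gmt_lines <- vapply(seq_len(k), function(kk) {
    top <- colnames(planted$true_phi)[order(-planted$true_phi[kk, ])]
    top <- head(top, gmt_top)
    paste(c(sprintf("PLANTED_TOPIC_%d", kk), "synthetic topic gene set", top),
          collapse = "\t")
  }, character(1L))
  writeLines(gmt_lines, gmt_path)

  invisible(list(predications = pred_path, gene_symbols = genes_path,
                 ontology = onto_path, annotations = ann_path,
                 gold = gold_path, gmt = gmt_path,
                 planted = planted, ontology_obj = onto))
}
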