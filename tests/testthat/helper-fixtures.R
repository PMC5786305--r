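# Shared fixture builders and independent brute-force oracles.

write_pred_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# association data frame shorthand
assoc_df <- function(disease, gene) {
  data.frame(disease_id = disease, disease_name = disease,
             disease_semtype = "dsyn", gene_symbol = gene,
             stringsAsFactors = FALSE)
}

# a topic_model built directly from count matrices (no fitting)
fake_model <- function(n_ck, n_pk, alpha = 0.1, beta = 0.01) {
  if (is.null(rownames(n_ck))) rownames(n_ck) <- paste0("topic", seq_len(nrow(n_ck)))
  if (is.null(colnames(n_ck))) colnames(n_ck) <- paste0("g", seq_len(ncol(n_ck)))
  if (is.null(rownames(n_pk))) rownames(n_pk) <- paste0("d", seq_len(nrow(n_pk)))
  colnames(n_pk) <- rownames(n_ck)
  structure(list(
    hyper = list(alpha = alpha, beta = beta, k = nrow(n_ck)),
    n_ck = n_ck, n_pk = n_pk,
    phi_hat = estimate_phi(n_ck, beta),
    theta_hat = estimate_theta(n_pk, alpha),
    assignments = NULL, algorithm = "cvb0",
    trace = structure(list(iteration = 1L, log_likelihood = 0,
                           converged = FALSE, seed = 1L),
                      class = "fit_trace")
  ), class = "topic_model")
}

# evaluate expr under a fixed seed without disturbing the suite's RNG stream
with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# random stochastic vector
rdirichlet_test <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# brute-force symmetric KL, term by term
brute_ldakl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[i] * log(p[i] / q[i]) + q[i] * log(q[i] / p[i])
  s
}

# brute-force connected-triple census over all C(n,3) node triples
brute_motifs <- function(net) {
  nodes <- c(net$diseases, net$genes)
  is_gene <- c(rep(FALSE, length(net$diseases)), rep(TRUE, length(net$genes)))
  ekeys <- paste(net$edges$disease, net$edges$gene)
  has_edge <- function(a, b) {
    paste(a, b) %in% ekeys || paste(b, a) %in% ekeys
  }
  counts <- c("D-G-D" = 0, "G-D-G" = 0)
  n <- length(nodes)
  if (n < 3) return(counts)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    trio <- nodes[c(i, j, k)]
    gene_flags <- is_gene[c(i, j, k)]
    e <- c(has_edge(trio[1], trio[2]), has_edge(trio[1], trio[3]),
           has_edge(trio[2], trio[3]))
    if (sum(e) < 2) next # disconnected (triangles impossible in bipartite)
    pat <- if (sum(gene_flags) == 1) "D-G-D" else "G-D-G"
    counts[pat] <- counts[pat] + 1
  }
  counts
}

# brute-force assignment: best permutation by exhaustive search
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) { best_cost <- cc; best <- p }
  }
  list(perm = best, cost = best_cost)
}

# small random bipartite network for property tests
random_net <- function(seed, max_nodes = 25) {
  set.seed(seed)
  nd <- sample(2:(max_nodes %/% 2), 1)
  ng <- sample(2:(max_nodes - nd), 1)
  maxe <- nd * ng
  ne <- sample(seq_len(min(maxe, 3 * (nd + ng))), 1)
  cells <- sample.int(maxe, ne)
  bipartite_network(data.frame(
    disease = paste0("d", ((cells - 1) %% nd) + 1),
    gene = paste0("g", ((cells - 1) %/% nd) + 1)))
}

# six-disease ontology fixture: d1, d2, d4 form a similar clique (terms t1-t3
# under parent A); d5 is annotated to a term deeper than the shared-ancestor
# bound; d3, d6 are unannotated.
pr_fixture <- function() {
  edges <- data.frame(
    child  = c("A", "B", "t1", "t2", "t3", "b1", "b2", "b3", "t5"),
    parent = c("R", "R", "A", "A", "A", "B", "b1", "b2", "b3"))
  ann <- data.frame(disease = c("d1", "d2", "d4", "d5"),
                    term = c("t1", "t2", "t3", "t5"))
  ontology_dag(edges, ann)
}
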