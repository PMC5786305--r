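test_that("planted corpora are reproducible and satisfy corpus invariants", {
  a <- generate_corpus(k = 4, n_diseases = 30, n_genes = 50, mean_doc_len = 20,
                       seed = 12)
  b <- generate_corpus(k = 4, n_diseases = 30, n_genes = 50, mean_doc_len = 20,
                       seed = 12)
  expect_identical(a$corpus$counts, b$corpus$counts)
  expect_identical(a$true_phi, b$true_phi)
  for (params in list(c(2, 10, 20, 5), c(5, 40, 60, 30), c(3, 25, 30, 12))) {
    pc <- generate_corpus(k = params[1], n_diseases = params[2],
                          n_genes = params[3], mean_doc_len = params[4],
                          seed = params[1] * 7)
    expect_silent(validate_corpus(pc$corpus))
    expect_equal(rowSums(pc$true_phi), rep(1, params[1]), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(rowSums(pc$true_theta), rep(1, params[2]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # K = 1: degenerate mixture
  pc1 <- generate_corpus(k = 1, n_diseases = 10, n_genes = 20,
                         mean_doc_len = 10, seed = 3)
  expect_true(all(pc1$true_theta == 1))
})

test_that("empirical gene frequencies track the mass-weighted topic mixture", {
  pc <- generate_corpus(k = 5, n_diseases = 200, n_genes = 100, alpha = 0.1,
                        beta = 0.01, mean_doc_len = 50, seed = 1)
  emp <- colSums(pc$corpus$counts) / sum(pc$corpus$counts)
  topic_mass <- colSums(pc$true_theta)  # expected token share per topic
  expected <- as.vector((topic_mass / sum(topic_mass)) %*% pc$true_phi)
  expect_gt(cor(emp, expected), 0.9)
})

test_that("complete ontology trees have the right size and aligned annotations", {
  onto <- generate_ontology(depth = 3, branching = 2, n_diseases = 5, seed = 2)
  expect_equal(length(onto$dag$terms), 15)  # 1 + 2 + 4 + 8
  expect_equal(nrow(onto$annotations), 5)

  pc <- generate_corpus(k = 3, n_diseases = 30, n_genes = 40, mean_doc_len = 20,
                        seed = 6)
  ao <- generate_ontology(depth = 4, branching = 3, aligned_topics = pc, seed = 6)
  dag <- ao$dag
  dom <- pc$dominant_topic
  within <- c(); between <- c()
  ds <- names(dom)
  for (i in 1:(length(ds) - 1)) for (j in (i + 1):length(ds)) {
    s <- diseases_similar(dag, ds[i], ds[j])
    if (dom[i] == dom[j]) within <- c(within, s) else between <- c(between, s)
  }
  expect_equal(mean(within), 1)   # same subtree by construction
  expect_equal(mean(between), 0)  # disjoint three-level closures
  expect_error(generate_ontology(depth = 4, branching = 2, aligned_topics = pc),
               "branching >= number of topics")
})

test_that("random annotations carry no group structure", {
  ps <- vapply(1:5, function(s) {
    onto <- generate_ontology(depth = 4, branching = 3, n_diseases = 60,
                              seed = 300 + s)
    dag <- onto$dag
    dis <- onto$annotations$disease
    grp <- rep(1:3, each = 20)
    sim <- outer(dis, dis,
                 Vectorize(function(a, b) isTRUE(diseases_similar(dag, a, b))))
    ut <- upper.tri(sim)
    same <- outer(grp, grp, "==")
    suppressWarnings(stats::chisq.test(table(sim[ut], same[ut]))$p.value)
  }, numeric(1))
  expect_true(all(ps > 0.01))
})

test_that("gold-standard coverage scales the recovered fraction", {
  pc <- generate_corpus(k = 3, n_diseases = 50, n_genes = 60, mean_doc_len = 30,
                        seed = 10)
  truth <- association_set(
    rep(rownames(pc$pair_counts), times = ncol(pc$pair_counts))[pc$pair_counts > 0],
    rep(colnames(pc$pair_counts), each = nrow(pc$pair_counts))[pc$pair_counts > 0])
  full <- generate_gold_associations(pc, coverage = 1, noise = 0, seed = 1)
  expect_equal(dgac(truth, full), 1)
  half <- generate_gold_associations(pc, coverage = 0.5, noise = 0, seed = 1)
  n <- nrow(truth)
  expect_lt(abs(dgac(truth, half) - 0.5), 3 * sqrt(0.25 / n))
  # noise pairs are never-generated ones
  noisy <- generate_gold_associations(pc, coverage = 0.5, noise = 0.2, seed = 2)
  extra <- setdiff(paste(noisy$disease, noisy$gene),
                   paste(truth$disease, truth$gene))
  expect_gt(length(extra), 0)
})

test_that("synthetic bipartite networks honor their attachment models", {
  full <- generate_bipartite_network(3, 4, 12, attachment = "uniform", seed = 1)
  expect_equal(nrow(full$edges), 12L)  # complete bipartite at saturation
  a <- generate_bipartite_network(20, 20, 60, attachment = "preferential", seed = 4)
  b <- generate_bipartite_network(20, 20, 60, attachment = "preferential", seed = 4)
  expect_identical(a$edges, b$edges)
  hubby <- vapply(1:5, function(s) {
    net <- generate_bipartite_network(1000, 1000, 4000,
                                      attachment = "preferential", seed = s)
    deg <- table(c(net$edges$disease, net$edges$gene))
    max(deg) > 5 * median(deg)
  }, logical(1))
  expect_true(all(hubby))
})

test_that("the assignment solver matches exhaustive search", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    got <- solve_assignment(cost)
    ref <- brute_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), ref$cost, tolerance = 1e-12)
  }
  expect_equal(solve_assignment(matrix(5, 1, 1)), 1L)
})

test_that("topic matching recovers permutations and handles uniform rows", {
  pc <- generate_corpus(k = 4, n_diseases = 20, n_genes = 40, mean_doc_len = 20,
                        seed = 14)
  perm <- c(3, 1, 4, 2)
  shuffled <- pc$true_phi[perm, ]
  rownames(shuffled) <- rownames(pc$true_phi)
  m <- match_topics(pc$true_phi, shuffled)
  expect_equal(m$mean_cosine, 1, tolerance = 1e-12)
  expect_equal(order(perm), m$permutation)
  # uniform learned rows: mean cosine is the closed-form cosine with uniform
  C <- ncol(pc$true_phi)
  unif <- matrix(1 / C, 4, C, dimnames = dimnames(pc$true_phi))
  mu <- match_topics(pc$true_phi, unif)
  expected <- mean(vapply(1:4, function(k)
    sum(pc$true_phi[k, ]) / (sqrt(sum(pc$true_phi[k, ]^2)) * sqrt(C)),
    numeric(1)))
  expect_equal(mu$mean_cosine, expected, tolerance = 1e-12)
  # K = 3 random pair agrees with brute force over all 6 permutations
  set.seed(9)
  t3 <- matrix(rgamma(18, 1), 3); t3 <- t3 / rowSums(t3)
  l3 <- matrix(rgamma(18, 1), 3); l3 <- l3 / rowSums(l3)
  sim <- outer(1:3, 1:3, Vectorize(function(i, j) cosine_similarity(t3[i, ], l3[j, ])))
  ref <- brute_assignment(1 - sim)
  got <- match_topics(t3, l3)
  expect_equal(got$permutation, ref$perm)
  expect_error(match_topics(t3, l3[1:2, ]), "same number of topics")
})

test_that("demo input bundles are written in the formats the pipeline reads", {
  dir <- tempfile()
  inp <- write_demo_inputs(dir, k = 2, n_diseases = 15, n_genes = 30,
                           mean_doc_len = 15, seed = 4)
  expect_true(all(file.exists(unlist(inp[1:6]))))
  preds <- read_predications(inp$predications)
  expect_gt(nrow(preds), 0)
  symbols <- read_gene_symbols(inp$gene_symbols)
  assoc <- filter_associations(preds, symbols)
  expect_equal(nrow(assoc), sum(inp$planted$corpus$counts))
  dag <- read_ontology_tsv(inp$ontology)
  expect_gt(length(dag$terms), 0)
  col <- read_gmt(inp$gmt)
  expect_equal(length(col$sets), 2L)
})
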