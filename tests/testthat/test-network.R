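test_that("bipartite networks are simple, colored and validated", {
  net <- bipartite_network(data.frame(disease = c("d1", "d1", "d2"),
                                      gene = c("g1", "g1", "g1")))
  expect_equal(nrow(net$edges), 2L)  # duplicate collapsed
  expect_error(bipartite_network(data.frame(disease = "x", gene = "x")),
               "both disease and gene")
})

test_that("topic networks keep only member-to-member associations", {
  n_ck <- rbind(c(6, 6, 0), c(0, 0, 6))
  n_pk <- rbind(c(5, 0), c(5, 0), c(0, 6))
  m <- fake_model(n_ck, n_pk)
  assoc <- association_set(c("d1", "d2", "d1", "d1"),
                           c("g1", "g1", "g3", "g1"))
  net <- build_topic_network(m, 1, assoc)
  # topic 1 members: diseases d1,d2; genes g1,g2 -> g3 edge excluded,
  # duplicate d1-g1 collapsed
  expect_equal(sort(c(net$diseases, net$genes)), c("d1", "d2", "g1"))
  expect_equal(nrow(net$edges), 2L)
  expect_error(build_topic_network(m, 2, association_set("d9", "g9")),
               "empty topic network")
})

test_that("global properties match hand-computed path statistics", {
  path <- bipartite_network(data.frame(disease = c("D1", "D2"), gene = c("G1", "G1")))
  gp <- global_properties(path)
  expect_equal(gp$diameter, 2)
  expect_equal(gp$characteristic_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(gp$n_nodes, 3L)
  expect_false(gp$disconnected)

  star4 <- bipartite_network(data.frame(disease = paste0("D", 1:4), gene = "G1"))
  gp4 <- global_properties(star4)
  expect_equal(gp4$diameter, 2)
  # CPL: 4 spokes at 1, C(4,2)=6 disease pairs at 2 -> 16/10
  expect_equal(gp4$characteristic_path_length, 1.6, tolerance = 1e-12)

  # hub rule (degree > mean + 2 sd) on a 9-spoke star
  star9 <- bipartite_network(data.frame(disease = paste0("D", 1:9), gene = "G1"))
  expect_equal(global_properties(star9)$hubs$id, "G1")

  # double star: hand diameter 4 via the shared disease
  dstar <- bipartite_network(data.frame(
    disease = c("D1", "D2", "D3", "D3", "D4", "D5"),
    gene = c("G1", "G1", "G1", "G2", "G2", "G2")))
  gpd <- global_properties(dstar)
  expect_equal(gpd$diameter, 4)
  expect_lte(gpd$characteristic_path_length, gpd$diameter)

  # disconnected: largest component reported with a warning
  two <- bipartite_network(data.frame(disease = c("D1", "D2", "D2"),
                                      gene = c("G1", "G2", "G3")))
  expect_warning(gp2 <- global_properties(two), "disconnected")
  expect_equal(gp2$n_components, 2L)
  expect_equal(gp2$component_sizes[1], 3)
  expect_equal(gp2$diameter, 2)

  single <- bipartite_network(data.frame(disease = "D1", gene = "G1")[0, ],
                              diseases = "D1")
  gps <- global_properties(single)
  expect_equal(gps$diameter, 0)
  expect_true(is.na(gps$characteristic_path_length))
})

test_that("motif census matches the all-triples brute-force oracle", {
  path <- bipartite_network(data.frame(disease = c("D1", "D2"), gene = c("G1", "G1")))
  expect_equal(enumerate_motifs(path), c("D-G-D" = 1, "G-D-G" = 0))
  star <- bipartite_network(data.frame(disease = paste0("D", 1:4), gene = "G1"))
  expect_equal(enumerate_motifs(star)[["D-G-D"]], choose(4, 2))
  for (s in 1:50) {
    net <- random_net(seed = s, max_nodes = 25)
    counts <- enumerate_motifs(net)
    expect_equal(counts, brute_motifs(net), tolerance = 0,
                 label = sprintf("seed %d census", s))
    expect_equal(sum(counts), sum(brute_motifs(net)))
  }
})

test_that("randomization preserves degrees, colors and edge count exactly", {
  net <- generate_bipartite_network(15, 12, 40, attachment = "preferential",
                                    seed = 3)
  r1 <- randomize_network(net, seed = 7)
  r2 <- randomize_network(net, seed = 7)
  expect_identical(r1$edges, r2$edges)            # deterministic per seed
  expect_false(identical(r1$edges, net$edges))    # but actually shuffled
  deg <- function(n) list(
    d = sort(table(factor(n$edges$disease, levels = n$diseases))),
    g = sort(table(factor(n$edges$gene, levels = n$genes))))
  expect_equal(deg(r1), deg(net))
  expect_identical(r1$diseases, net$diseases)
  expect_identical(r1$genes, net$genes)
  expect_equal(nrow(r1$edges), nrow(net$edges))

  # two disjoint edges: the only legal swap crosses them
  two <- bipartite_network(data.frame(disease = c("D1", "D2"), gene = c("G1", "G2")))
  swapped <- FALSE
  for (s in 1:5) {
    r <- randomize_network(two, seed = s, swaps_per_edge = 50)
    keys <- sort(paste(r$edges$disease, r$edges$gene))
    expect_true(identical(keys, c("D1 G1", "D2 G2")) ||
                identical(keys, c("D1 G2", "D2 G1")))
    if (identical(keys, c("D1 G2", "D2 G1"))) swapped <- TRUE
  }
  expect_true(swapped)
  expect_error(randomize_network(bipartite_network(
    data.frame(disease = "D1", gene = "G1")), seed = 1), "at least 2 edges")
})

test_that("motif z-score and candidate filtering follow their definitions", {
  zs <- motif_zscore(10, c(2, 4, 6))  # mean 4, sd 2
  expect_equal(zs$z, 3)
  expect_equal(zs$rand_mean, 4)
  expect_equal(zs$rand_sd, 2)
  zz <- motif_zscore(5, c(4, 4, 4))
  expect_true(is.na(zz$z))
  expect_true(zz$sd_zero)

  # a path has one D-G-D occurrence: below min_count -> no candidates
  path <- bipartite_network(data.frame(disease = c("D1", "D2"), gene = c("G1", "G1")))
  ms <- motif_significance(path, n_random = 5, min_count = 5, seed = 1)
  expect_equal(nrow(ms), 0L)
})

test_that("bipartite 3-node counts are degree-determined under the null", {
  net <- generate_bipartite_network(12, 10, 30, attachment = "uniform", seed = 5)
  ms <- motif_significance(net, n_random = 20, min_count = 1, seed = 2)
  # degree-preserving swaps reproduce the real counts exactly
  expect_true(all(ms$rand_sd == 0))
  expect_true(all(is.na(ms$z)))
  expect_true(all(ms$p == 1))
  expect_equal(ms$rand_mean, ms$n_real)
})

test_that("degree-distribution fitting flags regular graphs and recovers exponents", {
  reg <- bipartite_network(data.frame(disease = paste0("D", 1:6),
                                      gene = paste0("G", 1:6)))
  expect_true(degree_distribution_fit(reg)$no_heavy_tail)

  # inverse-CDF discrete power-law sample, exponent 2.5
  set.seed(42)
  u <- runif(5000)
  degs <- floor(0.5 * (1 - u)^(-1 / 1.5) + 0.5)
  fit <- degree_distribution_fit(degs)
  expect_false(fit$no_heavy_tail)
  expect_equal(fit$exponent, 2.5, tolerance = 0.2)

  pref <- generate_bipartite_network(1000, 1000, 4000,
                                     attachment = "preferential", seed = 9)
  fit2 <- degree_distribution_fit(pref)
  expect_gte(fit2$exponent, 1.5)
  expect_lte(fit2$exponent, 3.5)
  expect_error(degree_distribution_fit(bipartite_network(
    data.frame(disease = "D1", gene = "G1"))), "at least 10 nodes")
})

test_that("edge lists round-trip through TSV", {
  net <- generate_bipartite_network(5, 4, 10, attachment = "uniform", seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(sort(paste(back$edges$disease, back$edges$gene)),
               sort(paste(net$edges$disease, net$edges$gene)))
})
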