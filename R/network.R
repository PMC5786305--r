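# Per-topic bipartite disease-gene networks: global properties, three-node
# motif counts, degree-preserving randomization, and motif significance.
#
# Networks are simple, undirected and two-colored (disease / gene); every
# edge joins a disease to a gene. Being triangle-free, their connected
# three-node induced subgraphs are exactly the two colored paths
# disease-gene-disease (centered on a gene) and gene-disease-gene (centered
# on a disease).

#' Construct a bipartite disease-gene network
#'
#' @param edges Data frame with columns `disease`, `gene`; duplicates are
#'   collapsed.
#' @param diseases,genes Optional node sets (isolated nodes allowed); default
#'   to the endpoints occurring in `edges`.
#' @return Object of class `bipartite_network`: `diseases`, `genes`
#'   (character vectors) and `edges` (unique two-column data frame).
#' @export
bipartite_network <- function(edges, diseases = NULL, genes = NULL) {
  stopifnot(all(c("disease", "gene") %in% names(edges)))
  edges <- unique(data.frame(disease = as.character(edges$disease),
                             gene = as.character(edges$gene),
                             stringsAsFactors = FALSE))
  diseases <- sort(unique(c(edges$disease, diseases)))
  genes <- sort(unique(c(edges$gene, genes)))
  overlap <- intersect(diseases, genes)
  if (length(overlap) > 0L)
    stop_bad("node ids used as both disease and gene: ",
             paste(head(overlap, 3L), collapse = ", "))
  rownames(edges) <- NULL
  structure(list(diseases = diseases, genes = genes, edges = edges),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d diseases, %d genes, %d edges\n",
              length(x$diseases), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Read / write a bipartite network edge list (disease TAB gene)
#'
#' @param path TSV path; header auto-detected when the first row reads
#'   `disease<TAB>gene`.
#' @param net Network to write.
#' @return `read_edge_list`: a `bipartite_network`.
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  hdr <- identical(tolower(trimws(strsplit(first, "\t")[[1]]))[1:2], c("disease", "gene"))
  df <- read.delim(path, header = hdr, colClasses = "character")
  names(df)[1:2] <- c("disease", "gene")
  bipartite_network(df)
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = c(net$diseases, net$genes),
                          type = c(rep(FALSE, length(net$diseases)),
                                   rep(TRUE, length(net$genes)))))
  g
}

#' Build the association network of one topic
#'
#' Nodes are the topic's member diseases and genes (per
#' [topic_memberships()]); edges are the supplied association pairs with
#' both endpoints in the node set, deduplicated.
#'
#' @param model A `topic_model`.
#' @param topic Topic index or name.
#' @param associations An `association_set` (columns `disease`, `gene`).
#' @param epsilon Membership threshold passed to [topic_memberships()].
#' @return A `bipartite_network`.
#' @export
build_topic_network <- function(model, topic, associations, epsilon = 1e-6) {
  stopifnot(inherits(model, "topic_model"))
  if (is.character(topic)) topic <- match(topic, rownames(model$n_ck))
  memb <- topic_memberships(model, epsilon = epsilon)
  if (is.na(topic) || topic < 1L || topic > length(memb))
    stop_bad("topic index out of range")
  dis <- memb[[topic]]$diseases$id
  gen <- memb[[topic]]$genes$id
  keep <- associations$disease %in% dis & associations$gene %in% gen
  edges <- unique(associations[keep, c("disease", "gene")])
  if (nrow(edges) == 0L) stop_bad("empty topic network")
  bipartite_network(edges)
}

#' Global properties of a bipartite network
#'
#' Diameter (max shortest-path length) and characteristic path length (mean
#' shortest-path length over unordered node pairs) are computed on the
#' largest connected component; a `disconnected` flag and component sizes are
#' reported when the network is not connected. Hubs are nodes whose degree
#' exceeds mean + 2 sd of the component's degrees, ranked descending.
#'
#' @param net A `bipartite_network`.
#' @return List: `n_nodes`, `n_edges`, `n_components`, `component_sizes`,
#'   `disconnected`, `diameter`, `characteristic_path_length` (`NA` for a
#'   single-node component), `degrees` (named, whole network), `hubs`
#'   (data frame id, degree).
#' @export
global_properties <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L) stop_bad("empty network")
  comps <- igraph::components(g)
  sizes <- sort(comps$csize, decreasing = TRUE)
  disconnected <- comps$no > 1L
  if (disconnected)
    warning("network is disconnected; path statistics use the largest component",
            call. = FALSE)
  big <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == big))
  if (igraph::vcount(sub) > 1L) {
    d <- igraph::distances(sub)
    vals <- d[upper.tri(d)]
    diameter <- max(vals)
    cpl <- mean(vals)
  } else {
    diameter <- 0
    cpl <- NA_real_
  }
  deg_all <- igraph::degree(g)
  deg_sub <- igraph::degree(sub)
  thr <- mean(deg_sub) + 2 * sd(deg_sub)
  hub_ids <- names(deg_sub)[!is.na(thr) & deg_sub > thr]
  hubs <- data.frame(id = hub_ids, degree = unname(deg_sub[hub_ids]),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$id), , drop = FALSE]
  rownames(hubs) <- NULL
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       n_components = comps$no,
       component_sizes = sizes,
       disconnected = disconnected,
       diameter = diameter,
       characteristic_path_length = cpl,
       degrees = deg_all,
       hubs = hubs)
}

#' Fit a discrete power law to the degree distribution
#'
#' Maximum-likelihood exponent with the lower cutoff `k_min` chosen by
#' Kolmogorov-Smirnov minimization (plfit); the KS distance at the chosen
#' cutoff is the goodness score. Degenerate degree sequences (all degrees
#' equal) are flagged as having no heavy tail.
#'
#' @param net A `bipartite_network` with at least 10 nodes, or a numeric
#'   vector of degrees.
#' @return List: `exponent`, `k_min`, `ks_distance`, `no_heavy_tail`.
#' @export
degree_distribution_fit <- function(net) {
  if (inherits(net, "bipartite_network")) {
    if (length(net$diseases) + length(net$genes) < 10L)
      stop_bad("need at least 10 nodes to fit a degree distribution")
    deg <- igraph::degree(as_igraph(net))
  } else {
    deg <- as.numeric(net)
  }
  deg <- deg[deg > 0]
  if (length(unique(deg)) <= 1L) {
    return(list(exponent = NA_real_, k_min = NA_real_,
                ks_distance = NA_real_, no_heavy_tail = TRUE))
  }
  fit <- igraph::fit_power_law(deg, implementation = "plfit")
  list(exponent = fit$alpha, k_min = fit$xmin,
       ks_distance = fit$KS.stat, no_heavy_tail = FALSE)
}

#' Count colored three-node motifs
#'
#' Exact counts of connected three-node induced subgraphs by colored
#' isomorphism class. A simple bipartite graph is triangle-free, so every
#' connected triple is a two-edge path through its center node: pattern
#' `D-G-D` for gene centers and `G-D-G` for disease centers; the counts are
#' the sums of choose(degree, 2) over centers of each color.
#'
#' @param net A `bipartite_network`.
#' @return Named numeric vector `c("D-G-D" = ..., "G-D-G" = ...)`.
#' @export
enumerate_motifs <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  deg_gene <- table(factor(net$edges$gene, levels = net$genes))
  deg_dis <- table(factor(net$edges$disease, levels = net$diseases))
  c("D-G-D" = sum(choose(as.numeric(deg_gene), 2)),
    "G-D-G" = sum(choose(as.numeric(deg_dis), 2)))
}

#' Degree-preserving randomization of a bipartite network
#'
#' Double-edge swaps within the bipartite constraint: a swap
#' (d1,g1),(d2,g2) -> (d1,g2),(d2,g1) is attempted `swaps_per_edge * |E|`
#' times and rejected whenever it would create a parallel edge. Node colors
#' and the full degree sequence are preserved exactly; deterministic per
#' seed.
#'
#' @param net A `bipartite_network` with >= 2 edges.
#' @param seed Integer seed.
#' @param swaps_per_edge Attempted swaps per edge (default 100).
#' @return A randomized `bipartite_network` with attribute
#'   `swap_rejections`.
#' @export
randomize_network <- function(net, seed, swaps_per_edge = 100L) {
  stopifnot(inherits(net, "bipartite_network"))
  E <- nrow(net$edges)
  if (E < 2L) stop_bad("need at least 2 edges to randomize")
  em <- cbind(match(net$edges$disease, net$diseases),
              match(net$edges$gene, net$genes))
  res <- bipartite_swap_cpp(em, as.integer(swaps_per_edge) * E, as.integer(seed))
  out <- bipartite_network(
    data.frame(disease = net$diseases[res$edges[, 1L]],
               gene = net$genes[res$edges[, 2L]],
               stringsAsFactors = FALSE),
    diseases = net$diseases, genes = net$genes)
  attr(out, "swap_rejections") <- res$rejected
  out
}

#' Motif z-score against randomized counts
#'
#' `z = (n_real - mean(rand_counts)) / sd(rand_counts)`; `NA` (flagged) when
#' the randomized counts have zero spread.
#'
#' @param n_real Observed motif count.
#' @param rand_counts Vector of counts from randomized networks.
#' @return List: `z`, `rand_mean`, `rand_sd`, `sd_zero` flag.
#' @export
motif_zscore <- function(n_real, rand_counts) {
  m <- mean(rand_counts)
  s <- sd(rand_counts)
  if (is.na(s) || s == 0) {
    list(z = NA_real_, rand_mean = m, rand_sd = if (is.na(s)) NA_real_ else 0,
         sd_zero = TRUE)
  } else {
    list(z = (n_real - m) / s, rand_mean = m, rand_sd = s, sd_zero = FALSE)
  }
}

#' Three-node motif significance
#'
#' Counts each colored three-node pattern in the real network and in
#' `n_random` degree-preserving randomizations. Patterns occurring fewer
#' than `min_count` times are excluded as candidates. The empirical p-value
#' is the fraction of randomized networks in which the pattern occurred at
#' least as often as in the real network; `z` follows [motif_zscore()].
#' Because three-node pattern counts in a simple bipartite graph are
#' functions of the degree sequence alone, a degree-preserving null
#' reproduces them exactly (`rand_sd` 0, `z` flagged `NA`, p 1); the
#' machinery is general and reports whatever the randomizations yield.
#'
#' @param net A `bipartite_network`.
#' @param n_random Number of randomized networks (default 1000).
#' @param min_count Candidate threshold on the real count (default 5).
#' @param alpha_p Significance cutoff on p (default 0.05).
#' @param seed Integer seed; randomization i uses `seed + i`.
#' @param swaps_per_edge Passed to [randomize_network()].
#' @return Data frame: `pattern`, `n_real`, `rand_mean`, `rand_sd`, `z`,
#'   `p`, `significant`, `n_random`.
#' @export
motif_significance <- function(net, n_random = 1000L, min_count = 5L,
                               alpha_p = 0.05, seed = 1L,
                               swaps_per_edge = 100L) {
  stopifnot(inherits(net, "bipartite_network"))
  real <- enumerate_motifs(net)
  candidates <- names(real)[real >= min_count]
  if (length(candidates) == 0L) {
    return(data.frame(pattern = character(), n_real = numeric(),
                      rand_mean = numeric(), rand_sd = numeric(),
                      z = numeric(), p = numeric(), significant = logical(),
                      n_random = integer()))
  }
  rand <- matrix(NA_real_, nrow = n_random, ncol = length(candidates),
                 dimnames = list(NULL, candidates))
  for (i in seq_len(n_random)) {
    rnet <- randomize_network(net, seed = seed + i,
                              swaps_per_edge = swaps_per_edge)
    rand[i, ] <- enumerate_motifs(rnet)[candidates]
  }
  rows <- lapply(candidates, function(pat) {
    zs <- motif_zscore(real[[pat]], rand[, pat])
    p <- mean(rand[, pat] >= real[[pat]])
    data.frame(pattern = pat, n_real = unname(real[[pat]]),
               rand_mean = zs$rand_mean, rand_sd = zs$rand_sd,
               z = zs$z, p = p, significant = p <= alpha_p,
               n_random = as.integer(n_random))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
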