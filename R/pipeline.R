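# End-to-end orchestration: filter -> corpus -> fit (optionally select K)
# -> topic metrics -> ontology evaluation -> networks + motifs -> enrichment,
# with a reproducible manifest (stage status, seeds, output checksums).

#' Assemble a pipeline configuration
#'
#' @param predications Path to the predication TSV.
#' @param gene_symbols Path to the approved-symbol list.
#' @param out_dir Output directory.
#' @param ontology,annotations Optional ontology edge TSV and disease
#'   annotation TSV; the ontology stage is skipped when absent.
#' @param gold Optional gold-standard association TSV (enables coverage
#'   statistics).
#' @param gmt Optional GMT collection; the enrichment stage is skipped when
#'   absent.
#' @param k Number of topics; when `NULL` and `k_grid` is given, selected by
#'   log-likelihood.
#' @param k_grid Optional grid for topic-number selection.
#' @param alpha,beta,iterations,algorithm LDA controls (see [lda_fit()]).
#' @param seed Master seed; every stochastic stage derives its seed from it
#'   and records it in the manifest.
#' @param folds,levels Ontology evaluation controls.
#' @param n_random,min_count,alpha_p Motif significance controls.
#' @param alpha_adj Enrichment cutoff.
#' @param top_topics How many top-ranked topics get network/ontology/
#'   enrichment treatment (default 3).
#' @param min_doc_tokens,dedupe Corpus construction controls.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(predications, gene_symbols, out_dir,
                            ontology = NULL, annotations = NULL,
                            gold = NULL, gmt = NULL,
                            k = 5L, k_grid = NULL,
                            alpha = 0.1, beta = 0.01, iterations = 200L,
                            algorithm = "cvb0", seed = 1L,
                            folds = 10L, levels = 3L,
                            n_random = 100L, min_count = 5L, alpha_p = 0.05,
                            alpha_adj = 0.01, top_topics = 3L,
                            min_doc_tokens = 1L, dedupe = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing per-stage artifacts under
#' `out_dir` and a `manifest.yaml` recording package version, seeds, stage
#' status and MD5 checksums of every artifact. Optional stages (ontology
#' evaluation, coverage, enrichment) are marked "skipped" in the manifest
#' when their inputs are absent. Reruns with the same configuration and
#' seeds reproduce identical checksums.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  unlink(log_path)
  manifest <- list(package_version = as.character(utils::packageVersion("genetopics")),
                   seed = config$seed, stages = list())
  artifacts <- function(paths) {
    sums <- tools::md5sum(paths)
    as.list(setNames(unname(sums), basename(paths)))
  }
  stage <- function(name, status, files = character(), extra = list()) {
    manifest$stages[[name]] <<- c(list(status = status),
                                  if (length(files) > 0L)
                                    list(artifacts = artifacts(files)),
                                  extra)
  }
  run_stage <- function(name, expr) {
    logf("stage ", name, ": start")
    tryCatch(expr, error = function(e) {
      stage(name, "failed", extra = list(error = conditionMessage(e)))
      yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
      stop_bad("stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # -- stage 1: filter ------------------------------------------------------
  assoc_path <- file.path(out, "associations.tsv")
  associations <- run_stage("filter", {
    preds <- read_predications(config$predications)
    symbols <- read_gene_symbols(config$gene_symbols)
    a <- filter_associations(preds, symbols)
    write.table(a, assoc_path, sep = "\t", quote = FALSE, row.names = FALSE)
    stage("filter", "ok", assoc_path,
          list(n_predications = nrow(preds), n_associations = nrow(a)))
    a
  })

  # -- stage 2: corpus ------------------------------------------------------
  corpus_dir <- file.path(out, "corpus")
  corpus <- run_stage("corpus", {
    cp <- build_corpus(associations, min_doc_tokens = config$min_doc_tokens,
                       dedupe = config$dedupe)
    write_corpus(cp, corpus_dir)
    stage("corpus", "ok",
          file.path(corpus_dir, c("documents.tsv", "vocabulary.tsv", "counts.tsv")),
          list(n_documents = nrow(cp$counts), n_vocabulary = ncol(cp$counts)))
    cp
  })

  # -- stage 3: fit (with optional K selection) -----------------------------
  model_dir <- file.path(out, "model")
  model <- run_stage("fit", {
    k <- config$k
    sel_extra <- list()
    if (!is.null(config$k_grid)) {
      sel <- select_topic_number(corpus, config$k_grid,
                                 iterations = config$iterations,
                                 seeds = config$seed + 0:2,
                                 alpha = config$alpha, beta = config$beta,
                                 algorithm = config$algorithm)
      k <- sel$best_k
      write.csv(sel$mean_scores, file.path(out, "k_selection.csv"),
                row.names = FALSE)
      sel_extra <- list(selected_k = k)
    }
    m <- lda_fit(corpus, k = k, alpha = config$alpha, beta = config$beta,
                 iterations = config$iterations, seed = config$seed,
                 algorithm = config$algorithm, store_assignments = FALSE)
    write_topic_model(m, model_dir)
    files <- file.path(model_dir, c("hyper.yaml", "n_ck.tsv", "n_pk.tsv", "trace.csv"))
    if (!is.null(config$k_grid)) files <- c(files, file.path(out, "k_selection.csv"))
    stage("fit", "ok", files,
          c(list(k = k, algorithm = config$algorithm,
                 final_log_likelihood = tail(m$trace$log_likelihood, 1L)),
            sel_extra))
    m
  })

  ranked <- rank_topics(model)
  topics <- head(ranked$topic, config$top_topics)
  memb <- topic_memberships(model)
  corpus_assoc <- association_set(
    rep(corpus$documents, times = ncol(corpus$counts))[corpus$counts > 0L],
    rep(corpus$vocabulary, each = nrow(corpus$counts))[corpus$counts > 0L])

  # -- stage 4: metrics -----------------------------------------------------
  run_stage("metrics", {
    files <- character()
    write.csv(ranked, file.path(out, "topic_ranking.csv"), row.names = FALSE)
    files <- c(files, file.path(out, "topic_ranking.csv"))
    for (lv in c("gene", "disease")) {
      ts <- topic_similarity_matrix(model, level = lv)
      mp <- file.path(out, sprintf("topic_similarity_%s.csv", lv))
      write.csv(ts$matrix, mp)
      hp <- file.path(out, sprintf("topic_similarity_%s_histogram.csv", lv))
      write.csv(data.frame(interval = names(ts$histogram),
                           count = ts$histogram), hp, row.names = FALSE)
      files <- c(files, mp, hp)
    }
    extra <- list()
    if (!is.null(config$gold)) {
      gold <- read_association_set(config$gold)
      cov <- vapply(topics, function(tp) {
        ti <- match(tp, rownames(model$n_ck))
        ta <- association_set(
          corpus_assoc$disease[corpus_assoc$disease %in% memb[[ti]]$diseases$id &
                               corpus_assoc$gene %in% memb[[ti]]$genes$id],
          corpus_assoc$gene[corpus_assoc$disease %in% memb[[ti]]$diseases$id &
                            corpus_assoc$gene %in% memb[[ti]]$genes$id])
        dgac(ta, gold)
      }, numeric(1))
      cov_path <- file.path(out, "dgac.csv")
      write.csv(data.frame(topic = topics, dgac = cov), cov_path,
                row.names = FALSE)
      files <- c(files, cov_path)
      extra <- list(mean_dgac = mean(cov))
    }
    stage("metrics", "ok", files, extra)
  })

  # -- stage 5: ontology evaluation ----------------------------------------
  if (is.null(config$ontology) || is.null(config$annotations)) {
    stage("ontology", "skipped",
          extra = list(reason = "no ontology/annotations configured"))
  } else {
    run_stage("ontology", {
      dag <- read_ontology_tsv(config$ontology)
      dag <- annotate_diseases(dag, read_annotations(config$annotations))
      rows <- list(); aucs <- numeric()
      for (tp in topics) {
        ti <- match(tp, rownames(model$n_ck))
        ranked_dis <- memb[[ti]]$diseases$id
        pr <- precision_recall(ranked_dis, dag, folds = config$folds,
                               levels = config$levels)
        pr$topic <- tp
        rows[[tp]] <- pr
        aucs[tp] <- tryCatch(pr_auc(pr), error = function(e) NA_real_)
      }
      pr_path <- file.path(out, "precision_recall.csv")
      write.csv(do.call(rbind, rows), pr_path, row.names = FALSE)
      auc_path <- file.path(out, "auc.csv")
      write.csv(data.frame(topic = names(aucs), auc = unname(aucs)),
                auc_path, row.names = FALSE)
      stage("ontology", "ok", c(pr_path, auc_path),
            list(mean_auc = mean(aucs, na.rm = TRUE)))
    })
  }

  # -- stage 6: networks + motifs ------------------------------------------
  run_stage("network", {
    files <- character(); props_rows <- list(); motif_rows <- list()
    for (tp in topics) {
      net <- build_topic_network(model, tp, corpus_assoc)
      ep <- file.path(out, sprintf("network_%s_edges.tsv", tp))
      write_edge_list(net, ep)
      gp <- suppressWarnings(global_properties(net))
      props_rows[[tp]] <- data.frame(
        topic = tp, n_nodes = gp$n_nodes, n_edges = gp$n_edges,
        diameter = gp$diameter,
        characteristic_path_length = gp$characteristic_path_length,
        n_hubs = nrow(gp$hubs))
      ms <- motif_significance(net, n_random = config$n_random,
                               min_count = config$min_count,
                               alpha_p = config$alpha_p,
                               seed = config$seed)
      if (nrow(ms) > 0L) { ms$topic <- tp; motif_rows[[tp]] <- ms }
      files <- c(files, ep)
    }
    pp <- file.path(out, "network_properties.csv")
    write.csv(do.call(rbind, props_rows), pp, row.names = FALSE)
    files <- c(files, pp)
    if (length(motif_rows) > 0L) {
      mp <- file.path(out, "motifs.csv")
      write.csv(do.call(rbind, motif_rows), mp, row.names = FALSE)
      files <- c(files, mp)
    }
    stage("network", "ok", files)
  })

  # -- stage 7: enrichment --------------------------------------------------
  if (is.null(config$gmt)) {
    stage("enrichment", "skipped", extra = list(reason = "no GMT configured"))
  } else {
    run_stage("enrichment", {
      col <- read_gmt(config$gmt)
      files <- character()
      for (tp in topics) {
        ti <- match(tp, rownames(model$n_ck))
        genes <- intersect(memb[[ti]]$genes$id, col$universe)
        if (length(genes) == 0L) next
        res <- suppressWarnings(enrich(genes, col, alpha_adj = config$alpha_adj))
        rp <- file.path(out, sprintf("enrichment_%s.csv", tp))
        write_enrichment_report(res, rp)
        files <- c(files, rp)
      }
      stage("enrichment", "ok", files)
    })
  }

  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  logf("pipeline complete: ", length(manifest$stages), " stages")
  invisible(manifest)
}
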