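test_that("estimate_phi and estimate_theta are the smoothed count ratios", {
  expect_equal(unname(estimate_phi(matrix(0, 1, 3), beta = 0.01)[1, ]),
               rep(1 / 3, 3))
  expect_equal(unname(estimate_phi(matrix(c(3, 1), 1), beta = 0.5)[1, ]),
               c(0.7, 0.3))
  expect_equal(unname(estimate_theta(matrix(0, 1, 2), alpha = 0.1)[1, ]),
               c(0.5, 0.5))
  expect_equal(unname(estimate_theta(matrix(c(4, 1), 1), alpha = 1)[1, ]),
               c(5 / 7, 2 / 7))
  expect_error(estimate_phi(matrix(-1, 1, 2), beta = 0.1), "non-negative")
  expect_error(estimate_theta(matrix(-1, 1, 2), alpha = 0.1), "non-negative")
  # row-stochastic for arbitrary non-negative input
  set.seed(1)
  m <- matrix(rgamma(50, 1), 5)
  expect_equal(rowSums(estimate_phi(m, 0.01)), rep(1, 5), tolerance = 1e-12)
  expect_equal(rowSums(estimate_theta(m, 0.1)), rep(1, 5), tolerance = 1e-12)
})

test_that("log-likelihood matches hand-evaluated gamma expressions", {
  # all-zero counts: complete cancellation
  expect_equal(lda_log_likelihood(matrix(0, 1, 2), beta = 1), 0)
  # one topic, two genes, one token each: log(1/6)
  expect_equal(lda_log_likelihood(matrix(c(1, 1), 1), beta = 1), -log(6),
               tolerance = 1e-12)
  # longer sequences are less probable under a single topic
  ll2 <- lda_log_likelihood(matrix(c(1, 1), 1), beta = 1)
  ll3a <- lda_log_likelihood(matrix(c(2, 1), 1), beta = 1)
  ll3b <- lda_log_likelihood(matrix(c(1, 2), 1), beta = 1)
  expect_lt(ll3a, ll2)
  expect_lt(ll3b, ll2)
})

test_that("fitting is deterministic and conserves token mass", {
  pc <- generate_corpus(k = 3, n_diseases = 30, n_genes = 40,
                        mean_doc_len = 20, seed = 5)
  total <- sum(pc$corpus$counts)
  for (alg in c("cvb0", "gibbs")) {
    f1 <- lda_fit(pc$corpus, k = 3, iterations = 50, seed = 9, algorithm = alg)
    f2 <- lda_fit(pc$corpus, k = 3, iterations = 50, seed = 9, algorithm = alg)
    expect_identical(f1$phi_hat, f2$phi_hat)
    expect_equal(sum(f1$n_ck), total, tolerance = 1e-8)
    expect_equal(sum(f1$n_pk), total, tolerance = 1e-8)
    expect_equal(rowSums(f1$phi_hat), setNames(rep(1, 3), rownames(f1$phi_hat)),
                 tolerance = 1e-9)
    expect_equal(rowSums(f1$theta_hat),
                 setNames(rep(1, nrow(f1$theta_hat)), rownames(f1$theta_hat)),
                 tolerance = 1e-9)
  }
  # different seeds give different initializations
  f3 <- lda_fit(pc$corpus, k = 3, iterations = 50, seed = 10)
  expect_false(identical(
    lda_fit(pc$corpus, k = 3, iterations = 50, seed = 9)$phi_hat, f3$phi_hat))
})

test_that("a single-document corpus still yields stochastic posteriors", {
  cp <- new_corpus(matrix(1L, 1, 1, dimnames = list("d1", "g1")))
  fit <- lda_fit(cp, k = 2, iterations = 10, seed = 1)
  expect_equal(sum(fit$theta_hat[1, ]), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$phi_hat), setNames(rep(1, 2), rownames(fit$phi_hat)),
               tolerance = 1e-9)
})

test_that("Gibbs log-likelihood improves from early to late iterations", {
  pc <- generate_corpus(k = 4, n_diseases = 60, n_genes = 50,
                        mean_doc_len = 25, seed = 21)
  fit <- lda_fit(pc$corpus, k = 4, iterations = 100, seed = 3,
                 algorithm = "gibbs", trace_every = 1)
  ll <- fit$trace$log_likelihood
  n <- length(ll)
  expect_gt(mean(ll[(n - n %/% 5 + 1):n]), mean(ll[1:(n %/% 5)]))
})

test_that("CVB0 recovers planted topics on a small corpus", {
  pc <- generate_corpus(k = 3, n_diseases = 60, n_genes = 50,
                        mean_doc_len = 25, seed = 33)
  fit <- lda_fit(pc$corpus, k = 3, iterations = 200, seed = 1)
  m <- match_topics(pc$true_phi, fit$phi_hat)
  expect_gte(m$mean_cosine, 0.85)
})

test_that("early stopping flags convergence without changing the contract", {
  pc <- generate_corpus(k = 3, n_diseases = 30, n_genes = 40,
                        mean_doc_len = 20, seed = 5)
  fit <- lda_fit(pc$corpus, k = 3, iterations = 2000, seed = 1,
                 early_stop = TRUE, trace_every = 5, patience = 5)
  expect_true(fit$trace$converged)
  expect_lt(max(fit$trace$iteration), 2000)
})

test_that("topic memberships threshold on expected counts with ordered output", {
  n_ck <- rbind(c(5, 0, 2), c(0, 3, 2))
  n_pk <- rbind(c(4, 0), c(0, 3), c(2, 2))
  m <- fake_model(n_ck, n_pk)
  memb <- topic_memberships(m, epsilon = 1e-6)
  expect_equal(memb[[1]]$genes$id, c("g1", "g3"))       # g2 only in topic 2
  expect_equal(memb[[2]]$genes$id, c("g2", "g3"))
  expect_equal(memb[[1]]$diseases$id, c("d1", "d3"))
  # probabilities are sorted descending
  expect_false(is.unsorted(rev(memb[[1]]$genes$probability)))
  # a threshold above every count empties all lists
  memb_hi <- topic_memberships(m, epsilon = 100)
  expect_equal(nrow(memb_hi[[1]]$genes), 0L)
  expect_equal(nrow(memb_hi[[2]]$diseases), 0L)
})

test_that("rank_topics normalizes topic masses", {
  m <- fake_model(rbind(c(2, 1), c(1, 0)), rbind(c(3, 1)))
  rk <- rank_topics(m)
  expect_equal(rk$probability, c(0.75, 0.25))
  expect_equal(rk$topic, c("topic1", "topic2"))
  expect_equal(sum(rk$probability), 1, tolerance = 1e-12)
  # equal masses: uniform, ordered by topic id
  m2 <- fake_model(rbind(c(1, 1), c(1, 1)), rbind(c(2, 2)))
  rk2 <- rank_topics(m2)
  expect_equal(rk2$probability, c(0.5, 0.5))
  expect_equal(rk2$topic, c("topic1", "topic2"))
})

test_that("topic-number selection has guarded preconditions", {
  pc <- generate_corpus(k = 2, n_diseases = 10, n_genes = 20,
                        mean_doc_len = 10, seed = 2)
  expect_error(select_topic_number(pc$corpus, k_grid = 5), "at least 2")
  expect_error(select_topic_number(pc$corpus, k_grid = c(5, 3)), "increasing")
})

test_that("a degenerate constant corpus selects the smallest K", {
  cp <- new_corpus(matrix(5L, 8, 1, dimnames = list(paste0("d", 1:8), "g1")))
  sel <- select_topic_number(cp, k_grid = c(2, 4), iterations = 30, seeds = 1)
  expect_equal(sel$best_k, 2L)
})

test_that("models round-trip through their plain-text serialization", {
  pc <- generate_corpus(k = 3, n_diseases = 20, n_genes = 30,
                        mean_doc_len = 15, seed = 8)
  fit <- lda_fit(pc$corpus, k = 3, iterations = 30, seed = 1)
  dir <- tempfile()
  write_topic_model(fit, dir)
  back <- read_topic_model(dir)
  expect_equal(back$n_ck, fit$n_ck, tolerance = 1e-6)
  expect_equal(back$hyper, fit$hyper)
  expect_equal(tail(back$trace$log_likelihood, 1),
               tail(fit$trace$log_likelihood, 1), tolerance = 1e-9)
})
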