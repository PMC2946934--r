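test_that("ks_boot: identical samples give D+ = 0 and p near 1", {
  x <- c(0.2, 0.4, 0.4, 0.9)
  res <- ks_boot(x, x, n_boot = 1000, seed = 1)
  expect_equal(res$statistic, 0)
  expect_gt(res$p.value, 0.95)
})

test_that("ks_boot detects a stochastically larger first sample", {
  set.seed(99)
  a <- runif(200, 0.3, 1.3)
  b <- runif(200, 0, 1)
  res <- ks_boot(a, b, n_boot = 1000, seed = 7)
  expect_lt(res$p.value, 0.01)
  # shifted the other way: one-sided test must not reject
  res_rev <- ks_boot(b, a, n_boot = 1000, seed = 7)
  expect_gt(res_rev$p.value, 0.5)
})

test_that("ks_boot p-values stay in (0, 1], are reproducible, and match a
           permutation oracle on small samples", {
  set.seed(5)
  a <- sample(seq(0, 1, 0.1), 30, replace = TRUE)  # heavy ties
  b <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
  r1 <- ks_boot(a, b, n_boot = 2000, seed = 3)
  r2 <- ks_boot(a, b, n_boot = 2000, seed = 3)
  expect_identical(r1$p.value, r2$p.value)
  expect_gt(r1$p.value, 0)
  expect_lte(r1$p.value, 1)

  # independent oracle: Monte Carlo permutation distribution of D+
  d_obs <- max(0, ecdf(b)(sort(unique(c(a, b)))) - ecdf(a)(sort(unique(c(a, b)))))
  set.seed(11)
  pooled <- c(a, b)
  d_perm <- replicate(4000, {
    idx <- sample(length(pooled))
    pa <- pooled[idx[1:30]]; pb <- pooled[idx[31:60]]
    grid <- sort(unique(pooled))
    max(0, ecdf(pb)(grid) - ecdf(pa)(grid))
  })
  p_perm <- mean(d_perm >= d_obs)
  expect_equal(r1$p.value, p_perm, tolerance = 0.08)
  expect_error(ks_boot(numeric(0), a), "non-empty")
  expect_error(ks_boot(a, b, n_boot = 10), "1000")
})

test_that("pyramid bins at 0.1 intervals and conserves totals", {
  h <- pyramid(c(0.55, 0.55), 0.35)
  expect_equal(h$disease[6], 2L)
  expect_equal(h$all[4], 1L)
  expect_equal(sum(h$disease), 2L)
  expect_equal(sum(h$all), 1L)
  expect_length(h$disease, 10L)
  # boundary values: 1.0 falls in the last bin, 0 in the first
  h2 <- pyramid(c(0, 1), c(0.1))
  expect_equal(h2$disease[c(1, 10)], c(1L, 1L))
  expect_equal(h2$all[2], 1L)
  expect_error(pyramid(numeric(0), 0.5), "empty")
  expect_error(pyramid(c(0.5, 1.2), 0.5), "\\[0, 1\\]")
})

test_that("hypergeom_sf matches exhaustive enumeration and its edge cases", {
  expect_equal(hypergeom_sf(10, 3, 5, 2), 0.5)
  expect_equal(hypergeom_sf(10, 3, 5, 0), 1)
  expect_equal(hypergeom_sf(10, 3, 5, 4), 0)
  expect_equal(hypergeom_sf(10, 3, 5, 1.2), hypergeom_sf(10, 3, 5, 2))
  expect_error(hypergeom_sf(10, 11, 5, 2), "invalid")
  set.seed(2)
  for (rep in 1:200) {
    N <- sample(30, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:(min(K, n) + 1), 1)
    expect_equal(hypergeom_sf(N, K, n, k), oracle_hyper_sf(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("cv_power uses the smallest-integer quantile and strict exceedance", {
  # N=100, K=8, n=20, alpha=0.01: q = smallest x with cdf >= 0.99
  q <- 0
  while (oracle_hyper_sf(100, 8, 20, q + 1) > 0.01) q <- q + 1
  expect_equal(cv_power(rep(8, 5), 100, 8, 20, 0.01), 1)
  expect_equal(cv_power(rep(0, 5), 100, 8, 20, 0.01), 0)
  expect_equal(cv_power(c(q, q + 1, q + 1, q), 100, 8, 20, 0.01), 0.5)
  expect_error(cv_power(1, 100, 8, 20, alpha = 0), "alpha")
})

test_that("cross_validate is reproducible, windowed, and errors on bad setups", {
  inst <- random_instance(31, n_terms = 40L, n_genes = 40L)
  pr <- inst$profiles
  dis <- pr[1:10]
  cand <- pr[11:40]
  cv1 <- cross_validate(cand, dis, inst$graph, inst$ic,
                        n_iter = 50, holdout = 3, windows = c(10L, 5L),
                        seed = 42)
  cv2 <- cross_validate(cand, dis, inst$graph, inst$ic,
                        n_iter = 50, holdout = 3, windows = c(10L, 5L),
                        seed = 42)
  expect_identical(cv1$counts, cv2$counts)
  expect_true(all(cv1$counts >= 0 & cv1$counts <= 3))
  expect_equal(cv1$N, 33)
  # substream stability: first 50 iterations unchanged when n_iter grows
  cv3 <- cross_validate(cand, dis, inst$graph, inst$ic,
                        n_iter = 80, holdout = 3, windows = c(10L, 5L),
                        seed = 42)
  expect_identical(cv3$counts[1:50, ], cv1$counts)
  expect_error(
    cross_validate(cand, dis, inst$graph, inst$ic, n_iter = 5,
                   holdout = 10, seed = 1),
    "holdout")
  expect_error(
    cross_validate(cand, dis, inst$graph, inst$ic, n_iter = 5,
                   holdout = 3, windows = 100L, seed = 1),
    "window")
})

test_that("cross_validate recovers an enriched module ranking (means above null)", {
  spec <- fixture_spec(n_terms = 60L, n_layers = 5L, n_genes = 120L,
                       module_size = 15L, seed = 8)
  graph <- random_dag(spec)
  cc <- clustered_corpus(graph, spec)
  ic <- information_content(term_probability(graph, cc$corpus))
  dis <- cc$corpus$direct[cc$disease_genes]
  cand <- cc$corpus$direct[setdiff(names(cc$corpus$direct), cc$disease_genes)]
  cv <- cross_validate(cand, dis, graph, ic, n_iter = 200, holdout = 5,
                       windows = c(20L, 10L), seed = 4)
  null_means <- cv$windows * cv$K / cv$N
  expect_true(all(cv$means > null_means))
  expect_true(all(cv$p_values < 0.05))
})

test_that("cross_validate is marginally calibrated over fresh exchangeable corpora", {
  # one hold-out draw per corpus, so gene-level profile idiosyncrasies are
  # integrated out; the counts must then follow the hypergeometric null
  set.seed(1)
  counts <- integer(150)
  for (r in seq_len(150)) {
    spec <- fixture_spec(n_terms = 60L, n_layers = 5L, n_genes = 120L,
                         module_size = 0L, seed = 50000 + r)
    graph <- random_dag(spec)
    cc <- clustered_corpus(graph, spec)
    genes <- names(cc$corpus$direct)
    dis <- cc$corpus$direct[genes[1:20]]
    cand <- cc$corpus$direct[genes[21:120]]
    ic <- information_content(term_probability(graph, cc$corpus))
    suppressMessages(
      cv <- cross_validate(cand, dis, graph, ic, n_iter = 1, holdout = 8,
                           windows = 8L, seed = 60000 + r))
    counts[r] <- cv$counts[1, 1]
  }
  probs <- c(stats::dhyper(0, 8, 100, 8), stats::dhyper(1, 8, 100, 8),
             stats::phyper(1, 8, 100, 8, lower.tail = FALSE))
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts >= 2))
  x2 <- sum((obs - 150 * probs)^2 / (150 * probs))
  expect_gt(stats::pchisq(x2, df = 2, lower.tail = FALSE), 0.01)
})
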