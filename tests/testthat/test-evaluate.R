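# Comparator scorers, AUC, the experiment drivers at reduced scale, and
# the rank-sum / BH utilities.

test_that("z-scoring reduces to the standardized column for one gene", {
  X <- random_sparse_matrix(50, 6, seed = 81)
  z1 <- zscore_scores(X, 3)
  expect_equal(z1, as.numeric(scale(X[, 3])))
  # scores are centered across cells
  s <- zscore_scores(X, 1:5)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  # loop oracle
  g <- 1:5
  oracle <- rep(0, nrow(X))
  for (j in g) {
    oracle <- oracle + (X[, j] - mean(X[, j])) / sd(X[, j])
  }
  oracle <- oracle / sqrt(length(g))
  expect_equal(s, unname(oracle), tolerance = 1e-12)
  Xc <- X
  Xc[, 1:5] <- 1
  expect_error(zscore_scores(Xc, 1:5), "zero standard deviation")
})

test_that("PCA scores recover rank-1 structure with a stable sign", {
  u <- c(5, 1, 4, 2, 3, 6, 1, 2, 4, 3)
  v <- c(2, 1, 3)
  X <- u %*% t(v)
  s <- pca_scores(X, 1:3)
  uc <- u - mean(u)
  expect_equal(abs(cor(s, uc)), 1, tolerance = 1e-10)
  # variance of scores equals the leading eigenvalue of the covariance
  Xr <- random_sparse_matrix(80, 8, seed = 82)
  sr <- pca_scores(Xr, 1:8)
  ev <- eigen(var(Xr[, 1:8]))$values[1]
  expect_equal(var(sr), ev, tolerance = 1e-8)
  # deterministic sign under repetition
  expect_identical(sr, pca_scores(Xr, 1:8))
  expect_error(pca_scores(matrix(1, 5, 3), 1:3), "degenerate")
})

test_that("rank AUC matches brute-force pair counting and edge cases", {
  labels <- c(1, 1, 0, 0, 0)
  expect_equal(score_auc(c(1, 1, 0, 0, 0), labels), 1)
  set.seed(83)
  scores <- c(rnorm(20), rnorm(30))
  labs <- rep(c(TRUE, FALSE), c(20, 30))
  # brute-force over all positive-negative pairs (ties count half)
  brute <- 0
  for (i in which(labs)) {
    for (j in which(!labs)) {
      brute <- brute + (scores[i] > scores[j]) +
        0.5 * (scores[i] == scores[j])
    }
  }
  expect_equal(score_auc(scores, labs), brute / (20 * 30))
  # chance level for label-independent scores
  expect_equal(score_auc(sample(labs), labs), 0.5, tolerance = 0.25)
  expect_error(score_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("type I error driver is calibrated at reduced scale", {
  cfg <- small_config()
  res <- type_one_error_experiment(cfg, n.datasets = 4, seed = 1)
  expect_identical(res$n.tests, 4L * cfg$n.cells)
  # 1200 null tests: 99% binomial band around 0.05
  half <- 2.576 * sqrt(0.05 * 0.95 / res$n.tests)
  expect_lt(abs(res$estimate - 0.05), half + 1e-9)
  # alpha = 1 rejects everything
  res1 <- type_one_error_experiment(cfg, n.datasets = 1, alpha = 1,
                                    seed = 1)
  expect_equal(res1$estimate, 1)
})

test_that("uniform p-values reject at the nominal rate (driver oracle)", {
  # the rejection-counting logic itself, checked against Uniform(0,1)
  set.seed(84)
  p <- runif(20000)
  est <- mean(p < 0.05)
  expect_lt(abs(est - 0.05), 2.576 * sqrt(0.05 * 0.95 / 20000))
})

test_that("power rises with the inflated mean and is null at the null mean", {
  cfg <- small_config()
  res <- power_experiment(cfg, inflated.means = c(0.642, 1.1, 1.7),
                          n.datasets = 3, seed = 2)
  expect_identical(nrow(res), 3L)
  expect_identical(res$n.tests, rep(3L * cfg$signal.cells, 3))
  # no effect size -> power near alpha
  expect_lt(abs(res$estimate[1] - 0.05), 0.08)
  # monotone nondecreasing within 2 SEM across the grid
  ses <- pmax(res$se, 1 / res$n.tests)
  expect_true(all(diff(res$estimate) >= -2 * (ses[-1] + ses[-3])))
  expect_gt(res$estimate[3], res$estimate[1])
})

test_that("AUC experiment ranks methods and sits at chance under no effect", {
  cfg <- small_config()
  res <- auc_experiment(cfg, inflated.mean = 1.4, n.datasets = 5,
                        seed = 3)
  expect_identical(res$method, c("vam", "zscore", "pca"))
  expect_true(all(res$estimate > 0.5))
  null_res <- auc_experiment(cfg, inflated.mean = cfg$nonzero.mean,
                             n.datasets = 6, seed = 4)
  expect_true(all(abs(null_res$estimate - 0.5) < 0.03 + 2 * null_res$se))
})

test_that("cluster enrichment matches rank-sum oracles and orders by p", {
  set.seed(85)
  S <- cbind(up = c(rnorm(30, 2), rnorm(70)),
             flat = rnorm(100))
  cl <- rep(c("A", "B"), c(30, 70))
  tab <- cluster_enrichment(S, cl)
  a <- tab[tab$cluster == "A", ]
  expect_identical(a$set[1], "up")  # sorted by p within cluster
  expect_lt(a$p.value[a$set == "up"], 1e-6)
  expect_gt(a$p.value[a$set == "flat"], 0.05)

  # statistic equals exhaustive pair counting on small groups
  s_small <- c(3.2, 1.1, 4.8, 2.2, 0.5, 3.9, 2.8, 1.7)
  cl_small <- rep(c("g1", "g2"), each = 4)
  t_small <- cluster_enrichment(cbind(s = s_small), cl_small)
  u_brute <- sum(outer(s_small[1:4], s_small[5:8], ">")) +
    0.5 * sum(outer(s_small[1:4], s_small[5:8], "=="))
  expect_equal(t_small$statistic[t_small$cluster == "g1"], u_brute)

  # all cluster scores above the rest achieves the extreme statistic
  s_ext <- c(10, 11, 12, 1, 2, 3, 4)
  t_ext <- cluster_enrichment(cbind(s = s_ext),
                              rep(c("hi", "lo"), c(3, 4)))
  expect_equal(t_ext$statistic[t_ext$cluster == "hi"], 12)  # 3 * 4 pairs

  # identical distributions give a near-1 p for the one-sided test
  set.seed(86)
  same <- cbind(s = rnorm(200))
  t_same <- cluster_enrichment(same, rep(c("A", "B"), 100))
  expect_true(all(t_same$p.value > 0.01))

  expect_warning(
    cluster_enrichment(cbind(s = rnorm(5)), c("A", "B", "B", "C", "C")),
    "skipped")
})

test_that("BH FDR agrees with a sort-based reference implementation", {
  bh_ref <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  set.seed(87)
  p <- runif(500)^2
  out <- bh_fdr(p, q = 0.1)
  expect_equal(out$q.values, bh_ref(p))
  expect_identical(out$significant, out$q.values <= 0.1)

  expect_true(bh_fdr(0.04, q = 0.05)$significant)
  expect_false(any(bh_fdr(rep(1, 10))$significant))
  # matrix input keeps its shape; family-wide vs per-column adjustment
  pm <- matrix(runif(40), 10, 4)
  fam <- bh_fdr(pm)
  expect_identical(dim(fam$q.values), dim(pm))
  per <- bh_fdr(pm, by = "set")
  expect_equal(per$q.values[, 2], bh_ref(pm[, 2]))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
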