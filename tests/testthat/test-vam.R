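# End-to-end scoring: the five-step pipeline, its provenance reporting,
# and the S3 methods of the fitted object.

test_that("scores are bounded and a fully zero cell scores exactly 0", {
  X <- simulate_null_matrix(small_config(), seed = 41)
  X[3, 1:25] <- 0  # cell 3 expresses no gene of the scored set
  fit <- vam(X, list(s = 1:25), seed = 41, min.nonzero.fit = 30)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  expect_true(all(fit$distances >= 0))
  expect_identical(unname(fit$scores[3, 1]), 0)
  expect_identical(unname(fit$pvalues[3, 1]), 1)
  # distance 0 iff all retained set genes are zero in that cell
  zero_cells <- rowSums(X[, fit$set.genes[[1]], drop = FALSE]) == 0
  expect_equal(unname(fit$distances[, 1] == 0), unname(zero_cells))
})

test_that("scaling up a cell's set genes never decreases its score", {
  X <- simulate_null_matrix(small_config(), seed = 42)
  tv <- tech_variances(X)  # held fixed so the null is shared
  fit1 <- vam(X, list(s = 1:25), tech.var = tv, seed = 7,
              min.nonzero.fit = 30)
  X2 <- X
  X2[5, 1:25] <- X2[5, 1:25] * 2
  fit2 <- vam(X2, list(s = 1:25), tech.var = tv, seed = 7,
              min.nonzero.fit = 30)
  expect_gte(fit2$distances[5, 1], fit1$distances[5, 1])
  # under either fitted null, the larger distance scores at least as high
  for (f in list(fit1, fit2)) {
    expect_gte(
      gamma_cdf_scores(fit2$distances[5, 1], f$gamma$shape, f$gamma$rate),
      gamma_cdf_scores(fit1$distances[5, 1], f$gamma$shape, f$gamma$rate))
  }
})

test_that("set resolution drops unmatched symbols and small sets with a report", {
  X <- random_sparse_matrix(60, 30, seed = 43)
  sets <- list(
    good = c("g1", "g2", "g3", "g4", "g5", "g6", "NOT_A_GENE"),
    tiny = c("g7", "g8"),
    ghost = c("NOPE1", "NOPE2", "NOPE3", "NOPE4", "NOPE5")
  )
  fit <- vam(X, sets, seed = 1, min.set.size = 5, min.nonzero.fit = 10)
  expect_identical(colnames(fit$scores), "good")
  expect_identical(sort(fit$skipped$set), c("ghost", "tiny"))
  expect_identical(fit$gamma$original_size, 7L)
  expect_identical(fit$gamma$n_unmatched, 1L)
  expect_identical(fit$gamma$g, 6L)
  # case-insensitive matching recovers differently-cased symbols
  fit_ci <- vam(X, list(s = paste0("G", 1:6)), seed = 1,
                min.set.size = 5, min.nonzero.fit = 10,
                case.insensitive = TRUE)
  expect_identical(fit_ci$gamma$g, 6L)
  expect_error(vam(X, list(ghost = sets$ghost), seed = 1),
               "no gene sets remain")
})

test_that("zero-variance genes are removed from sets before scoring", {
  X <- random_sparse_matrix(60, 20, seed = 44)
  X[, 3] <- 0
  fit <- vam(X, list(s = 1:10), seed = 2, min.set.size = 5,
             min.nonzero.fit = 10)
  expect_identical(fit$gamma$g, 9L)
  expect_false("g3" %in% fit$set.genes[[1]])
})

test_that("gamma fit provenance is recorded with fallback and failure", {
  X <- random_sparse_matrix(100, 40, sparsity = 0.5, seed = 45)
  fit <- vam(X, list(s = 1:10), seed = 3, min.nonzero.fit = 50)
  expect_identical(fit$gamma$fit_source, "permuted")

  # an impossible nonzero requirement forces failure, but the run
  # continues and the columns are NA
  warns <- capture_warnings(
    fit_bad <- vam(X, list(s = 1:10, ok = 11:20), seed = 3,
                   min.nonzero.fit = 1000))
  expect_match(warns, "scores set to NA", all = TRUE)
  expect_true(all(is.na(fit_bad$scores[, "s"])))
  expect_identical(fit_bad$gamma$fit_source[1], "failed")

  fit_direct <- vam(X, list(s = 1:10), seed = 3, min.nonzero.fit = 50,
                    fit.on.permuted = FALSE)
  expect_identical(fit_direct$gamma$fit_source, "unpermuted")
})

test_that("user-supplied technical variances bypass estimation", {
  X <- random_sparse_matrix(80, 20, seed = 46)
  tv <- rep(0.5, 20)
  fit <- vam(X, list(s = 1:8), tech.var = tv, seed = 4,
             min.nonzero.fit = 20)
  expect_equal(unname(fit$distances[, 1]),
               unname(rowSums(X[, 1:8]^2) / 0.5))
  expect_error(vam(X, list(s = 1:8), tech.var = tv[-1], seed = 4),
               "one entry per gene")
})

test_that("same seed gives identical results, different seeds differ", {
  X <- simulate_null_matrix(small_config(), seed = 47)
  f1 <- vam(X, list(s = 1:25), seed = 10, min.nonzero.fit = 30)
  f2 <- vam(X, list(s = 1:25), seed = 10, min.nonzero.fit = 30)
  f3 <- vam(X, list(s = 1:25), seed = 11, min.nonzero.fit = 30)
  expect_identical(f1$scores, f2$scores)
  expect_false(identical(f1$gamma$shape, f3$gamma$shape))
})

test_that("fitted object methods print, summarise, coef, plot and predict", {
  X <- simulate_null_matrix(small_config(), seed = 48)
  fit <- vam(X, list(a = 1:25, b = 26:50), seed = 5, min.nonzero.fit = 30)
  expect_output(print(fit), "2 set\\(s\\) scored")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.vam")
  expect_output(print(sm), "shape")
  cf <- coef(fit)
  expect_identical(dim(cf), c(2L, 2L))
  expect_true(all(cf > 0))
  pdf(NULL)
  expect_silent(plot(fit, set = "a"))
  dev.off()
  # predicting the training matrix reproduces the training scores
  pr <- predict(fit, X)
  expect_equal(pr, fit$scores)
  expect_error(predict(fit, X[, 1:30]), "lacks gene")
})

test_that("sparse and dense inputs give the same scores", {
  X <- random_sparse_matrix(120, 30, seed = 49)
  Xsp <- Matrix::Matrix(X, sparse = TRUE)
  # the direct (unpermuted) fit is RNG-free, so results must coincide
  fd <- vam(X, list(s = 1:12), min.nonzero.fit = 20,
            fit.on.permuted = FALSE)
  fs <- vam(Xsp, list(s = 1:12), min.nonzero.fit = 20,
            fit.on.permuted = FALSE)
  expect_equal(fd$distances, fs$distances, tolerance = 1e-12)
  expect_equal(fd$scores, fs$scores, tolerance = 1e-10)
  # with permutation, both representations stay calibrated even though
  # the permuted draws differ between storage formats
  fdp <- vam(X, list(s = 1:12), seed = 6, min.nonzero.fit = 20)
  fsp <- vam(Xsp, list(s = 1:12), seed = 6, min.nonzero.fit = 20)
  expect_equal(fdp$distances, fsp$distances, tolerance = 1e-12)
  expect_equal(fdp$scores, fsp$scores, tolerance = 0.05)
})
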