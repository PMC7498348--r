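# Validation experiments (type I error, power, classification AUC) and
# the rank-sum / FDR utilities used in downstream enrichment analyses.
# Each replicate derives its own seed from the master seed so runs are
# reproducible and replicates independent.

#' Type I error experiment under the simulation null
#'
#' Simulates `n.datasets` null matrices, scores one random gene set of
#' `config$signal.set.size` genes per dataset (sample variances as
#' technical variances), pools all cell-level p-values and reports the
#' rejection fraction at `alpha` with its binomial standard error. At
#' the defaults this pools 20,000 tests.
#'
#' @param config a [sim_config()] describing the null model.
#' @param n.datasets number of independent datasets.
#' @param alpha nominal significance level.
#' @param seed master seed; dataset `i` uses `seed + i`.
#' @param fit.on.permuted passed to [vam()].
#' @return One-row data frame: `metric`, `alpha`, `sparsity`,
#'   `estimate`, `se`, `n.tests`, `n.datasets`.
#' @export
type_one_error_experiment <- function(config = sim_config(),
                                      n.datasets = 10L, alpha = 0.05,
                                      seed = 1L,
                                      fit.on.permuted = TRUE) {
  pv <- unlist(lapply(seq_len(n.datasets), function(i) {
    with_seed(seed + i, {
      X <- simulate_null_matrix(config, seed = NULL)
      genes <- sample.int(config$n.genes, config$signal.set.size)
      fit <- vam(X, list(random_set = genes), seed = NULL,
                 fit.on.permuted = fit.on.permuted)
      fit$pvalues[, 1L]
    })
  }), use.names = FALSE)
  est <- mean(pv < alpha)
  data.frame(metric = "type1", alpha = alpha, sparsity = config$sparsity,
             estimate = est, se = sqrt(est * (1 - est) / length(pv)),
             n.tests = length(pv), n.datasets = n.datasets)
}

#' Power experiment across inflated signal means
#'
#' For each inflated mean, simulates `n.datasets` datasets in which a
#' random group of `config$signal.set.size` genes receives inflated
#' log-normal values in the first `config$signal.cells` cells, scores
#' that group with [vam()] and reports the fraction of signal-cell
#' p-values below `alpha` (500 hypothesis tests per level at the
#' defaults).
#'
#' @inheritParams type_one_error_experiment
#' @param inflated.means vector of target nonzero means for the signal
#'   block.
#' @return Data frame, one row per inflated mean: `metric`,
#'   `inflated.mean`, `estimate`, `se`, `n.tests`, `n.datasets`.
#' @export
power_experiment <- function(config = sim_config(),
                             inflated.means = seq(0.7, 1.7, by = 0.1),
                             n.datasets = 10L, alpha = 0.05, seed = 1L,
                             fit.on.permuted = TRUE) {
  rows <- lapply(seq_along(inflated.means), function(mi) {
    mu <- inflated.means[mi]
    pv <- unlist(lapply(seq_len(n.datasets), function(i) {
      with_seed(seed + 1000L * mi + i, {
        X <- simulate_null_matrix(config, seed = NULL)
        genes <- sample.int(config$n.genes, config$signal.set.size)
        X <- inject_signal(X, genes, seq_len(config$signal.cells), mu,
                           seed = NULL)
        fit <- vam(X, list(signal_set = genes), seed = NULL,
                   fit.on.permuted = fit.on.permuted)
        fit$pvalues[seq_len(config$signal.cells), 1L]
      })
    }), use.names = FALSE)
    est <- mean(pv < alpha)
    data.frame(metric = "power", inflated.mean = mu, alpha = alpha,
               estimate = est, se = sqrt(est * (1 - est) / length(pv)),
               n.tests = length(pv), n.datasets = n.datasets)
  })
  do.call(rbind, rows)
}

#' Z-scoring comparator
#'
#' The standardized-mean family of single-sample scores: each used gene
#' is z-scored across cells and a cell's score is the sum of its
#' z-scores over the set divided by `sqrt(g)`. Genes with zero standard
#' deviation across cells are dropped (they carry no ranking
#' information); if every set gene is constant the score is undefined
#' and an error is raised.
#'
#' @param X expression matrix, cells x genes.
#' @param genes set member indices or gene ids.
#' @return Numeric vector of length `nrow(X)`.
#' @export
zscore_scores <- function(X, genes) {
  validate_expression_matrix(X)
  idx <- resolve_gene_index(genes, X)
  Xk <- as.matrix(X[, idx, drop = FALSE])
  sds <- apply(Xk, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    stop("all set genes have zero standard deviation; z-score undefined",
         call. = FALSE)
  }
  Xk <- Xk[, keep, drop = FALSE]
  z <- scale(Xk)
  as.numeric(rowSums(z)) / sqrt(ncol(Xk))
}

#' PCA comparator
#'
#' The first-principal-component family of single-sample scores: the
#' projection of each cell onto the first PC of the centered set
#' submatrix. The sign is fixed so the largest-magnitude loading is
#' positive, making repeated runs deterministic.
#'
#' @inheritParams zscore_scores
#' @return Numeric vector of length `nrow(X)`.
#' @export
pca_scores <- function(X, genes) {
  validate_expression_matrix(X)
  idx <- resolve_gene_index(genes, X)
  if (length(idx) < 2L) stop("PCA scores need at least 2 genes",
                             call. = FALSE)
  Xk <- as.matrix(X[, idx, drop = FALSE])
  Xc <- scale(Xk, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < .Machine$double.eps * 100)) {
    stop("degenerate set submatrix: no variance for PCA", call. = FALSE)
  }
  sv <- svd(Xc, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  if (v[which.max(abs(v))] < 0) v <- -v
  as.numeric(Xc %*% v)
}

#' Rank-based AUC of scores against binary labels
#'
#' Area under the ROC curve computed by the Mann-Whitney rank formula
#' with midranks for ties: the probability that a randomly chosen
#' positive cell outranks a randomly chosen negative one (ties counted
#' half).
#'
#' @param scores numeric score per cell (higher = more positive).
#' @param labels logical or 0/1 vector; `TRUE` marks signal cells.
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("'scores' and 'labels' must have equal length", call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification experiment: VAM versus comparator scorers
#'
#' Simulates `n.datasets` datasets with an injected signal block (a
#' random gene group inflated to `inflated.mean` in the first
#' `config$signal.cells` cells), scores the signal set with each
#' requested method and measures how well the scores rank signal cells
#' above the rest via [score_auc()]. Reports the mean AUC and its
#' standard error across datasets per method.
#'
#' @inheritParams type_one_error_experiment
#' @param inflated.mean target nonzero mean of the signal block.
#' @param methods subset of `c("vam", "zscore", "pca")`.
#' @return Data frame, one row per method: `method`, `estimate` (mean
#'   AUC), `se` (SEM across datasets), `n.datasets`, `inflated.mean`,
#'   `sparsity`.
#' @export
auc_experiment <- function(config = sim_config(), inflated.mean = 1.2,
                           methods = c("vam", "zscore", "pca"),
                           n.datasets = 50L, seed = 1L,
                           fit.on.permuted = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  aucs <- matrix(NA_real_, n.datasets, length(methods),
                 dimnames = list(NULL, methods))
  for (i in seq_len(n.datasets)) {
    aucs[i, ] <- with_seed(seed + i, {
      X <- simulate_null_matrix(config, seed = NULL)
      genes <- sample.int(config$n.genes, config$signal.set.size)
      X <- inject_signal(X, genes, seq_len(config$signal.cells),
                         inflated.mean, seed = NULL)
      labels <- seq_len(nrow(X)) <= config$signal.cells
      vapply(methods, function(mth) {
        s <- switch(mth,
          vam = vam(X, list(signal_set = genes), seed = NULL,
                    fit.on.permuted = fit.on.permuted)$scores[, 1L],
          zscore = zscore_scores(X, genes),
          pca = pca_scores(X, genes))
        score_auc(s, labels)
      }, numeric(1))
    })
  }
  data.frame(method = methods,
             estimate = colMeans(aucs),
             se = apply(aucs, 2L, stats::sd) / sqrt(n.datasets),
             n.datasets = n.datasets, inflated.mean = inflated.mean,
             sparsity = config$sparsity, row.names = NULL)
}

#' Cluster-level enrichment of gene set scores
#'
#' For each cluster, tests every set's cell-specific scores one cluster
#' versus all other cells with a Wilcoxon rank-sum test (normal
#' approximation with continuity and tie correction, appropriate for
#' group sizes in the thousands). The table is ordered by p-value
#' within each cluster, and a Benjamini-Hochberg FDR over the whole
#' table is appended.
#'
#' @param scores a fitted [vam()] object or a cells x sets score
#'   matrix.
#' @param clusters factor-like cluster label per cell.
#' @param alternative `"greater"` (default) tests for elevated scores
#'   in the cluster, matching the usual up-regulation question.
#' @return Data frame with `cluster`, `set`, `statistic` (Mann-Whitney
#'   U of cluster vs rest), `p.value` and `fdr`.
#' @export
cluster_enrichment <- function(scores, clusters,
                               alternative = c("greater", "two.sided",
                                               "less")) {
  alternative <- match.arg(alternative)
  if (inherits(scores, "vam")) scores <- scores$scores
  scores <- as.matrix(scores)
  clusters <- as.factor(clusters)
  if (length(clusters) != nrow(scores)) {
    stop("'clusters' must have one label per cell (row of scores)",
         call. = FALSE)
  }
  rows <- list()
  for (lv in levels(clusters)) {
    inc <- clusters == lv
    if (sum(inc) < 2L || sum(!inc) < 2L) {
      warning("cluster '", lv, "' skipped: fewer than 2 cells on one ",
              "side of the comparison", call. = FALSE)
      next
    }
    stat <- pval <- rep(NA_real_, ncol(scores))
    for (j in seq_len(ncol(scores))) {
      s <- scores[, j]
      if (anyNA(s)) next  # failed-fit set
      wt <- stats::wilcox.test(s[inc], s[!inc],
                               alternative = alternative,
                               exact = FALSE, correct = TRUE)
      stat[j] <- unname(wt$statistic)
      pval[j] <- wt$p.value
    }
    df <- data.frame(cluster = lv,
                     set = colnames(scores) %||%
                       paste0("set_", seq_len(ncol(scores))),
                     statistic = stat, p.value = pval,
                     stringsAsFactors = FALSE)
    rows[[lv]] <- df[order(df$p.value), ]
  }
  if (!length(rows)) {
    stop("no cluster had enough cells for a comparison", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- stats::p.adjust(out$p.value, method = "BH")
  out
}

#' Benjamini-Hochberg FDR over a family of p-values
#'
#' Step-up BH adjustment with significance flags at level `q`. By
#' default the whole input (e.g. the full cells x sets p-value matrix)
#' is treated as one family; `by = "set"` adjusts each column
#' separately.
#'
#' @param pvals numeric vector or matrix of p-values in `[0, 1]`.
#' @param q FDR level for the flags (default 0.1).
#' @param by `"family"` (default) or `"set"` for per-column adjustment
#'   of a matrix.
#' @return List with `q.values` and logical `significant`, shaped like
#'   the input.
#' @export
bh_fdr <- function(pvals, q = 0.1, by = c("family", "set")) {
  by <- match.arg(by)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  qv <- pvals
  if (by == "set" && is.matrix(pvals)) {
    for (j in seq_len(ncol(pvals))) {
      qv[, j] <- stats::p.adjust(pvals[, j], method = "BH")
    }
  } else {
    qv[] <- stats::p.adjust(as.vector(pvals), method = "BH")
  }
  list(q.values = qv, significant = qv <= q, q = q)
}
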