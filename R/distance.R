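#' Per-gene technical variance estimates
#'
#' Estimates the technical component of each gene's variance by the
#' per-gene sample variance (denominator `n - 1`) computed over all cells,
#' zeros included. This is the default used when the observed marginal
#' variance of a gene is assumed to be entirely technical; pipelines that
#' decompose variance into technical and biological components (e.g.
#' regularised negative-binomial normalization) can supply their own
#' vector to [vam()] instead.
#'
#' @param X numeric matrix or sparse `Matrix`, cells in rows and genes in
#'   columns, holding nonnegative normalized expression.
#' @return Named numeric vector of length `ncol(X)` with one nonnegative
#'   variance per gene.
#' @examples
#' X <- matrix(c(0, 0, 2, 2, 1, 1, 1, 1), nrow = 4)
#' tech_variances(X)  # gene 1: var(c(0,0,2,2)) = 4/3; gene 2: 0
#' @export
tech_variances <- function(X) {
  validate_expression_matrix(X)
  if (nrow(X) < 2L) {
    stop("insufficient cells for variance estimation (need n >= 2)",
         call. = FALSE)
  }
  v <- col_vars(X)
  names(v) <- gene_ids(X)
  v
}

#' Squared variance-adjusted Mahalanobis distance from the origin
#'
#' For gene set `k` with member columns `X_k` and technical variances
#' `sigma^2_j`, computes per cell `c` the diagonal-weighted squared
#' distance from the origin
#' \deqn{M_{c,k} = \sum_{j \in k} x_{c,j}^2 / \hat\sigma^2_j.}
#' Unlike the standard Mahalanobis distance this uses only the technical
#' variance of each gene (covariances are ignored, so deviations along
#' directions of biological covariation are not discounted) and measures
#' distance from the origin rather than the multivariate mean, so a
#' distance of 0 means no expression of any set gene and larger distances
#' always mean elevated coordinated expression.
#'
#' @param X expression matrix, cells x genes (dense or sparse).
#' @param genes integer indices or character gene ids selecting the set's
#'   member columns of `X`.
#' @param tech.var technical variances: either a full length-`ncol(X)`
#'   vector (subset internally) or a vector aligned with `genes`. All
#'   variances used must be strictly positive; remove zero-variance genes
#'   first (see [vam()], which does this filtering).
#' @return Named numeric vector of length `nrow(X)` of squared distances.
#' @seealso [standard_mahalanobis()] for the classical definition this
#'   modifies.
#' @examples
#' X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
#' modified_mahalanobis(X, 1:2, c(1, 1))  # 0, 4, 4, 8
#' @export
modified_mahalanobis <- function(X, genes, tech.var) {
  validate_expression_matrix(X)
  idx <- resolve_gene_index(genes, X)
  if (length(idx) == 0L) {
    stop("empty gene set: no genes left to score", call. = FALSE)
  }
  tv <- tech.var
  if (length(tv) == ncol(X)) {
    tv <- tv[idx]
  } else if (length(tv) != length(idx)) {
    stop("'tech.var' must have length ncol(X) or length(genes)",
         call. = FALSE)
  }
  if (anyNA(tv) || any(tv < 0)) {
    stop("technical variances must be nonnegative and non-missing",
         call. = FALSE)
  }
  if (any(tv == 0)) {
    bad <- gene_ids(X)[idx][tv == 0]
    stop("zero technical variance for gene(s) ",
         paste(head(bad, 5L), collapse = ", "),
         "; remove zero-variance genes before computing distances",
         call. = FALSE)
  }
  Xk <- X[, idx, drop = FALSE]
  d <- as.numeric((Xk * Xk) %*% (1 / tv))
  names(d) <- cell_ids(X)
  d
}

#' Standard squared Mahalanobis distance (comparison utility)
#'
#' The classical squared Mahalanobis distance
#' \eqn{(x - \bar x)^T \hat\Sigma^{-1} (x - \bar x)} of each cell from the
#' multivariate mean, using the full sample covariance. Provided purely as
#' a comparison/oracle utility to contrast with
#' [modified_mahalanobis()] -- it is never part of the scoring path.
#'
#' @param X numeric matrix (cells x genes) for one gene set.
#' @param center reference point; defaults to the column means.
#' @param cov covariance matrix; defaults to the sample covariance of `X`.
#' @return Numeric vector of squared distances, one per row of `X`.
#' @examples
#' X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
#' standard_mahalanobis(X, center = c(1, 1), cov = diag(2))  # all 2
#' @export
standard_mahalanobis <- function(X, center = NULL, cov = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("need at least one gene column", call. = FALSE)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(cov)) cov <- stats::var(X)
  d <- tryCatch(
    stats::mahalanobis(X, center = center, cov = cov),
    error = function(e) {
      stop("covariance matrix is singular or invalid for this ",
           ncol(X), "-gene set: ", conditionMessage(e), call. = FALSE)
    }
  )
  names(d) <- cell_ids(X)
  d
}

#' Permute each gene column independently
#'
#' Returns a copy of `X` in which the cell labels of every gene column
#' have been independently and uniformly permuted. This breaks any
#' across-gene correlation while preserving each gene's marginal value
#' multiset exactly, which is what the null of uncorrelated technical
#' noise requires; distances computed on the permuted matrix provide the
#' sample to which the gamma null is fitted.
#'
#' @param X expression matrix, cells x genes (dense or sparse).
#' @param seed integer seed for reproducibility, or `NULL` to draw from
#'   the current RNG stream.
#' @return A matrix of the same class and dimensions as `X`.
#' @export
permute_columns <- function(X, seed = NULL) {
  validate_expression_matrix(X)
  n <- nrow(X)
  with_seed(seed, {
    if (n <= 1L) return(X)
    if (is_sparse(X)) {
      Xc <- as(X, "CsparseMatrix")
      p <- Xc@p
      new_i <- integer(length(Xc@i))
      new_x <- numeric(length(Xc@x))
      for (j in seq_len(ncol(Xc))) {
        r <- if (p[j + 1L] > p[j]) (p[j] + 1L):p[j + 1L] else integer(0)
        if (!length(r)) next
        # a uniformly random injection of the column's nonzeros into rows
        pos <- sample.int(n, length(r))
        o <- order(pos)
        new_i[r] <- pos[o] - 1L
        new_x[r] <- Xc@x[r][o]
      }
      out <- Xc
      out@i <- new_i
      out@x <- new_x
      out
    } else {
      out <- X
      for (j in seq_len(ncol(X))) out[, j] <- X[sample.int(n), j]
      out
    }
  })
}

#' Non-central chi-square approximation for null distances
#'
#' Under multivariate normality, squared distances from the origin with
#' diagonal weights are classically approximated by a non-central
#' chi-square with `g` degrees of freedom and non-centrality
#' \eqn{\sum_j \bar x_j^2 / \hat\sigma^2_j}. This approximation breaks
#' down on sparse expression data (it badly underestimates the spread of
#' the distances once half or more of the entries are zero), which is why
#' scoring uses a fitted gamma null instead; the function exists so the
#' two nulls can be compared.
#'
#' @inheritParams modified_mahalanobis
#' @param tech.var optional; defaults to [tech_variances()] of `X`.
#' @return List with `df` (set size used) and `ncp`.
#' @export
noncentral_chisq_params <- function(X, genes, tech.var = NULL) {
  validate_expression_matrix(X)
  idx <- resolve_gene_index(genes, X)
  tv <- tech.var %||% tech_variances(X)
  if (length(tv) == ncol(X)) tv <- tv[idx]
  if (any(tv <= 0)) {
    stop("all technical variances must be positive", call. = FALSE)
  }
  mu <- colMeans(X[, idx, drop = FALSE])
  list(df = length(idx), ncp = sum(mu^2 / tv))
}

# Map integer or character gene selectors to validated column indices.
resolve_gene_index <- function(genes, X, arg = "genes") {
  p <- ncol(X)
  if (is.character(genes)) {
    ids <- colnames(X)
    if (is.null(ids)) {
      stop("'", arg, "' given as gene ids but the matrix has no column ",
           "names", call. = FALSE)
    }
    idx <- match(genes, ids)
    if (anyNA(idx)) {
      stop("gene id(s) not found in matrix: ",
           paste(head(genes[is.na(idx)], 5L), collapse = ", "),
           call. = FALSE)
    }
  } else {
    idx <- as.integer(genes)
    if (anyNA(idx) || any(idx < 1L) || any(idx > p)) {
      stop("'", arg, "' indices must lie in [1, ", p, "]", call. = FALSE)
    }
  }
  if (anyDuplicated(idx)) {
    stop("'", arg, "' contains duplicate genes", call. = FALSE)
  }
  idx
}
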