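# Internal helpers shared across modules.

is_sparse <- function(x) methods::is(x, "sparseMatrix")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current stream" so that
# experiment drivers can derive all randomness from one master seed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation so state can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Validate a cells x genes expression matrix. Normalized scRNA-seq
# matrices encode absence as 0, so missing values are rejected outright
# rather than imputed.
validate_expression_matrix <- function(X, min.cells = 1L,
                                       arg = deparse(substitute(X))) {
  if (!(is.matrix(X) && is.numeric(X)) && !is_sparse(X)) {
    stop("'", arg, "' must be a numeric matrix or sparse Matrix ",
         "(cells x genes)", call. = FALSE)
  }
  if (nrow(X) < min.cells) {
    stop("'", arg, "' must have at least ", min.cells, " cell(s)",
         call. = FALSE)
  }
  vals <- if (is_sparse(X)) X@x else X
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("'", arg, "' contains missing or non-finite values; normalized ",
         "expression matrices must encode absence as 0", call. = FALSE)
  }
  if (length(vals) && min(vals) < 0) {
    stop("'", arg, "' contains negative values; normalized expression ",
         "must be nonnegative", call. = FALSE)
  }
  ids <- colnames(X)
  if (!is.null(ids) && anyDuplicated(ids)) {
    stop("duplicate gene ids in '", arg, "': ",
         paste(head(unique(ids[duplicated(ids)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(X)
}

# Per-gene sample variances (denominator n - 1), computed over all cells
# including zeros. Dense input uses a two-pass formula; sparse input uses
# the sum-of-squares identity (safe here because nonnegative sparse data
# never has a mean close to its root-mean-square).
col_vars <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  if (is_sparse(X)) {
    ss <- colSums(X * X)
    v <- (ss - n * mu^2) / (n - 1)
    v <- pmax(v, 0)
  } else {
    cent <- X - rep(mu, each = n)
    v <- colSums(cent * cent) / (n - 1)
  }
  names(v) <- colnames(X)
  v
}

cell_ids <- function(X) rownames(X) %||% paste0("cell_", seq_len(nrow(X)))
gene_ids <- function(X) colnames(X) %||% paste0("gene_", seq_len(ncol(X)))
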