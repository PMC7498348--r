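#' Read a Matrix Market expression bundle
#'
#' Reads a sparse expression matrix in Matrix Market coordinate format
#' together with its gene and barcode sidecar files (one id per line,
#' first tab-separated field used). Orientation is auto-detected: a
#' genes x cells file (the common exchange convention) is transposed so
#' the result is always cells x genes. A square matrix is treated as
#' genes x cells.
#'
#' @param mtx.path path to the `.mtx` coordinate file.
#' @param genes.path path to the gene id sidecar (one gene per line).
#' @param barcodes.path path to the cell barcode sidecar.
#' @return A `dgCMatrix` with barcodes as row names and gene ids as
#'   column names.
#' @export
read_mtx_bundle <- function(mtx.path, genes.path, barcodes.path) {
  for (p in c(mtx.path, genes.path, barcodes.path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- tryCatch(
    Matrix::readMM(mtx.path),
    error = function(e) stop("malformed Matrix Market file '", mtx.path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  genes <- read_id_column(genes.path)
  barcodes <- read_id_column(barcodes.path)
  if (length(m@x) && min(m@x) < 0) {
    stop("negative entries in '", mtx.path, "'", call. = FALSE)
  }
  ng <- length(genes)
  nb <- length(barcodes)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    stop("dimension/id mismatch for '", mtx.path, "': matrix is ",
         nrow(m), " x ", ncol(m), " but sidecars list ", ng,
         " genes and ", nb, " barcodes", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids in '", genes.path, "'", call. = FALSE)
  }
  dimnames(m) <- list(barcodes, genes)
  as(m, "CsparseMatrix")
}

#' Write a Matrix Market expression bundle
#'
#' Inverse of [read_mtx_bundle()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` into `dir` using the genes x cells exchange convention.
#'
#' @param X cells x genes matrix with cell and gene ids as dimnames.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_mtx_bundle <- function(X, dir) {
  validate_expression_matrix(X)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  Xs <- if (is_sparse(X)) X else Matrix::Matrix(X, sparse = TRUE)
  Matrix::writeMM(Matrix::t(Xs), paths[1L])
  writeLines(gene_ids(X), paths[2L])
  writeLines(cell_ids(X), paths[3L])
  invisible(paths)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Read a dense expression matrix from TSV
#'
#' Dialect: first column holds cell ids, header row holds gene ids.
#'
#' @param path path to the tab-separated file.
#' @return Numeric matrix, cells x genes.
#' @export
read_dense_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("non-numeric values in '", path, "'", call. = FALSE)
  }
  validate_expression_matrix(m, arg = path)
  m
}

#' Read a GMT gene set collection
#'
#' Parses the tab-separated MSigDB GMT dialect: each line is a set name,
#' a description, then gene symbols. Duplicate symbols within a set are
#' removed (order preserved) with a single summary warning; lines with
#' fewer than three fields are an error reported with the line number.
#'
#' @param path path to the `.gmt` file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(gene_set_collection(list(), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("malformed GMT line ", short[1L], " in '", path,
         "': fewer than 3 tab-separated fields", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (any(!nzchar(nm))) {
    stop("empty set name at GMT line ", which(!nzchar(nm))[1L],
         call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s) in '", path, "': ",
         paste(head(unique(nm[duplicated(nm)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  raw <- lapply(fields, function(f) f[-(1:2)])
  sets <- lapply(raw, unique)
  ndup <- sum(lengths(raw) - lengths(sets))
  if (ndup > 0) {
    warning(ndup, " duplicate gene symbol(s) removed across ",
            length(sets), " set(s)", call. = FALSE)
  }
  names(sets) <- nm
  gene_set_collection(sets, setNames(desc, nm))
}

gene_set_collection <- function(sets, descriptions = NULL) {
  structure(
    list(sets = sets,
         descriptions = descriptions %||%
           setNames(rep("", length(sets)), names(sets))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  m <- length(x$sets)
  cat("Gene set collection:", m, "set(s)\n")
  if (m) {
    sz <- lengths(x$sets)
    cat("  set sizes: min", min(sz), "/ median", stats::median(sz),
        "/ max", max(sz), "\n")
    cat("  ", paste(head(names(x$sets), 5L), collapse = ", "),
        if (m > 5L) "..." else "", "\n")
  }
  invisible(x)
}

#' Resolve a gene set collection against a matrix's genes
#'
#' Intersects each set with the matrix gene ids by exact string match
#' (optionally case-insensitive), dropping and counting unmatched
#' symbols, and discards sets whose resolved size falls below
#' `min.set.size`.
#'
#' @param sets a `gene_set_collection` from [read_gmt()], or a named list
#'   of character gene-id vectors or integer column indices.
#' @param gene.ids character vector of matrix gene ids (column names).
#' @param min.set.size smallest resolved set retained (default 5).
#' @param case.insensitive match symbols case-insensitively. Off by
#'   default so symbol-case bugs stay visible.
#' @return List with `indices` (named list of integer vectors into
#'   `gene.ids`), `original.sizes`, `n.unmatched` and a `dropped`
#'   data frame describing discarded sets.
#' @export
resolve_gene_sets <- function(sets, gene.ids, min.set.size = 5L,
                              case.insensitive = FALSE) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (!is.list(sets) || !length(sets)) {
    stop("'sets' must be a nonempty list or gene_set_collection",
         call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set_", seq_along(sets))
  }
  key <- if (case.insensitive) tolower(gene.ids) else gene.ids
  indices <- vector("list", length(sets))
  original <- integer(length(sets))
  unmatched <- integer(length(sets))
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    if (is.character(s)) {
      s <- unique(s)
      original[k] <- length(s)
      idx <- match(if (case.insensitive) tolower(s) else s, key)
      unmatched[k] <- sum(is.na(idx))
      indices[[k]] <- idx[!is.na(idx)]
    } else {
      idx <- unique(as.integer(s))
      if (anyNA(idx) || any(idx < 1L) || any(idx > length(gene.ids))) {
        stop("set '", names(sets)[k], "': indices out of range",
             call. = FALSE)
      }
      original[k] <- length(idx)
      indices[[k]] <- idx
    }
  }
  names(indices) <- names(sets)
  keep <- lengths(indices) >= min.set.size
  dropped <- data.frame(
    set = names(sets)[!keep],
    resolved_size = lengths(indices)[!keep],
    reason = rep(sprintf("fewer than %d genes after matching",
                         min.set.size), sum(!keep)),
    stringsAsFactors = FALSE
  )
  list(indices = indices[keep],
       original.sizes = setNames(original, names(sets))[keep],
       n.unmatched = setNames(unmatched, names(sets))[keep],
       dropped = dropped)
}

#' Write scoring results to TSV files
#'
#' Writes three tab-separated files into `dir`: `scores.tsv` and
#' `pvalues.tsv` (cells x sets, first column `cell_id`) and
#' `gamma_fit.tsv` (per-set shape, rate, effective set size, nonzero fit
#' count and fit provenance). Numbers are formatted with 12 significant
#' digits; columns of sets whose gamma fit failed are written as `NA`,
#' never as 0.
#'
#' @param fit a fitted [vam()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_vam_results <- function(fit, dir) {
  stopifnot(inherits(fit, "vam"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir,
                             call. = FALSE)
  paths <- file.path(dir, c("scores.tsv", "pvalues.tsv", "gamma_fit.tsv"))
  write_num_matrix(fit$scores, "cell_id", paths[1L])
  write_num_matrix(fit$pvalues, "cell_id", paths[2L])
  gm <- fit$gamma
  gm$shape <- fmt_num(gm$shape)
  gm$rate <- fmt_num(gm$rate)
  utils::write.table(gm, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

write_num_matrix <- function(m, id.col, path) {
  ch <- matrix(fmt_num(as.vector(as.matrix(m))), nrow = nrow(m),
               dimnames = dimnames(m))
  df <- data.frame(rownames(m) %||% paste0("cell_", seq_len(nrow(m))),
                   ch, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c(id.col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
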