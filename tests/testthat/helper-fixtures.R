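# Shared fixtures, built in code at test time.

# The two-gene worked example: four cells at the corners of a square,
# set mean (1,1), identity covariance.
corner_cells <- function() {
  rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
}

# Small random sparse nonnegative matrix with dimnames.
random_sparse_matrix <- function(n, p, sparsity = 0.6, seed = 1) {
  set.seed(seed)
  x <- matrix(rlnorm(n * p, -0.5, 0.5), n, p)
  x[matrix(runif(n * p) < sparsity, n, p)] <- 0
  dimnames(x) <- list(paste0("c", seq_len(n)), paste0("g", seq_len(p)))
  x
}

# Write a tiny GMT file; returns the path.
write_gmt_fixture <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# Reduced-size simulation config so unit tests stay fast; experiment
# structure is identical to the full-scale defaults.
small_config <- function(...) {
  sim_config(n.cells = 300, n.genes = 120, signal.set.size = 25,
             signal.cells = 25, ...)
}
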