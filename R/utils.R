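# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||% .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr imap keep
NULL

# Derive a reproducible child seed from a user seed and a stream index.
# Kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647L)
}

# Evaluate under withr::with_seed when a seed is given; otherwise use the
# ambient RNG state (the runner seeds each method call deterministically).
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Dense numeric matrix view of a possibly sparse matrix.
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

# Store a count/layer matrix sparse when density < 50%, dense otherwise.
pack_matrix <- function(x) {
  xm <- as_dense(x)
  if (mean(xm != 0) < 0.5) {
    methods::as(methods::as(Matrix::Matrix(xm, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  } else {
    xm
  }
}

is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}

# Pairwise Euclidean distance matrix (dense, rows of x vs rows of y).
euclid_dist <- function(x, y = NULL) {
  x <- as_dense(x)
  if (is.null(y)) {
    as.matrix(stats::dist(x))
  } else {
    y <- as_dense(y)
    xx <- rowSums(x^2)
    yy <- rowSums(y^2)
    d2 <- outer(xx, yy, "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    sqrt(d2)
  }
}

# Index matrix of the k nearest neighbours of each row (self excluded).
knn_index <- function(x, k) {
  d <- euclid_dist(x)
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

# Top-d principal component scores (centered, not scaled).
pca_scores <- function(x, d) {
  x <- as_dense(x)
  d <- min(d, ncol(x), nrow(x) - 1L)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
  p$x
}

timestamp_utc <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

log_msg <- function(level, ...) {
  msg <- paste0("[", timestamp_utc(), "] ", level, " ", paste0(...))
  message(msg)
}
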