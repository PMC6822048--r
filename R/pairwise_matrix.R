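#' Symmetric site-by-site matrix
#'
#' Light wrapper used for geographic distances (km), linearized genetic
#' differentiation, and effective resistance. A pairwise matrix is a plain
#' symmetric numeric matrix with matching row/column site ids, a zero
#' diagonal, and a `kind` attribute.
#'
#' @param values symmetric numeric matrix.
#' @param ids site ids (defaults to existing dimnames).
#' @param kind tag: e.g. "geographic_km", "linearized_gst", "resistance".
#' @return the matrix with dimnames and a `kind` attribute.
#' @export
pairwise_matrix <- function(values, ids = rownames(values), kind = "generic") {
  values <- as.matrix(values)
  if (is.null(ids)) stop("site ids required")
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (length(ids) != nrow(values)) stop("ids length must match matrix size")
  off <- !is.na(values) & !is.na(t(values))
  if (any(abs(values[off] - t(values)[off]) > 1e-8))
    stop("matrix must be symmetric")
  dimnames(values) <- list(ids, ids)
  diag(values) <- 0
  attr(values, "kind") <- kind
  values
}

#' Lower-triangle vector of a pairwise matrix
#' @param m symmetric matrix.
#' @return numeric vector in column-major lower-triangle order.
#' @export
lower_vec <- function(m) m[lower.tri(m)]

# index pairs (i > j) of the lower triangle, column-major, matching lower_vec
lower_idx <- function(n) {
  j <- rep(seq_len(n - 1), times = (n - 1):1)
  i <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

# fold a lower-triangle vector back into a symmetric matrix with zero diagonal
unfold_to_matrix <- function(v, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- v
  m <- m + t(m)
  m
}

# align B (and optionally C) to A's site ordering; error on mismatch
align_pairwise <- function(A, ...) {
  ids <- rownames(A)
  out <- lapply(list(...), function(B) {
    if (is.null(rownames(B)) || !setequal(rownames(B), ids))
      stop("pairwise matrices cover different site sets")
    B[ids, ids]
  })
  c(list(A), out)
}

#' Write a square pairwise matrix as a delimited file with id headers
#' @param m pairwise matrix.
#' @param path output file.
#' @export
write_pairwise <- function(m, path) {
  df <- data.frame(site = rownames(m), as.data.frame(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square pairwise matrix written by [write_pairwise()]
#' @param path input file.
#' @param kind kind tag to attach.
#' @return a pairwise matrix.
#' @export
read_pairwise <- function(path, kind = "generic") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  pairwise_matrix(m, ids, kind)
}
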