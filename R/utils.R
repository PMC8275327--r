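# small geometry helpers shared across modules

vnorm <- function(x) sqrt(sum(x * x))

normalize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rowwise cross product for n x 3 matrices
rows_cross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

rows_norm <- function(A) sqrt(rowSums(A * A))

bbox_diagonal <- function(V) {
  vnorm(apply(V, 2, max) - apply(V, 2, min))
}

# an arbitrary unit vector orthogonal to u
orthogonal_unit <- function(u) {
  u <- normalize(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  normalize(cross3(u, ref))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix3 <- function(x, what = "matrix") {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
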