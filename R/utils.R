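#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so library internals never perturb a caller's stream.
#' With `seed = NULL` the code runs against the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# row-wise euclidean norm of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Check that a 3x3 matrix is a proper rotation
#' @param R 3x3 matrix.
#' @param tol Orthonormality tolerance.
#' @return Logical scalar.
#' @keywords internal
is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}
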