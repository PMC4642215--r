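# Complex linear-algebra primitives shared by both Fock-space sectors.
# Convention: the Hermitian inner product is conjugate-linear in its LEFT
# argument, <u|v> = sum(Conj(u) * v).  All dimensions in this package are
# 2, 3, 4 or 9.

#' Hermitian inner product
#'
#' Computes `<u|v> = sum(Conj(u) * v)`, conjugate-linear in the left
#' argument. This is the bra-ket pairing used throughout the package.
#'
#' @param u,v Numeric or complex vectors of equal length.
#' @return A complex scalar.
#' @export
#' @examples
#' qip(c(1i, 0), c(1i, 0)) # 1+0i
qip <- function(u, v) {
  if (length(u) != length(v)) {
    abort("`u` and `v` must have the same length.")
  }
  sum(Conj(u) * v)
}

vec_norm <- function(u) sqrt(Re(qip(u, u)))

# Make the first component of modulus > tol real and non-negative; fixes the
# global phase so constructed bases are reproducible bit-for-bit.
fix_phase <- function(v, tol = 1e-12) {
  k <- which(Mod(v) > tol)
  if (length(k) == 0L) {
    return(v)
  }
  ph <- v[k[1L]] / Mod(v[k[1L]])
  v / ph
}

canonical_vector <- function(k, dim) {
  e <- rep(0 + 0i, dim)
  e[k] <- 1 + 0i
  e
}

canonical_basis <- function(dim) lapply(seq_len(dim), canonical_vector, dim = dim)

# Projector onto the span of the first `rank` canonical vectors.
canonical_projector <- function(dim, rank) {
  diag(c(rep(1 + 0i, rank), rep(0 + 0i, dim - rank)), nrow = dim, ncol = dim)
}

gram_matrix <- function(vectors) {
  n <- length(vectors)
  g <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) g[i, j] <- qip(vectors[[i]], vectors[[j]])
  }
  g
}

is_orthonormal <- function(vectors, tol = 1e-10) {
  if (length(vectors) == 0L) {
    return(TRUE)
  }
  g <- gram_matrix(vectors)
  max(Mod(g - diag(nrow(g)))) < tol
}

check_square <- function(m, what = "operator") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", what))
  }
  invisible(m)
}

is_hermitian <- function(m, tol = 1e-10) max(Mod(m - Conj(t(m)))) < tol

is_projector <- function(m, tol = 1e-10) {
  is_hermitian(m, tol) && max(Mod(m %*% m - m)) < tol
}

projector_rank <- function(m) as.integer(round(Re(sum(diag(m)))))

#' Complete a set of orthonormal vectors to a full orthonormal basis
#'
#' Extends `vectors` to an orthonormal basis of the `dim`-dimensional complex
#' space by modified Gram-Schmidt against the canonical basis: at each step
#' the canonical vector whose residual (after projecting out the current set)
#' has the largest norm is orthonormalised and appended; ties break towards
#' the lowest canonical index. The completion is deterministic, and every
#' appended vector has its first nonzero component real non-negative.
#'
#' @param vectors A list of orthonormal numeric/complex vectors (possibly
#'   empty).
#' @param dim Target dimension.
#' @param tol Orthonormality tolerance for the input check.
#' @return A list of `dim` orthonormal vectors whose first `length(vectors)`
#'   elements are the inputs.
#' @export
#' @examples
#' b <- complete_orthonormal_basis(list(c(1, 0, 0, 0)), 4)
#' length(b) # 4
complete_orthonormal_basis <- function(vectors, dim, tol = 1e-10) {
  vectors <- lapply(vectors, function(v) as.complex(v))
  if (any(lengths(vectors) != dim)) {
    abort("All input vectors must have length `dim`.")
  }
  if (length(vectors) > dim) {
    abort("More input vectors than `dim`.")
  }
  if (!is_orthonormal(vectors, tol)) {
    abort("Input vectors are not orthonormal within tolerance.")
  }
  basis <- vectors
  while (length(basis) < dim) {
    best <- NULL
    best_norm <- -1
    for (k in seq_len(dim)) {
      r <- canonical_vector(k, dim)
      for (b in basis) r <- r - qip(b, r) * b
      nr <- vec_norm(r)
      if (nr > best_norm + 1e-12) {
        best_norm <- nr
        best <- r
      }
    }
    # second orthogonalisation pass for numerical stability
    for (b in basis) best <- best - qip(b, best) * b
    basis[[length(basis) + 1L]] <- fix_phase(best / vec_norm(best))
  }
  basis
}

#' Build the unitary change of basis between two orthonormal bases
#'
#' Returns `U = sum_k |target_k><source_k|`, the unitary matrix mapping the
#' k-th source basis vector onto the k-th target basis vector.
#'
#' @param source,target Lists of orthonormal vectors of equal length, each
#'   spanning the full space.
#' @param tol Orthonormality tolerance.
#' @return A complex unitary matrix with attributes `source_basis` and
#'   `target_basis`.
#' @export
build_basis_change <- function(source, target, tol = 1e-10) {
  if (length(source) != length(target)) {
    abort("`source` and `target` must contain the same number of vectors.")
  }
  dim <- length(source[[1L]])
  if (length(source) != dim || any(lengths(c(source, target)) != dim)) {
    abort("Bases must contain `dim` vectors of length `dim`.")
  }
  if (!is_orthonormal(source, tol) || !is_orthonormal(target, tol)) {
    abort("Both bases must be orthonormal within tolerance.")
  }
  u <- matrix(0 + 0i, dim, dim)
  for (k in seq_len(dim)) {
    u <- u + outer(as.complex(target[[k]]), Conj(as.complex(source[[k]])))
  }
  structure(u, source_basis = source, target_basis = target)
}

#' Conjugate an operator by a unitary
#'
#' Returns `U op U^-1` (with `U^-1 = U^dagger` for unitary `U`). Conjugation
#' preserves rank, Hermiticity, idempotence and every expectation value
#' `<Uv| U op U^-1 |Uv> = <v|op|v>`.
#'
#' @param op Square complex matrix.
#' @param u Unitary matrix of the same dimension.
#' @return The conjugated operator.
#' @export
conjugate_operator <- function(op, u) {
  check_square(op, "op")
  check_square(u, "u")
  if (nrow(op) != nrow(u)) {
    abort("`op` and `u` must have the same dimension.")
  }
  u %*% op %*% Conj(t(u))
}

# --- tensor <-> flat isomorphism ------------------------------------------
# A state on C^n (x) C^n with coefficient matrix c[i, j] corresponds to the
# flat vector with entry n*(i-1)+j, i.e. |i> (x) |j> -> e_{n(i-1)+j}.  This
# is exactly the ordering of base::kronecker, so operators X (x) Y are
# kronecker(X, Y).

#' Map a tensor coefficient matrix to its flat vector form
#'
#' The bijection sends the coefficient of `|i> (x) |j>` to flat position
#' `n*(i-1)+j` (so `|1>(x)|1> -> e1` and `|2>(x)|2> -> e4` when `n = 2`).
#'
#' @param coef An `n x n` coefficient matrix (row index = first factor).
#' @return A complex vector of length `n^2`.
#' @export
#' @examples
#' tensor_to_vec(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)) # e1
tensor_to_vec <- function(coef) {
  check_square(coef, "coef")
  as.vector(t(as.matrix(coef)))
}

#' @rdname tensor_to_vec
#' @param v A flat vector of length `n^2`.
#' @export
vec_to_tensor <- function(v) {
  n <- sqrt(length(v))
  if (n != round(n)) {
    abort("`v` must have square length.")
  }
  n <- as.integer(n)
  t(matrix(v, nrow = n, ncol = n))
}

# Complex matrix -> nested [re, im] arrays for JSON reports.
complex_mat_to_json <- function(m) {
  m <- as.matrix(m)
  lapply(seq_len(nrow(m)), function(i) {
    lapply(seq_len(ncol(m)), function(j) c(Re(m[i, j]), Im(m[i, j])))
  })
}

complex_vec_to_json <- function(v) lapply(v, function(z) c(Re(z), Im(z)))
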