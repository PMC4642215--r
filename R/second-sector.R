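# Second (logical) sector: tensor-product representations of classical
# conjunction data.  A triplet is realised on C^2 (x) C^2 by a unit state
# |C> and a rank-1 projector M on one factor, with
#   <C|M (x) 1|C> = mu(A), <C|1 (x) M|C> = mu(B), <C|M (x) M|C> = mu(AB).
# The constructive state has all-real coefficients
#   c11 = sqrt(mu_ab), c12 = sqrt(mu_a - mu_ab),
#   c21 = sqrt(mu_b - mu_ab), c22 = sqrt(1 - mu_a - mu_b + mu_ab),
# which exist exactly when the triplet is classical.  Whole datasets are
# unified (zero-type) by a unitary change of basis in the flat C^4 picture
# so that every exemplar shares the state |1> (x) |1>.

#' Construct a tensor-product representation of one classical triplet
#'
#' Builds the canonical second-sector representation on `C^2 (x) C^2` with
#' real coefficients (all construction phases zero) and `M` the rank-1
#' projector onto the first canonical vector of each factor. Exists exactly
#' for classical conjunction data; non-classical triplets raise a
#' representability error naming the violated inequality.
#'
#' @param mu_a,mu_b,mu_ab Membership weights in `[0, 1]` (scalars).
#' @param tol Classicality tolerance.
#' @return An object of class `tensor_rep`: `coefficients` (2 x 2 real
#'   matrix, row = first factor), `state` (flat length-4 vector), `projector`
#'   (the 2 x 2 factor projector), `phases` (2 x 2, all zero), and `triplet`.
#' @export
#' @examples
#' r <- construct_tensor_rep(0.56, 0.8, 0.42)
#' round(r$coefficients, 4)
construct_tensor_rep <- function(mu_a, mu_b, mu_ab, tol = 1e-9) {
  stopifnot(length(mu_a) == 1L, length(mu_b) == 1L, length(mu_ab) == 1L)
  cls <- check_classical(
    membership_triplets("x", mu_a, mu_b, mu_ab),
    tol = tol
  )
  if (!cls$is_classical) {
    which_bad <- c(
      if (cls$overextended_a) "mu_ab <= mu_a",
      if (cls$overextended_b) "mu_ab <= mu_b",
      if (cls$kolmogorov_violation) "mu_a + mu_b - mu_ab <= 1"
    )
    abort(
      sprintf(
        paste0(
          "Triplet (%g, %g, %g) is not classical conjunction data, so it ",
          "has no tensor-product representation; violated: %s."
        ),
        mu_a, mu_b, mu_ab, paste(which_bad, collapse = ", ")
      ),
      class = "fockconj_representability_error"
    )
  }
  clamp0 <- function(x) sqrt(pmax(x, 0))
  coef <- matrix(
    c(
      clamp0(mu_ab), clamp0(mu_a - mu_ab),
      clamp0(mu_b - mu_ab), clamp0(1 - mu_a - mu_b + mu_ab)
    ),
    nrow = 2, byrow = TRUE
  )
  coef <- coef / sqrt(sum(coef^2)) # renormalise tolerance-level clamping
  structure(
    list(
      coefficients = coef,
      state = tensor_to_vec(coef) + 0i,
      projector = canonical_projector(2, 1),
      phases = matrix(0, 2, 2),
      triplet = c(mu_a = mu_a, mu_b = mu_b, mu_ab = mu_ab)
    ),
    class = "tensor_rep"
  )
}

#' Expectation values of a tensor representation
#'
#' Evaluates `<C|M (x) 1|C>`, `<C|1 (x) M|C>` and `<C|M (x) M|C>` for a
#' tensor representation (the second-sector analogues of the two marginal
#' memberships and the conjunction membership).
#'
#' @param rep A `tensor_rep`.
#' @return A named numeric vector `mu_a`, `mu_b`, `mu_ab`.
#' @export
tensor_expectations <- function(rep) {
  m <- rep$projector
  n <- nrow(m)
  id <- diag(n) + 0i
  v <- rep$state
  c(
    mu_a = Re(qip(v, kronecker(m, id) %*% v)),
    mu_b = Re(qip(v, kronecker(id, m) %*% v)),
    mu_ab = Re(qip(v, kronecker(m, m) %*% v))
  )
}

#' Fit tensor-product representations to a dataset
#'
#' Runs [construct_tensor_rep()] on every triplet; non-classical exemplars
#' are flagged and carry no representation.
#'
#' @inheritParams fit_first_sector
#' @return An object of class `second_sector_fit` with `data` (triplets plus
#'   classicality columns), `reps` (named list, `NULL` where non-classical),
#'   and `tol`.
#' @export
fit_second_sector <- function(data, tol = 1e-9) {
  data <- check_classical(data, tol = tol)
  reps <- purrr::pmap(
    list(data$mu_a, data$mu_b, data$mu_ab, data$is_classical),
    function(a, b, ab, ok) {
      if (!ok) {
        return(NULL)
      }
      construct_tensor_rep(a, b, ab, tol = tol)
    }
  )
  names(reps) <- data$exemplar
  structure(list(data = data, reps = reps, tol = tol),
    class = "second_sector_fit"
  )
}

#' Unify a classical dataset into a zero-type tensor model
#'
#' Builds, for every exemplar, the canonical tensor representation, then
#' rotates it so that all exemplars share the single conceptual state
#' `|1> (x) |1>`: the exemplar state `|C_i>` (flat `C^4` form) is completed
#' to an orthonormal basis, the basis-change unitary `U_i` maps that basis
#' onto the canonical one, and the three measurement operators
#' `M (x) 1`, `1 (x) M`, `M (x) M` are conjugated by `U_i`. Conjugation
#' preserves all expectation values, so the model reproduces every triplet
#' exactly. Exemplars whose conjugated marginal operators factor as
#' `X (x) 1` and `1 (x) Y` are additionally flagged `first_type`.
#'
#' @param data A data frame of membership triplets, all classical.
#' @param tol Classicality tolerance.
#' @return An object of class `zero_type_model`: `state` (flat, `e1`),
#'   `factor_dim` (2), `operators` (named list of lists with 4 x 4 matrices
#'   `m_a`, `m_b`, `m_and`), `unitaries`, `first_type` (named logical), and
#'   `data`.
#' @export
#' @examples
#' d <- membership_triplets(c("cave", "synagogue"),
#'   mu_a = c(0.28, 0.93), mu_b = c(0.85, 0.49), mu_ab = c(0.28, 0.45)
#' )
#' m <- unify_zero_type(d)
#' tidy(m)
unify_zero_type <- function(data, tol = 1e-9) {
  cls <- check_classical(data, tol = tol)
  bad <- cls$exemplar[!cls$is_classical]
  if (length(bad) > 0L) {
    abort(sprintf(
      "Cannot build a zero-type model: exemplar%s %s %s not classical.",
      if (length(bad) > 1L) "s" else "",
      paste0('"', bad, '"', collapse = ", "),
      if (length(bad) > 1L) "are" else "is"
    ), class = "fockconj_representability_error")
  }
  canon <- canonical_basis(4)
  id2 <- diag(2) + 0i
  ops <- list()
  us <- list()
  ft <- logical(0)
  for (i in seq_len(nrow(cls))) {
    r <- construct_tensor_rep(cls$mu_a[i], cls$mu_b[i], cls$mu_ab[i], tol = tol)
    basis <- complete_orthonormal_basis(list(r$state), 4)
    u <- build_basis_change(basis, canon)
    m <- r$projector
    trip <- list(
      m_a = conjugate_operator(kronecker(m, id2), u),
      m_b = conjugate_operator(kronecker(id2, m), u),
      m_and = conjugate_operator(kronecker(m, m), u)
    )
    nm <- cls$exemplar[i]
    ops[[nm]] <- trip
    us[[nm]] <- u
    ft[nm] <- is_kron_left(trip$m_a) && is_kron_right(trip$m_b)
  }
  structure(
    list(
      state = canon[[1L]], factor_dim = 2L,
      operators = ops, unitaries = us, first_type = ft, data = cls
    ),
    class = "zero_type_model"
  )
}

# M4 == X (x) I?  blocks B_kl must be multiples of the identity.
is_kron_left <- function(m4, tol = 1e-10) {
  n <- as.integer(sqrt(nrow(m4)))
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      blk <- m4[((k - 1) * n + 1):(k * n), ((l - 1) * n + 1):(l * n)]
      if (max(Mod(blk - blk[1, 1] * diag(n))) > tol) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# M4 == I (x) Y?  diagonal blocks equal, off-diagonal blocks zero.
is_kron_right <- function(m4, tol = 1e-10) {
  n <- as.integer(sqrt(nrow(m4)))
  ref <- m4[1:n, 1:n]
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      blk <- m4[((k - 1) * n + 1):(k * n), ((l - 1) * n + 1):(l * n)]
      target <- if (k == l) ref else matrix(0 + 0i, n, n)
      if (max(Mod(blk - target)) > tol) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Unify independent triplets into a second-type (product-state) model
#'
#' A second-type representation puts the shared state in product form
#' `|1> (x) |1>` with *single-factor* projectors `M_i^A`, `M_i^B` per
#' exemplar, so that the conjunction operator `M_i^A (x) M_i^B` factorises.
#' On a product state the conjunction expectation necessarily factorises
#' too, so a triplet admits this representation exactly when it is
#' independent, `mu_ab = mu_a * mu_b` (within `tol`); other triplets raise
#' an error. Each factor representation `|A_i> = (sqrt(mu_a),
#' sqrt(1-mu_a))` with projector onto `|1>` is rotated by the single-factor
#' unitary taking `|A_i>` to `|1>`.
#'
#' @inheritParams unify_zero_type
#' @return An object of class `second_type_model`: `state` (flat `e1` on
#'   `C^4`), `factor_dim` (2), `operators` (per exemplar: 2 x 2 `m_a`,
#'   `m_b`), `unitaries` (per exemplar: `u_a`, `u_b`), and `data`.
#' @export
unify_second_type <- function(data, tol = 1e-9) {
  data <- validate_triplets(data)
  dep <- abs(data$mu_ab - data$mu_a * data$mu_b) > tol
  if (any(dep)) {
    abort(sprintf(
      paste0(
        "Exemplar%s %s: mu_ab != mu_a * mu_b, so no product-state ",
        "representation exists and a second-type model cannot be built."
      ),
      if (sum(dep) > 1L) "s" else "",
      paste0('"', data$exemplar[dep], '"', collapse = ", ")
    ), class = "fockconj_representability_error")
  }
  canon2 <- canonical_basis(2)
  ops <- list()
  us <- list()
  for (i in seq_len(nrow(data))) {
    mk <- function(mu) {
      st <- c(sqrt(mu), sqrt(1 - mu)) + 0i
      u <- build_basis_change(complete_orthonormal_basis(list(st), 2), canon2)
      list(op = conjugate_operator(canonical_projector(2, 1), u), u = u)
    }
    fa <- mk(data$mu_a[i])
    fb <- mk(data$mu_b[i])
    nm <- data$exemplar[i]
    ops[[nm]] <- list(m_a = fa$op, m_b = fb$op)
    us[[nm]] <- list(u_a = fa$u, u_b = fb$u)
  }
  structure(
    list(
      state = canonical_vector(1, 4), factor_dim = 2L,
      operators = ops, unitaries = us, data = data
    ),
    class = "second_type_model"
  )
}

#' Trivially embed a tensor model into the three-dimensional factors
#'
#' Zero-pads a `C^2 (x) C^2` model into `C^3 (x) C^3`: state coefficients
#' `c*_ij = c_ij` for `i, j` in `{1, 2}` and 0 otherwise, operators padded
#' accordingly. All expectation values, Hermiticity and idempotence are
#' unchanged.
#'
#' @param model A `zero_type_model` or `second_type_model` with
#'   `factor_dim = 2`.
#' @return A model of the same class with `factor_dim = 3` (flat dimension
#'   9 for zero-type operators, 3 x 3 single-factor operators for
#'   second-type).
#' @export
embed_in_C3 <- function(model) {
  UseMethod("embed_in_C3")
}

# old flat index 2(i-1)+j -> new flat index 3(i-1)+j
embed_map_idx <- function() {
  idx <- integer(4)
  for (i in 1:2) for (j in 1:2) idx[2 * (i - 1) + j] <- 3 * (i - 1) + j
  idx
}

embed_vec_c9 <- function(v4) {
  v9 <- rep(0 + 0i, 9)
  v9[embed_map_idx()] <- v4
  v9
}

embed_op_c9 <- function(m4) {
  m9 <- matrix(0 + 0i, 9, 9)
  idx <- embed_map_idx()
  m9[idx, idx] <- m4
  m9
}

embed_op_c3 <- function(m2) {
  m3 <- matrix(0 + 0i, 3, 3)
  m3[1:2, 1:2] <- m2
  m3
}

#' @export
embed_in_C3.zero_type_model <- function(model) {
  if (model$factor_dim != 2L) {
    abort("`model` must have two-dimensional factors.")
  }
  model$state <- embed_vec_c9(model$state)
  model$operators <- lapply(model$operators, function(trip) {
    lapply(trip, embed_op_c9)
  })
  model$unitaries <- NULL # basis changes are not propagated through embedding
  model$factor_dim <- 3L
  model
}

#' @export
embed_in_C3.second_type_model <- function(model) {
  if (model$factor_dim != 2L) {
    abort("`model` must have two-dimensional factors.")
  }
  model$state <- embed_vec_c9(model$state)
  model$operators <- lapply(model$operators, function(ops) {
    lapply(ops, embed_op_c3)
  })
  model$unitaries <- NULL
  model$factor_dim <- 3L
  model
}

# zero-type view of a model's operator triple on the full tensor space
model_operator_triple <- function(model, exemplar) {
  ops <- model$operators[[exemplar]]
  if (inherits(model, "second_type_model")) {
    id <- diag(model$factor_dim) + 0i
    list(
      m_a = kronecker(ops$m_a, id),
      m_b = kronecker(id, ops$m_b),
      m_and = kronecker(ops$m_a, ops$m_b)
    )
  } else {
    ops
  }
}

#' @export
print.second_sector_fit <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf(
    "Second-sector (tensor) fit: %d exemplar%s, %d classical/representable\n",
    n, if (n == 1L) "" else "s", sum(x$data$is_classical)
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
print.zero_type_model <- function(x, ...) {
  cat(sprintf(
    "Zero-type tensor model (C^%d (x) C^%d): %d exemplars, shared state |1>(x)|1>\n",
    x$factor_dim, x$factor_dim, length(x$operators)
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
print.second_type_model <- function(x, ...) {
  cat(sprintf(
    "Second-type tensor model (C^%d factors): %d exemplars, product state\n",
    x$factor_dim, length(x$operators)
  ))
  invisible(x)
}
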