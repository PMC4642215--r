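# Measurement compatibility.  Once a whole dataset is expressed in one
# basis (a unified model), any two exemplars' membership operators can be
# compared: they are compatible when their commutator [M1, M2] = M1 M2 -
# M2 M1 has vanishing expectation on the relevant conceptual states.
# Nonzero values predict order effects in sequential membership judgements.

#' Commutator expectation value
#'
#' Computes `<v|(M1 M2 - M2 M1)|v>`. For Hermitian `M1`, `M2` this is
#' purely imaginary.
#'
#' @param m1,m2 Square complex matrices of equal dimension.
#' @param state A vector of matching length.
#' @return A complex scalar.
#' @export
commutator_expectation <- function(m1, m2, state) {
  check_square(m1, "m1")
  check_square(m2, "m2")
  if (nrow(m1) != nrow(m2) || nrow(m1) != length(state)) {
    abort("`m1`, `m2` and `state` must have matching dimensions.")
  }
  qip(state, (m1 %*% m2 - m2 %*% m1) %*% state)
}

compat_row <- function(ex1, ex2, c_a, c_b, c_ab, tol) {
  tibble(
    exemplar_1 = ex1, exemplar_2 = ex2,
    c_a = c_a, c_b = c_b, c_ab = c_ab,
    mag_a = Mod(c_a), mag_b = Mod(c_b), mag_ab = Mod(c_ab),
    compatible_a = Mod(c_a) < tol,
    compatible_b = Mod(c_b) < tol,
    compatible_ab = Mod(c_ab) < tol,
    compatible = Mod(c_a) < tol & Mod(c_b) < tol & Mod(c_ab) < tol
  )
}

#' Compatibility of one exemplar pair in a unified model
#'
#' For a unified first-sector model, evaluates the commutator expectations
#' `c_A = <A|[M1,M2]|A>`, `c_B = <B|[M1,M2]|B>` and `c_AB = (1/2)(<A| +
#' <B|)[M1,M2](|A> + |B>)` (the superposed conjunction state, with the 1/2
#' prefactor compensating the unnormalised sum). For a tensor (zero-type or
#' second-type) model, evaluates `c'_X = <C|[M1^X, M2^X]|C>` on the shared
#' state for `X` in `{A, B, AB}`.
#'
#' The exemplars `p1` and `p2` are compatible with respect to a concept
#' when the corresponding value vanishes. Because first-sector
#' representations are non-unique (the constructive solver fixes one of a
#' continuum of phase choices), the *numeric* first-sector c-values are
#' convention-dependent; their zero/nonzero structure is not.
#'
#' @param model A `unified_first_sector`, `zero_type_model` or
#'   `second_type_model`.
#' @param i,j Exemplar indices or names (must differ).
#' @param tol Compatibility threshold on the commutator magnitude.
#' @return A one-row tibble: `exemplar_1`, `exemplar_2`, complex `c_a`,
#'   `c_b`, `c_ab`, their magnitudes `mag_*`, and logical `compatible_a`,
#'   `compatible_b`, `compatible_ab`, `compatible`.
#' @export
compatibility_pair <- function(model, i, j, tol = 1e-10) {
  UseMethod("compatibility_pair")
}

resolve_exemplar <- function(names, k) {
  if (is.character(k)) {
    if (!k %in% names) abort(sprintf("Unknown exemplar \"%s\".", k))
    return(k)
  }
  if (k < 1 || k > length(names)) {
    abort(sprintf("Exemplar index %d out of range [1, %d].", k, length(names)))
  }
  names[k]
}

#' @export
compatibility_pair.unified_first_sector <- function(model, i, j, tol = 1e-10) {
  nms <- names(model$operators)
  i <- resolve_exemplar(nms, i)
  j <- resolve_exemplar(nms, j)
  m1 <- model$operators[[i]]
  m2 <- model$operators[[j]]
  comm <- m1 %*% m2 - m2 %*% m1
  a <- model$state_a
  b <- model$state_b
  s <- a + b
  compat_row(i, j,
    c_a = qip(a, comm %*% a),
    c_b = qip(b, comm %*% b),
    c_ab = qip(s, comm %*% s) / 2,
    tol = tol
  )
}

compat_pair_tensor <- function(model, i, j, tol) {
  nms <- names(model$operators)
  i <- resolve_exemplar(nms, i)
  j <- resolve_exemplar(nms, j)
  t1 <- model_operator_triple(model, i)
  t2 <- model_operator_triple(model, j)
  v <- model$state
  compat_row(i, j,
    c_a = commutator_expectation(t1$m_a, t2$m_a, v),
    c_b = commutator_expectation(t1$m_b, t2$m_b, v),
    c_ab = commutator_expectation(t1$m_and, t2$m_and, v),
    tol = tol
  )
}

#' @export
compatibility_pair.zero_type_model <- function(model, i, j, tol = 1e-10) {
  compat_pair_tensor(model, i, j, tol)
}

#' @export
compatibility_pair.second_type_model <- function(model, i, j, tol = 1e-10) {
  compat_pair_tensor(model, i, j, tol)
}

#' Pairwise compatibility matrix of a unified model
#'
#' Evaluates [compatibility_pair()] for every unordered exemplar pair
#' (including the all-compatible diagonal) and returns the results as one
#' tidy tibble, ready for [autoplot()].
#'
#' @param model A unified model with at least two exemplars.
#' @param tol Compatibility threshold.
#' @return A tibble of class `fockconj_compat` with one row per pair.
#' @export
#' @examples
#' d <- membership_triplets(c("cave", "synagogue"),
#'   mu_a = c(0.28, 0.93), mu_b = c(0.85, 0.49), mu_ab = c(0.28, 0.45)
#' )
#' compatibility_matrix(unify_zero_type(d))
compatibility_matrix <- function(model, tol = 1e-10) {
  nms <- names(model$operators)
  if (length(nms) < 2L) {
    abort("Need at least two exemplars for a compatibility matrix.")
  }
  pairs <- expand.grid(
    i = seq_along(nms), j = seq_along(nms),
    KEEP.OUT.ATTRS = FALSE
  )
  pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
  out <- purrr::pmap_dfr(pairs, function(i, j) {
    compatibility_pair(model, i, j, tol = tol)
  })
  class(out) <- c("fockconj_compat", class(out))
  out
}
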