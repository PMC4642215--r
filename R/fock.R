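# Two-sector Fock membership formula.  The conjunction state lives in the
# direct sum of the emergent sector (C^3) and the logical sector (tensor
# product), weighted by n^2 and 1 - n^2:
#   mu(AB) = n^2 * ((mu(A)+mu(B))/2 + I) + (1 - n^2) * mu(A)*mu(B),
# with first-sector interference I = Re<A|M|B> bounded by
# |I| <= sqrt(mu(A) mu(B)).

#' Bound on the first-sector interference term
#'
#' The interference `Re<A|M|B>` achievable by a rank-1 membership projector
#' is bounded in modulus by `sqrt(mu_a * mu_b)`.
#'
#' @param mu_a,mu_b Membership weights (vectorised).
#' @return `sqrt(mu_a * mu_b)`.
#' @export
#' @examples
#' interference_bound(1, 0.49) # 0.7
interference_bound <- function(mu_a, mu_b) {
  sqrt(mu_a * mu_b)
}

#' Two-sector Fock membership formula
#'
#' Evaluates `n^2 * ((mu_a + mu_b)/2 + interference) + (1 - n^2) * mu_a *
#' mu_b`. With `n = 1` the conjunction behaves as an emergent entity (the
#' average plus interference); with `n = 0` as a logical joint of two
#' independent events (the product).
#'
#' @param mu_a,mu_b Membership weights (vectorised).
#' @param n Fock weight of the first sector, in `[0, 1]`.
#' @param interference First-sector interference term `Re<A|M|B>`; must
#'   satisfy `|interference| <= interference_bound(mu_a, mu_b)`.
#' @param tol Tolerance on the bound check.
#' @return Predicted conjunction membership weight(s).
#' @export
#' @examples
#' fock_membership(0.56, 0.8, n = 1, interference = 0) # 0.68
#' fock_membership(0.56, 0.8, n = 0, interference = 0) # 0.448
fock_membership <- function(mu_a, mu_b, n, interference, tol = 1e-9) {
  if (any(n < 0 | n > 1)) {
    abort("`n` must lie in [0, 1].")
  }
  bound <- interference_bound(mu_a, mu_b)
  if (any(abs(interference) > bound + tol)) {
    k <- which(abs(interference) > bound + tol)[1L]
    abort(sprintf(
      "Interference %g exceeds the bound sqrt(mu_a*mu_b) = %g.",
      interference[min(k, length(interference))], bound[min(k, length(bound))]
    ), class = "fockconj_validation_error")
  }
  n^2 * ((mu_a + mu_b) / 2 + interference) + (1 - n^2) * mu_a * mu_b
}

# Solve, for fixed n, the interference reproducing mu_ab; NA if n = 0 and
# the product does not already match.
fock_solve_interference <- function(mu_a, mu_b, mu_ab, n, tol = 1e-9) {
  prod <- mu_a * mu_b
  if (n == 0) {
    if (abs(mu_ab - prod) <= tol) {
      return(0)
    }
    return(NA_real_)
  }
  intf <- (mu_ab - (1 - n^2) * prod) / n^2 - (mu_a + mu_b) / 2
  if (abs(intf) <= interference_bound(mu_a, mu_b) + tol) intf else NA_real_
}

#' Fit Fock parameters to membership triplets
#'
#' For each triplet, finds a deterministic representative `(n,
#' interference)` reproducing `mu_ab` under the two-sector formula. The
#' preference rule is largest-`n`-first: `n = 1` with `interference = mu_ab
#' - (mu_a + mu_b)/2` when that value is within the interference bound;
#' otherwise `n` is scanned downward on a fixed grid (step `grid_step`) and
#' the largest feasible `n` is returned. Triplets reproducible by no `(n,
#' interference)` pair are flagged infeasible.
#'
#' When `n` is supplied, that single sector weight is imposed on every
#' exemplar (one conceptual state shared across the concept pair) and only
#' the interference is solved per exemplar.
#'
#' @param data A data frame of membership triplets.
#' @param n Optional fixed Fock weight shared by all exemplars; default
#'   fits per exemplar.
#' @param grid_step Grid resolution of the downward scan over `n`.
#' @param tol Numerical tolerance.
#' @return The input tibble with columns `fock_n`, `interference`,
#'   `fock_feasible`, and `mu_ab_fit` (the formula re-evaluated at the fit;
#'   equals `mu_ab` wherever feasible).
#' @export
#' @examples
#' d <- membership_triplets("heated waterbed", 1, 0.49, 0.78,
#'   concept_a = "Furniture", concept_b = "Household Appliances"
#' )
#' fit_fock(d)[, c("fock_n", "interference", "fock_feasible")]
fit_fock <- function(data, n = NULL, grid_step = 0.01, tol = 1e-9) {
  data <- validate_triplets(data)
  if (!is.null(n) && (length(n) != 1L || n < 0 || n > 1)) {
    abort("`n` must be a single value in [0, 1].")
  }
  fit_one <- function(a, b, ab) {
    if (!is.null(n)) {
      intf <- fock_solve_interference(a, b, ab, n, tol)
      return(list(n = n, interference = intf, feasible = !is.na(intf)))
    }
    for (nk in rev(seq(0, 1, by = grid_step))) {
      intf <- fock_solve_interference(a, b, ab, nk, tol)
      if (!is.na(intf)) {
        return(list(n = nk, interference = intf, feasible = TRUE))
      }
    }
    list(n = NA_real_, interference = NA_real_, feasible = FALSE)
  }
  fits <- purrr::pmap(list(data$mu_a, data$mu_b, data$mu_ab), fit_one)
  out <- dplyr::mutate(data,
    fock_n = purrr::map_dbl(fits, "n"),
    interference = purrr::map_dbl(fits, "interference"),
    fock_feasible = purrr::map_lgl(fits, "feasible")
  )
  dplyr::mutate(out,
    mu_ab_fit = ifelse(
      .data$fock_feasible,
      .data$fock_n^2 * ((.data$mu_a + .data$mu_b) / 2 + .data$interference) +
        (1 - .data$fock_n^2) * .data$mu_a * .data$mu_b,
      NA_real_
    )
  )
}
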