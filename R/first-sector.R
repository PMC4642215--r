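# First (emergent) sector: membership triplets realised in C^3 by a pair of
# orthonormal unit states |A>, |B> and an orthogonal projector M with
#   <A|M|A> = mu(A),  <B|M|B> = mu(B),
#   mu(AB) = (mu(A) + mu(B))/2 + Re<A|M|B>.
# A triplet is representable iff mu(AB) lies in [ave - dev, ave + dev] with
# ave = (mu(A)+mu(B))/2 and dev = min(sqrt(mu(A)mu(B)),
# sqrt((1-mu(A))(1-mu(B)))).  The solver is a deterministic closed form: the
# proof of the feasibility theorem leaves two amplitude-splitting parameters
# lambda, kappa and three relative phases free; we fix lambda = kappa = 1/2
# and solve the phases in closed form (see the methods vignette).

#' Feasibility interval for a first-sector representation
#'
#' Computes, per triplet, the exact interval of conjunction weights
#' `mu(AB)` realisable in the emergent-conjunction Hilbert-space model in
#' three complex dimensions:
#' `ave = (mu_a + mu_b)/2`, `dev = min(sqrt(mu_a*mu_b),
#' sqrt((1-mu_a)*(1-mu_b)))`, interval `[ave - dev, ave + dev]`.
#'
#' @param data A data frame with columns `mu_a` and `mu_b` (and optionally
#'   `mu_ab`, in which case a feasibility flag is added).
#' @param tol Boundary tolerance; membership in the interval is inclusive
#'   within `tol`.
#' @return The input tibble with columns `ave`, `dev`, `fs_lo`, `fs_hi`, and
#'   (when `mu_ab` is present) `first_sector_feasible`.
#' @export
#' @examples
#' feasibility_interval(tibble::tibble(mu_a = 0.28, mu_b = 0.84, mu_ab = 0.34))
feasibility_interval <- function(data, tol = 1e-9) {
  data <- as_tibble(data)
  out <- dplyr::mutate(data,
    ave = (.data$mu_a + .data$mu_b) / 2,
    dev = pmin(
      sqrt(.data$mu_a * .data$mu_b),
      sqrt((1 - .data$mu_a) * (1 - .data$mu_b))
    ),
    fs_lo = .data$ave - .data$dev,
    fs_hi = .data$ave + .data$dev
  )
  if ("mu_ab" %in% names(out)) {
    out <- dplyr::mutate(out,
      first_sector_feasible = .data$mu_ab >= .data$fs_lo - tol &
        .data$mu_ab <= .data$fs_hi + tol
    )
  }
  out
}

# scalar interval helper
fs_bounds <- function(mu_a, mu_b) {
  ave <- (mu_a + mu_b) / 2
  dev <- min(sqrt(mu_a * mu_b), sqrt((1 - mu_a) * (1 - mu_b)))
  list(ave = ave, dev = dev, lo = ave - dev, hi = ave + dev)
}

#' Construct a first-sector representation of one triplet
#'
#' Builds unit states `|A>`, `|B>` in three complex dimensions and an
#' orthogonal projector `M` realising the triplet, deterministically.
#' Branch selection: degenerate all-zero (all-one) triplets use the rank-0
#' (rank-3) projector with canonical states; otherwise the rank-1 branch is
#' used when `mu_a + mu_b <= 1` (inclusive at equality) and the rank-2
#' branch when `mu_a + mu_b > 1`. The amplitude split is `lambda = kappa =
#' 1/2` and the three relative phases are solved in closed form with the
#' sine of the leading phase non-negative, so the output is unique.
#'
#' @param mu_a,mu_b,mu_ab Membership weights in `[0, 1]` (scalars).
#' @param tol Feasibility boundary tolerance.
#' @return An object of class `first_sector_rep`: a list with `state_a`,
#'   `state_b` (complex length-3 unit vectors), `projector` (3 x 3 complex),
#'   `branch` (`"rank0"`, `"rank1"`, `"rank2"`, `"rank3"`), `lambda`,
#'   `kappa`, `gamma` (three relative phases, radians), and `triplet`.
#' @export
#' @examples
#' rep <- construct_first_sector(0.97, 0.31, 0.53)
#' max(verify_first_sector(rep)) < 1e-10
construct_first_sector <- function(mu_a, mu_b, mu_ab, tol = 1e-9) {
  stopifnot(length(mu_a) == 1L, length(mu_b) == 1L, length(mu_ab) == 1L)
  if (any(c(mu_a, mu_b, mu_ab) < 0) || any(c(mu_a, mu_b, mu_ab) > 1)) {
    abort("Membership weights must lie in [0, 1].",
      class = "fockconj_validation_error"
    )
  }
  fb <- fs_bounds(mu_a, mu_b)
  if (mu_ab < fb$lo - tol || mu_ab > fb$hi + tol) {
    abort(
      sprintf(
        paste0(
          "Triplet (%g, %g, %g) has no first-sector representation: ",
          "mu_ab must lie in [%.6g, %.6g]."
        ),
        mu_a, mu_b, mu_ab, fb$lo, fb$hi
      ),
      class = "fockconj_representability_error"
    )
  }

  eps <- 1e-12
  gamma <- c(0, 0, 0)
  lambda <- kappa <- 0.5

  if (mu_a < eps && mu_b < eps && mu_ab < eps) {
    # degenerate all-zero: rank-0 projector, canonical orthonormal states
    state_a <- canonical_vector(1, 3)
    state_b <- canonical_vector(2, 3)
    m <- canonical_projector(3, 0)
    branch <- "rank0"
  } else if (mu_a > 1 - eps && mu_b > 1 - eps && mu_ab > 1 - eps) {
    state_a <- canonical_vector(1, 3)
    state_b <- canonical_vector(2, 3)
    m <- canonical_projector(3, 3)
    branch <- "rank3"
  } else if (mu_a + mu_b <= 1) {
    # rank-1 branch: M projects onto e1;
    # |A> = (sqrt(a) e^{i g1}, sqrt((1-a)/2) e^{i g2}, sqrt((1-a)/2) e^{i g3})
    # |B> = (sqrt(b),          sqrt((1-b)/2),          sqrt((1-b)/2))
    branch <- "rank1"
    p <- sqrt(mu_a * mu_b) # modulus of the M-overlap term
    tt <- sqrt((1 - mu_a) * (1 - mu_b)) # modulus of the orthogonal remainder
    intf <- mu_ab - fb$ave # required interference Re<A|M|B>
    if (p < eps) {
      # dev = 0 here, so intf = 0; any orthogonal phase split works
      delta <- pi / 2
      gamma <- c(0, pi + delta, pi - delta)
    } else {
      g1 <- acos(min(1, max(-1, intf / p)))
      delta <- acos(min(1, max(0, p / tt))) # p <= tt since mu_a + mu_b <= 1
      gamma <- c(g1, pi + g1 + delta, pi + g1 - delta)
    }
    state_a <- c(sqrt(mu_a), rep(sqrt((1 - mu_a) / 2), 2)) * exp(1i * gamma)
    state_b <- c(sqrt(mu_b), rep(sqrt((1 - mu_b) / 2), 2)) + 0i
    m <- canonical_projector(3, 1)
  } else {
    # rank-2 branch: M projects onto span(e1, e2);
    # |A> = (sqrt(a/2) e^{i g1}, sqrt(a/2) e^{i g2}, sqrt(1-a) e^{i g3})
    branch <- "rank2"
    p <- sqrt(mu_a * mu_b)
    tt <- sqrt((1 - mu_a) * (1 - mu_b))
    intf <- mu_ab - fb$ave
    if (p < eps && tt < eps) {
      gamma <- c(0, 0, 0) # (1,0)/(0,1) type pair: orthogonality is automatic
    } else if (tt < eps) {
      gamma <- c(pi / 2, -pi / 2, 0) # intf = 0 forced (dev = 0)
    } else {
      g3 <- acos(min(1, max(-1, -intf / tt)))
      delta <- acos(min(1, max(0, tt / p))) # tt <= p since mu_a + mu_b >= 1
      gamma <- c(pi + g3 + delta, pi + g3 - delta, g3)
    }
    state_a <- c(rep(sqrt(mu_a / 2), 2), sqrt(1 - mu_a)) * exp(1i * gamma)
    state_b <- c(rep(sqrt(mu_b / 2), 2), sqrt(1 - mu_b)) + 0i
    m <- canonical_projector(3, 2)
  }

  structure(
    list(
      state_a = state_a, state_b = state_b, projector = m,
      branch = branch, lambda = lambda, kappa = kappa, gamma = gamma,
      triplet = c(mu_a = mu_a, mu_b = mu_b, mu_ab = mu_ab)
    ),
    class = "first_sector_rep"
  )
}

#' Residuals of a first-sector representation
#'
#' Evaluates how well a representation satisfies the six defining
#' conditions: unit norms of the two states, their orthogonality, the two
#' marginal membership expectations, and the conjunction membership formula
#' `(mu_a + mu_b)/2 + Re<A|M|B> = mu_ab`.
#'
#' @param rep A `first_sector_rep` (or any list with `state_a`, `state_b`,
#'   `projector`, `triplet`).
#' @return A named numeric vector of absolute residuals: `norm_a`, `norm_b`,
#'   `orthogonality`, `mu_a`, `mu_b`, `mu_ab`, plus `projector` (deviation
#'   of `M` from a Hermitian idempotent).
#' @export
verify_first_sector <- function(rep) {
  a <- rep$state_a
  b <- rep$state_b
  m <- rep$projector
  tr <- rep$triplet
  c(
    norm_a = abs(Re(qip(a, a)) - 1),
    norm_b = abs(Re(qip(b, b)) - 1),
    orthogonality = Mod(qip(a, b)),
    mu_a = abs(Re(qip(a, m %*% a)) - tr[["mu_a"]]),
    mu_b = abs(Re(qip(b, m %*% b)) - tr[["mu_b"]]),
    mu_ab = abs((tr[["mu_a"]] + tr[["mu_b"]]) / 2 + Re(qip(a, m %*% b)) -
      tr[["mu_ab"]]),
    projector = max(Mod(m - Conj(t(m))), Mod(m %*% m - m))
  )
}

#' Fit first-sector representations to a dataset
#'
#' Runs [construct_first_sector()] on every triplet of the dataset,
#' recording per-exemplar feasibility; infeasible exemplars are kept in the
#' table (flagged, with no representation) so a pipeline can continue.
#'
#' @param data A data frame of membership triplets.
#' @param tol Feasibility boundary tolerance.
#' @return An object of class `first_sector_fit` with elements `data` (the
#'   triplets plus interval columns and `first_sector_feasible`), `reps`
#'   (named list of `first_sector_rep`, `NULL` where infeasible), and `tol`.
#'   Use [tidy()] for per-exemplar parameters and residuals.
#' @export
fit_first_sector <- function(data, tol = 1e-9) {
  data <- validate_triplets(data)
  tab <- feasibility_interval(data, tol = tol)
  reps <- purrr::pmap(
    list(tab$mu_a, tab$mu_b, tab$mu_ab, tab$first_sector_feasible),
    function(a, b, ab, ok) {
      if (!ok) {
        return(NULL)
      }
      construct_first_sector(a, b, ab, tol = tol)
    }
  )
  names(reps) <- tab$exemplar
  structure(list(data = tab, reps = reps, tol = tol),
    class = "first_sector_fit"
  )
}

#' Unify first-sector representations under one conceptual state pair
#'
#' Re-expresses every exemplar's representation in a single canonical basis:
#' the concept states become `|A> = (1,0,0)` and `|B> = (0,1,0)` for *all*
#' exemplars, and each exemplar keeps its own measurement projector
#' `M_i = U_i Mhat_i U_i^-1`, where `U_i` maps the exemplar's solved basis
#' `{|A_i>, |B_i>, |C_i>}` onto the canonical one. `|C_i>` is the complex
#' conjugate of the component-wise cross product of `|A_i>` and `|B_i>`,
#' normalised (orthogonal to both under the Hermitian inner product).
#' Unitarity preserves all membership expectations.
#'
#' @param fit A `first_sector_fit` in which every exemplar is feasible (fit
#'   or filter the data first otherwise).
#' @return An object of class `unified_first_sector`: `state_a`, `state_b`
#'   (canonical), `operators` (named list of 3 x 3 projectors), `unitaries`
#'   (the `U_i`), and `data`.
#' @export
unify_first_sector <- function(fit) {
  if (!inherits(fit, "first_sector_fit")) {
    abort("`fit` must be a `first_sector_fit` (see `fit_first_sector()`).")
  }
  bad <- fit$data$exemplar[!fit$data$first_sector_feasible]
  if (length(bad) > 0L) {
    abort(sprintf(
      "Cannot unify: exemplar%s %s lack a first-sector representation.",
      if (length(bad) > 1L) "s" else "", paste0('"', bad, '"', collapse = ", ")
    ), class = "fockconj_representability_error")
  }
  canon <- canonical_basis(3)
  ops <- list()
  us <- list()
  for (nm in names(fit$reps)) {
    r <- fit$reps[[nm]]
    cvec <- Conj(cross3(r$state_a, r$state_b))
    cvec <- fix_phase(cvec / vec_norm(cvec))
    u <- build_basis_change(list(r$state_a, r$state_b, cvec), canon)
    ops[[nm]] <- conjugate_operator(r$projector, u)
    us[[nm]] <- u
  }
  structure(
    list(
      state_a = canon[[1L]], state_b = canon[[2L]],
      operators = ops, unitaries = us, data = fit$data
    ),
    class = "unified_first_sector"
  )
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' @export
print.first_sector_fit <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf(
    "First-sector (C^3) fit: %d exemplar%s, %d representable\n",
    n, if (n == 1L) "" else "s", sum(x$data$first_sector_feasible)
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
print.unified_first_sector <- function(x, ...) {
  cat(sprintf(
    "Unified first-sector model: %d exemplar projectors on canonical |A>, |B>\n",
    length(x$operators)
  ))
  print(tidy(x))
  invisible(x)
}
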