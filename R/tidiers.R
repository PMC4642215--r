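# broom-style tidiers for the fitted objects.

#' Tidy a first-sector fit
#'
#' @param x A `first_sector_fit`.
#' @param ... Unused.
#' @return One row per exemplar: the triplet, feasibility interval, solver
#'   branch and phases, and the maximum condition residual.
#' @export
tidy.first_sector_fit <- function(x, ...) {
  res <- purrr::map(x$reps, function(r) {
    if (is.null(r)) {
      tibble(
        branch = NA_character_, lambda = NA_real_, kappa = NA_real_,
        gamma_1 = NA_real_, gamma_2 = NA_real_, gamma_3 = NA_real_,
        residual = NA_real_
      )
    } else {
      tibble(
        branch = r$branch, lambda = r$lambda, kappa = r$kappa,
        gamma_1 = r$gamma[1], gamma_2 = r$gamma[2], gamma_3 = r$gamma[3],
        residual = max(verify_first_sector(r))
      )
    }
  })
  dplyr::bind_cols(x$data, dplyr::bind_rows(res))
}

#' @rdname tidy.first_sector_fit
#' @export
glance.first_sector_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_exemplars = nrow(td),
    n_representable = sum(td$first_sector_feasible),
    max_residual = suppressWarnings(max(td$residual, na.rm = TRUE))
  )
}

#' Tidy a second-sector fit
#'
#' @param x A `second_sector_fit`.
#' @param ... Unused.
#' @return One row per exemplar with classicality, the four tensor
#'   coefficients, and the maximum expectation residual.
#' @export
tidy.second_sector_fit <- function(x, ...) {
  res <- purrr::map(x$reps, function(r) {
    if (is.null(r)) {
      tibble(
        c_11 = NA_real_, c_12 = NA_real_, c_21 = NA_real_, c_22 = NA_real_,
        residual = NA_real_
      )
    } else {
      cf <- r$coefficients
      tibble(
        c_11 = cf[1, 1], c_12 = cf[1, 2], c_21 = cf[2, 1], c_22 = cf[2, 2],
        residual = max(abs(tensor_expectations(r) - r$triplet))
      )
    }
  })
  dplyr::bind_cols(x$data, dplyr::bind_rows(res))
}

#' @rdname tidy.second_sector_fit
#' @export
glance.second_sector_fit <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_exemplars = nrow(td),
    n_representable = sum(td$is_classical),
    max_residual = suppressWarnings(max(td$residual, na.rm = TRUE))
  )
}

#' Tidy a unified first-sector model
#'
#' @param x A `unified_first_sector`.
#' @param ... Unused.
#' @return One row per exemplar: membership expectations recomputed from
#'   the shared canonical states and the exemplar's projector, and their
#'   deviation from the data.
#' @export
tidy.unified_first_sector <- function(x, ...) {
  rows <- purrr::imap(x$operators, function(m, nm) {
    a <- x$state_a
    b <- x$state_b
    mu_a <- Re(qip(a, m %*% a))
    mu_b <- Re(qip(b, m %*% b))
    mu_ab <- (mu_a + mu_b) / 2 + Re(qip(a, m %*% b))
    tibble(exemplar = nm, mu_a_hat = mu_a, mu_b_hat = mu_b, mu_ab_hat = mu_ab)
  })
  td <- dplyr::bind_rows(rows)
  td <- dplyr::left_join(
    td,
    x$data[c("exemplar", "mu_a", "mu_b", "mu_ab")],
    by = "exemplar"
  )
  dplyr::mutate(td, residual = pmax(
    abs(.data$mu_a_hat - .data$mu_a),
    abs(.data$mu_b_hat - .data$mu_b),
    abs(.data$mu_ab_hat - .data$mu_ab)
  ))
}

#' @rdname tidy.unified_first_sector
#' @export
glance.unified_first_sector <- function(x, ...) {
  td <- tidy(x)
  tibble(n_exemplars = nrow(td), max_residual = max(td$residual))
}

#' Tidy a zero-type tensor model
#'
#' @param x A `zero_type_model`.
#' @param ... Unused.
#' @return One row per exemplar: the three expectation values of the
#'   conjugated operators on the shared state, their deviation from the
#'   data, and the `first_type` factorisation flag.
#' @export
tidy.zero_type_model <- function(x, ...) {
  v <- x$state
  rows <- purrr::imap(x$operators, function(trip, nm) {
    tibble(
      exemplar = nm,
      mu_a_hat = Re(qip(v, trip$m_a %*% v)),
      mu_b_hat = Re(qip(v, trip$m_b %*% v)),
      mu_ab_hat = Re(qip(v, trip$m_and %*% v)),
      first_type = unname(x$first_type[nm])
    )
  })
  td <- dplyr::bind_rows(rows)
  td <- dplyr::left_join(
    td,
    x$data[c("exemplar", "mu_a", "mu_b", "mu_ab")],
    by = "exemplar"
  )
  dplyr::mutate(td, residual = pmax(
    abs(.data$mu_a_hat - .data$mu_a),
    abs(.data$mu_b_hat - .data$mu_b),
    abs(.data$mu_ab_hat - .data$mu_ab)
  ))
}

#' @rdname tidy.zero_type_model
#' @export
glance.zero_type_model <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_exemplars = nrow(td),
    n_first_type = sum(td$first_type),
    max_residual = max(td$residual)
  )
}
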