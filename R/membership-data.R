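# Membership-triplet data model: validation, CSV I/O, classicality
# classification (overextension taxonomy), JSON reports.

TRIPLET_COLS <- c("exemplar", "concept_a", "concept_b", "mu_a", "mu_b", "mu_ab")

#' Assemble a validated tibble of membership triplets
#'
#' A membership triplet records, for one exemplar `p` and a pair of concepts
#' `A` and `B`, the empirical membership weights `mu(A)`, `mu(B)` and
#' `mu(AB)` of `p` with respect to `A`, `B` and their conjunction `AB`. All
#' weights must lie in `[0, 1]`; 0 and 1 are legal. Weights are never
#' clamped: out-of-range values are an error naming the offending field and
#' row.
#'
#' @param exemplar Character vector of exemplar identifiers (unique).
#' @param mu_a,mu_b,mu_ab Membership weights in `[0, 1]`.
#' @param concept_a,concept_b Concept labels (recycled if scalar).
#' @return A tibble with columns `exemplar`, `concept_a`, `concept_b`,
#'   `mu_a`, `mu_b`, `mu_ab`.
#' @export
#' @examples
#' membership_triplets(
#'   exemplar = c("sailboat", "skateboard"),
#'   mu_a = c(0.56, 0.28), mu_b = c(0.8, 0.84), mu_ab = c(0.42, 0.34),
#'   concept_a = "Machine", concept_b = "Vehicle"
#' )
membership_triplets <- function(exemplar, mu_a, mu_b, mu_ab,
                                concept_a = "A", concept_b = "B") {
  data <- tibble(
    exemplar = as.character(exemplar),
    concept_a = as.character(concept_a),
    concept_b = as.character(concept_b),
    mu_a = as.numeric(mu_a),
    mu_b = as.numeric(mu_b),
    mu_ab = as.numeric(mu_ab)
  )
  validate_triplets(data)
}

#' Validate a data frame of membership triplets
#'
#' Checks the schema (all of `exemplar`, `concept_a`, `concept_b`, `mu_a`,
#' `mu_b`, `mu_ab` present), that every weight is a real number in
#' `[0, 1]`, and that exemplar identifiers are unique. Weights are never
#' clamped.
#'
#' @param data A data frame with the triplet columns.
#' @return The validated data as a tibble (column order normalised).
#' @export
validate_triplets <- function(data) {
  missing <- setdiff(TRIPLET_COLS, names(data))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Missing required column%s: %s.",
      if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ), class = "fockconj_schema_error")
  }
  data <- as_tibble(data)[TRIPLET_COLS]
  for (col in c("mu_a", "mu_b", "mu_ab")) {
    x <- data[[col]]
    if (!is.numeric(x) || anyNA(x)) {
      abort(sprintf("Column `%s` must be numeric with no missing values.", col),
        class = "fockconj_schema_error"
      )
    }
    bad <- which(x < 0 | x > 1)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Membership weight `%s` out of [0, 1] in row %d (exemplar \"%s\"): %g.",
        col, bad[1L], data$exemplar[bad[1L]], x[bad[1L]]
      ), class = "fockconj_validation_error")
    }
  }
  dup <- data$exemplar[duplicated(data$exemplar)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate exemplar identifier: \"%s\".", dup[1L]),
      class = "fockconj_schema_error"
    )
  }
  data
}

#' Read membership triplets from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `exemplar`,
#' `concept_a`, `concept_b`, `mu_a`, `mu_b`, `mu_ab` and one concept pair
#' per file. An empty file with a header yields an empty (zero-row) tibble.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of triplets in file order.
#' @export
read_membership_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  for (col in intersect(c("exemplar", "concept_a", "concept_b"), names(data))) {
    data[[col]] <- as.character(data[[col]])
  }
  if (nrow(data) == 0L) {
    for (col in intersect(c("mu_a", "mu_b", "mu_ab"), names(data))) {
      data[[col]] <- as.numeric(data[[col]])
    }
  }
  validate_triplets(data)
}

#' Classify membership triplets as classical or overextended
#'
#' A triplet is *classical conjunction data* -- representable by a
#' Kolmogorovian probability model -- if and only if
#' `mu(AB) <= mu(A)`, `mu(AB) <= mu(B)` and
#' `mu(A) + mu(B) - mu(AB) <= 1`. Violating the first (second) inequality is
#' overextension with respect to `A` (`B`); a single violation is *single
#' overextension*, both together *double overextension*; violating only the
#' third is the *Kolmogorovian factor violation*.
#'
#' @param data A data frame of membership triplets.
#' @param tol Numerical tolerance on the inequalities (violation means the
#'   slack is below `-tol`).
#' @return The input tibble with columns `slack_a`, `slack_b`, `slack_k`
#'   (raw inequality slacks), `overextended_a`, `overextended_b`,
#'   `kolmogorov_violation`, `is_classical`, and `category` (one of
#'   `"classical"`, `"single_overextension"`, `"double_overextension"`,
#'   `"kolmogorov_only"`).
#' @export
#' @examples
#' d <- membership_triplets("sailboat", 0.56, 0.8, 0.42)
#' check_classical(d)$is_classical # TRUE
check_classical <- function(data, tol = 1e-9) {
  data <- validate_triplets(data)
  out <- dplyr::mutate(data,
    slack_a = .data$mu_a - .data$mu_ab,
    slack_b = .data$mu_b - .data$mu_ab,
    slack_k = 1 - (.data$mu_a + .data$mu_b - .data$mu_ab),
    overextended_a = .data$slack_a < -tol,
    overextended_b = .data$slack_b < -tol,
    kolmogorov_violation = .data$slack_k < -tol,
    is_classical = !.data$overextended_a & !.data$overextended_b &
      !.data$kolmogorov_violation,
    category = dplyr::case_when(
      .data$overextended_a & .data$overextended_b ~ "double_overextension",
      .data$overextended_a | .data$overextended_b ~ "single_overextension",
      .data$kolmogorov_violation ~ "kolmogorov_only",
      TRUE ~ "classical"
    )
  )
  out
}

#' Write a per-exemplar report to JSON
#'
#' Serialises any tidy per-exemplar result table (classicality report,
#' Fock fit, compatibility matrix, ...) as a JSON array of records, with
#' numbers at 12 significant digits.
#'
#' @param report A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path,
    dataframe = "rows", auto_unbox = TRUE, digits = 12, pretty = TRUE
  )
  invisible(path)
}
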