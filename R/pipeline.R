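# End-to-end pipeline: classify -> represent (both sectors) -> unify ->
# compatibility -> Fock fit, with JSON reports.  The thin command-line
# wrapper in inst/cli/fockconj.R exposes the same steps as subcommands.

#' Run the full analysis pipeline on a membership CSV
#'
#' Reads a triplet CSV, classifies every exemplar, constructs first-sector
#' and tensor representations where feasible, unifies each sector's
#' representable exemplars under a single conceptual state, computes
#' pairwise compatibility matrices, fits the two-sector Fock formula, and
#' writes JSON reports. Infeasible exemplars are flagged in the tables and
#' the pipeline continues.
#'
#' @param input Path to a membership CSV (see [read_membership_csv()]).
#' @param out_dir Output directory for the JSON reports; created if needed.
#'   `NULL` skips writing.
#' @param sector `"both"`, `"first"` or `"second"`.
#' @param tol Numerical tolerance for all inequality checks.
#' @param verbose Log progress to standard error.
#' @return (Invisibly) a list with elements `classicality`, `feasibility`,
#'   `first_sector`, `second_sector`, `unified_first`, `zero_type`, `fock`,
#'   `compat_first`, `compat_second` (entries `NULL` where not applicable).
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         sector = c("both", "first", "second"),
                         tol = 1e-9, verbose = FALSE) {
  sector <- match.arg(sector)
  say <- function(...) if (verbose) message(sprintf(...))

  data <- read_membership_csv(input)
  say("Read %d triplets from %s", nrow(data), input)
  res <- list()
  res$classicality <- check_classical(data, tol = tol)
  res$feasibility <- feasibility_interval(data, tol = tol)
  res$fock <- fit_fock(data, tol = tol)

  if (nrow(data) > 0L && sector %in% c("both", "first")) {
    fit1 <- fit_first_sector(data, tol = tol)
    res$first_sector <- tidy(fit1)
    ok <- fit1$data$first_sector_feasible
    if (all(ok)) {
      res$unified_first <- unify_first_sector(fit1)
    } else if (sum(ok) >= 1L) {
      res$unified_first <- unify_first_sector(
        fit_first_sector(data[ok, ], tol = tol)
      )
    }
    if (!is.null(res$unified_first) &&
      length(res$unified_first$operators) >= 2L) {
      res$compat_first <- compatibility_matrix(res$unified_first)
    }
  }

  if (nrow(data) > 0L && sector %in% c("both", "second")) {
    fit2 <- fit_second_sector(data, tol = tol)
    res$second_sector <- tidy(fit2)
    ok <- fit2$data$is_classical
    if (sum(ok) >= 1L) {
      res$zero_type <- unify_zero_type(data[ok, ], tol = tol)
    }
    if (!is.null(res$zero_type) && length(res$zero_type$operators) >= 2L) {
      res$compat_second <- compatibility_matrix(res$zero_type)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      if (is.null(obj)) {
        return(invisible(NULL))
      }
      write_report(obj, file.path(out_dir, paste0(name, ".json")))
      say("Wrote %s.json", name)
    }
    wr(res$classicality, "classicality")
    wr(res$feasibility, "feasibility")
    wr(res$first_sector, "first_sector")
    wr(res$second_sector, "second_sector")
    wr(res$fock, "fock")
    if (!is.null(res$compat_first)) {
      wr(compat_json(res$compat_first), "compatibility_first")
    }
    if (!is.null(res$compat_second)) {
      wr(compat_json(res$compat_second), "compatibility_second")
    }
    if (!is.null(res$unified_first)) {
      jsonlite::write_json(
        unified_first_json(res$unified_first),
        file.path(out_dir, "unified_first.json"),
        auto_unbox = TRUE, digits = 12, pretty = TRUE
      )
    }
    if (!is.null(res$zero_type)) {
      jsonlite::write_json(
        zero_type_json(res$zero_type),
        file.path(out_dir, "zero_type.json"),
        auto_unbox = TRUE, digits = 12, pretty = TRUE
      )
    }
  }
  invisible(res)
}

# complex columns -> re/im pairs for JSON
compat_json <- function(compat) {
  out <- as_tibble(compat)
  for (col in c("c_a", "c_b", "c_ab")) {
    out[[paste0(col, "_re")]] <- Re(out[[col]])
    out[[paste0(col, "_im")]] <- Im(out[[col]])
    out[[col]] <- NULL
  }
  out
}

unified_first_json <- function(model) {
  list(
    state_a = complex_vec_to_json(model$state_a),
    state_b = complex_vec_to_json(model$state_b),
    operators = lapply(model$operators, complex_mat_to_json)
  )
}

zero_type_json <- function(model) {
  list(
    state = complex_vec_to_json(model$state),
    factor_dim = model$factor_dim,
    first_type = as.list(model$first_type),
    operators = lapply(model$operators, function(trip) {
      lapply(trip, complex_mat_to_json)
    })
  )
}
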