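# Deterministic synthetic-data generator.  Each regime draws triplets from
# a verifiable region of the (mu_a, mu_b, mu_ab) cube:
#   classical                 -- marginals of a uniform 4-atom probability
#                                mass function, so the three classicality
#                                inequalities hold by construction;
#   overextended_representable -- non-classical, yet inside the first-sector
#                                feasibility interval;
#   first_sector_infeasible   -- outside the feasibility interval;
#   independent               -- mu_ab = mu_a * mu_b exactly.

#' Simulate membership triplets by regime
#'
#' Draws `n` triplets from the requested region. `classical` samples a
#' 4-atom probability mass function `(p11, p12, p21, p22)` uniformly from
#' the simplex (sorted-uniform spacings) and marginalises (`mu_a = p11 +
#' p12`, `mu_b = p11 + p21`, `mu_ab = p11`); `overextended_representable`
#' rejection-samples `mu_ab` inside the first-sector feasibility interval
#' but exceeding `min(mu_a, mu_b)`; `first_sector_infeasible` samples
#' `mu_ab` outside the interval; `independent` sets `mu_ab = mu_a * mu_b`.
#' Output is deterministic for a fixed seed (the seed is part of the
#' contract: identical seeds give identical datasets).
#'
#' @param n Number of triplets.
#' @param regime One of `"classical"`, `"overextended_representable"`,
#'   `"first_sector_infeasible"`, `"independent"`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param concept_a,concept_b Concept labels.
#' @param max_tries Rejection-sampling cap per draw.
#' @return A validated tibble of membership triplets with exemplars
#'   `p001, p002, ...`.
#' @export
#' @examples
#' simulate_triplets(3, "classical", seed = 7)
simulate_triplets <- function(n,
                              regime = c(
                                "classical", "overextended_representable",
                                "first_sector_infeasible", "independent"
                              ),
                              seed = NULL,
                              concept_a = "A", concept_b = "B",
                              max_tries = 1e4) {
  regime <- match.arg(regime)
  if (n < 1) abort("`n` must be a positive integer.")
  draw <- function() {
    switch(regime,
      classical = {
        u <- sort(runif(3))
        p <- diff(c(0, u, 1))
        c(p[1] + p[2], p[1] + p[3], p[1])
      },
      independent = {
        a <- runif(1)
        b <- runif(1)
        c(a, b, a * b)
      },
      overextended_representable = {
        for (k in seq_len(max_tries)) {
          a <- runif(1)
          b <- runif(1)
          fb <- fs_bounds(a, b)
          floor_ab <- max(fb$lo, min(a, b))
          hi <- min(fb$hi, 1)
          if (hi <= floor_ab + 1e-6) next
          ab <- runif(1, floor_ab, hi)
          if (ab > min(a, b) + 1e-9) {
            return(c(a, b, ab))
          }
        }
        abort("Rejection-sampling cap reached for regime region.")
      },
      first_sector_infeasible = {
        for (k in seq_len(max_tries)) {
          a <- runif(1)
          b <- runif(1)
          fb <- fs_bounds(a, b)
          lo_room <- max(fb$lo, 0)
          hi_room <- min(fb$hi, 1)
          lengths <- c(lo_room, 1 - hi_room)
          if (sum(lengths) <= 1e-6) next
          if (runif(1) < lengths[1] / sum(lengths)) {
            ab <- runif(1, 0, lo_room - 1e-9 * lo_room)
            if (ab < fb$lo - 1e-9) {
              return(c(a, b, ab))
            }
          } else {
            ab <- runif(1, hi_room, 1)
            if (ab > fb$hi + 1e-9) {
              return(c(a, b, ab))
            }
          }
        }
        abort("Rejection-sampling cap reached for regime region.")
      }
    )
  }
  sample_all <- function() {
    trips <- t(vapply(seq_len(n), function(i) draw(), numeric(3)))
    membership_triplets(
      exemplar = sprintf("p%03d", seq_len(n)),
      mu_a = trips[, 1], mu_b = trips[, 2], mu_ab = trips[, 3],
      concept_a = concept_a, concept_b = concept_b
    )
  }
  if (is.null(seed)) sample_all() else withr::with_seed(seed, sample_all())
}
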