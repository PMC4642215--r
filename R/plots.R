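# ggplot2 displays for the main result types.

#' Plot membership triplets with their classicality category
#'
#' Dodged bars of `mu(A)`, `mu(B)` and `mu(AB)` per exemplar, coloured by
#' weight and faceted nowhere; the exemplar label carries its category.
#'
#' @param data A data frame of membership triplets (classified on the fly
#'   if the `category` column is absent).
#' @param tol Classicality tolerance, used only if classification is
#'   needed.
#' @return A ggplot object.
#' @export
plot_membership <- function(data, tol = 1e-9) {
  if (!"category" %in% names(data)) data <- check_classical(data, tol = tol)
  long <- tidyr::pivot_longer(
    data[c("exemplar", "category", "mu_a", "mu_b", "mu_ab")],
    cols = c("mu_a", "mu_b", "mu_ab"),
    names_to = "weight", values_to = "value"
  )
  long$weight <- factor(long$weight, levels = c("mu_a", "mu_b", "mu_ab"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$exemplar, y = .data$value, fill = .data$weight)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(. ~ category, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = NULL, y = "membership weight", fill = NULL,
      title = "Membership triplets by classicality category"
    ) +
    ggplot2::ylim(0, 1)
}

#' Plot first-sector feasibility intervals
#'
#' Per exemplar, the realisable interval of conjunction weights as a
#' vertical segment with the observed `mu(AB)` as a point; points outside
#' their segment are exemplars with no emergent-sector representation.
#'
#' @param data A data frame of membership triplets (interval columns are
#'   added on the fly if absent).
#' @param tol Feasibility tolerance.
#' @return A ggplot object.
#' @export
plot_feasibility <- function(data, tol = 1e-9) {
  if (!"fs_lo" %in% names(data)) data <- feasibility_interval(data, tol = tol)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$exemplar)) +
    ggplot2::geom_linerange(
      ggplot2::aes(ymin = .data$fs_lo, ymax = .data$fs_hi),
      linewidth = 3, colour = "grey70"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$mu_ab, colour = .data$first_sector_feasible),
      size = 2
    ) +
    ggplot2::labs(
      x = NULL, y = "mu(AB)", colour = "representable",
      title = "First-sector feasibility intervals"
    )
}

#' Heat map of a pairwise compatibility matrix
#'
#' @param object A `fockconj_compat` tibble from [compatibility_matrix()].
#' @param ... Unused.
#' @return A ggplot object: commutator-expectation magnitudes per exemplar
#'   pair, one panel per concept (`A`, `B`, conjunction).
#' @export
autoplot.fockconj_compat <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("exemplar_1", "exemplar_2", "mag_a", "mag_b", "mag_ab")],
    cols = c("mag_a", "mag_b", "mag_ab"),
    names_to = "concept", values_to = "magnitude"
  )
  long$concept <- factor(long$concept,
    levels = c("mag_a", "mag_b", "mag_ab"),
    labels = c("A", "B", "AB")
  )
  # mirror so the heat map is symmetric
  mirror <- long[long$exemplar_1 != long$exemplar_2, ]
  names(mirror)[1:2] <- c("exemplar_2", "exemplar_1")
  long <- dplyr::bind_rows(long, mirror)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$exemplar_1, y = .data$exemplar_2, fill = .data$magnitude)
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~concept) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "|<[M1,M2]>|",
      title = "Measurement incompatibility by exemplar pair"
    )
}
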