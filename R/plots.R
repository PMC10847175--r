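# ggplot2 views of the three result types users inspect most: segregation
# tables, insertion calls and the construct layout.

#' Plot observed vs expected segregation
#'
#' Bars of observed resistant fractions with the Mendelian expectation
#' overlaid, one panel row; controls are shown without an expectation line.
#'
#' @param records A segregation tibble (optionally already through
#'   [chisq_gof()]).
#' @return A ggplot object.
#' @export
plot_segregation <- function(records) {
  d <- records |>
    dplyr::mutate(
      cross = paste(.data$ovule_parent, "×", .data$pollen_parent),
      cross = make.unique(.data$cross),
      total = .data$n_resistant + .data$n_susceptible,
      obs = .data$n_resistant / .data$total,
      expected = purrr::map_dbl(.data$ratio, function(r) {
        if (is.na(r) || r %in% c("-", "")) return(NA_real_)
        p <- as.numeric(strsplit(r, ":", fixed = TRUE)[[1]])
        p[1] / sum(p)
      })
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cross, y = .data$obs)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected),
                        colour = "firebrick", shape = 95, size = 10,
                        na.rm = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction resistant",
                  title = "Observed segregation vs Mendelian expectation") +
    ggplot2::theme_minimal()
}

#' Plot insertion-call support
#'
#' One segment per call along its chromosome with strand-partitioned
#' support counts.
#'
#' @param calls An `insertion_calls` tibble.
#' @return A ggplot object.
#' @export
plot_insertion_calls <- function(calls) {
  d <- tibble::as_tibble(calls) |>
    tidyr::pivot_longer(c("support_fwd", "support_rev"),
                        names_to = "orientation", values_to = "support") |>
    dplyr::mutate(orientation = sub("support_", "", .data$orientation),
                  locus = sprintf("%s:%d-%d", .data$dest_ref, .data$start,
                                  .data$end))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$support,
                                  fill = .data$orientation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "supporting mates",
                  title = "T-DNA insertion calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a construct map
#'
#' Linearized feature track of a construct, one row per feature role.
#'
#' @param x A `construct_map`.
#' @return A ggplot object.
#' @export
plot_construct <- function(x) {
  stopifnot(inherits(x, "construct_map"))
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start, xend = .data$end,
                                  y = .data$name, yend = .data$name,
                                  colour = .data$role)) +
    ggplot2::geom_segment(linewidth = 5) +
    ggplot2::labs(x = "construct position (bp)", y = NULL,
                  title = sprintf("%d bp %s construct", x$length,
                                  if (x$is_circular) "circular" else "linear")) +
    ggplot2::theme_minimal()
}
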