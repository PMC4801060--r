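# ggplot2 views of fitted objects. Violin-style posterior plots are drawn
# from the discretized masses directly (bar per bin), faithful to the
# grid the inference ran on.

.unnest_mass <- function(fit, values) {
  as_tibble(fit) %>%
    mutate(.bin = purrr::map(.data$mass, ~ values),
           .mass = .data$mass) %>%
    select("lsv_id", "junction_id", ".bin", ".mass") %>%
    tidyr::unnest(c(".bin", ".mass"))
}

#' @rdname plot_psi
#' @param object A `psi_fit`.
#' @param ... Unused.
#' @export
autoplot.psi_fit <- function(object, ...) plot_psi(object, ...)

#' Plot discretized PSI posteriors
#'
#' @param fit A `psi_fit` tibble.
#' @param lsv_ids Optional subset of LSVs to plot.
#' @return A ggplot: per-junction posterior mass over the PSI grid,
#'   faceted by LSV.
#' @export
plot_psi <- function(fit, lsv_ids = NULL) {
  if (!is.null(lsv_ids)) fit <- fit %>% filter(.data$lsv_id %in% lsv_ids)
  V <- attr(fit, "V") %||% (length(fit$mass[[1]]))
  long <- .unnest_mass(fit, .bin_centers(V))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.bin, y = .data$.mass,
                                     fill = .data$junction_id)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = 1 / V) +
    ggplot2::facet_wrap(~lsv_id) +
    ggplot2::labs(x = expression(Psi), y = "posterior mass",
                  fill = "junction") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dpsi
#' @param object A `dpsi_fit`.
#' @param ... Unused.
#' @export
autoplot.dpsi_fit <- function(object, ...) plot_dpsi(object, ...)

#' Plot discretized dPSI posteriors
#'
#' @param fit A `dpsi_fit` tibble.
#' @param lsv_ids Optional subset of LSVs to plot.
#' @return A ggplot of the posterior mass over the dPSI grid.
#' @export
plot_dpsi <- function(fit, lsv_ids = NULL) {
  if (!is.null(lsv_ids)) fit <- fit %>% filter(.data$lsv_id %in% lsv_ids)
  V <- attr(fit, "V") %||% ((length(fit$mass[[1]]) + 1) / 2)
  long <- .unnest_mass(fit, .dpsi_values(V))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.bin, y = .data$.mass,
                                     fill = .data$junction_id)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = 1 / V) +
    ggplot2::facet_wrap(~lsv_id) +
    ggplot2::labs(x = expression(Delta * Psi), y = "posterior mass",
                  fill = "junction") +
    ggplot2::theme_minimal()
}

#' @rdname plot_rr
#' @param object An `rr_curve`.
#' @param ... Unused.
#' @export
autoplot.rr_curve <- function(object, ...) plot_rr(object, ...)

#' Plot a reproducibility-ratio curve
#'
#' @param rr An `rr_curve` tibble (or several bound together with a
#'   distinguishing `run` column).
#' @return A ggplot of RR(n) against rank n.
#' @export
plot_rr <- function(rr) {
  p <- ggplot2::ggplot(rr, ggplot2::aes(x = .data$n, y = .data$rr))
  if ("run" %in% names(rr)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data$run))
  } else {
    p <- p + ggplot2::geom_line(color = "#4263eb")
  }
  p + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "rank n", y = "RR(n)") +
    ggplot2::theme_minimal()
}
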