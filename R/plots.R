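# ggplot2 quick-look plots for each result type.

regime_palette <- c(EXTINCTION = "#b2182b", COOP_LIKELY = "#fddbc7",
                    PURE_COOP = "#2166ac", COEXISTENCE = "#67a9cf")

#' Plot a replicate trajectory
#'
#' Cooperator frequency and population occupancy over the generations of a
#' single replicate.
#'
#' @param object A `deme_replicate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deme_replicate <- function(object, ...) {
  df <- object$trajectory |>
    dplyr::mutate(occupancy = .data$total_size /
                    (object$params$N0 * object$params$D)) |>
    tidyr::pivot_longer(c("rho", "occupancy"),
                        names_to = "observable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$value,
                                   colour = .data$observable)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(rho = "#2166ac", occupancy = "grey50"),
      labels = c(rho = "cooperator frequency", occupancy = "occupancy")) +
    ggplot2::labs(x = "generation", y = NULL, colour = NULL,
                  title = paste0("Replicate seed ", object$seed, ": ",
                                 object$outcome)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a migration sweep
#'
#' Fixation and coexistence probability (with binomial standard-error bars)
#' against the migration rate, plus the conditional cooperation level.
#'
#' @param object A `deme_sweep` tibble from [sweep_migration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deme_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("p_coop", "p_coex", "mean_rho"),
                        names_to = "observable", values_to = "value") |>
    dplyr::mutate(se = dplyr::case_when(
      .data$observable == "p_coop" ~ .data$p_coop_se,
      .data$observable == "p_coex" ~ .data$p_coex_se,
      TRUE ~ NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$value,
                                   colour = .data$observable)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$se,
                                          ymax = .data$value + .data$se),
                             na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "migration rate m", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase diagram
#'
#' Regime tiles over the scanned (migration rate, deme number) grid, with
#' the critical deme number marked when found.
#'
#' @param object A `deme_phase` from [phase_diagram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deme_phase <- function(object, ...) {
  df <- object$phase |>
    dplyr::mutate(m = factor(.data$m), D = factor(.data$D))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$D,
                                        fill = .data$regime)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = regime_palette, drop = FALSE) +
    ggplot2::labs(x = "migration rate m", y = "number of demes D",
                  title = paste0("Phase diagram (D_c = ",
                                 ifelse(is.na(object$D_c), "not found",
                                        object$D_c), ")")) +
    ggplot2::theme_minimal()
  if (!is.na(object$D_c)) {
    p <- p + ggplot2::geom_hline(
      yintercept = which(levels(df$D) == as.character(object$D_c)) - 0.5,
      linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a topology comparison
#'
#' Conditional cooperation level against migration rate, one curve per
#' migration-network topology.
#'
#' @param object A `deme_topology` tibble from [compare_topologies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deme_topology <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$m, .data$mean_rho,
                               colour = .data$topology)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "migration rate m",
                  y = "cooperator frequency given persistence",
                  colour = "topology") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Fixation probability against migration rate, one curve per elimination
#' threshold.
#'
#' @param object A `deme_threshold` from [sweep_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deme_threshold <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object$sweeps), E = factor(.data$E))
  ggplot2::ggplot(df,
                  ggplot2::aes(.data$m, .data$p_coop, colour = .data$E)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "migration rate m", y = "P(fixation of cooperation)",
                  colour = "threshold E") +
    ggplot2::theme_minimal()
}

#' @export
plot.deme_replicate <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.deme_phase <- function(x, ...) print(autoplot(x, ...))
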