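#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FBA result into a flux table
#'
#' @param x an `fba_result` from [solve_fba()].
#' @param ... unused.
#' @return a tibble `reaction`, `flux`.
#' @export
tidy.fba_result <- function(x, ...) x$fluxes

#' One-row summary of an FBA result
#'
#' @inheritParams tidy.fba_result
#' @return a tibble `status`, `objective_value`, `n_reactions`.
#' @export
glance.fba_result <- function(x, ...) {
  tibble::tibble(status = x$status, objective_value = x$objective_value,
                 n_reactions = nrow(x$fluxes))
}

#' Tidy a steady-state analysis into its constraint table
#'
#' @param x an `rsa_result` from [run_rsa()].
#' @param ... unused.
#' @return the `qf_steady_state` tibble (`component`, `type`, `lb`, `ub`,
#'   `value`).
#' @export
tidy.rsa_result <- function(x, ...) x$steady_state

#' One-row summary of a steady-state analysis
#'
#' @inheritParams tidy.rsa_result
#' @return a tibble `kind`, `attractor_size`, `n_components`.
#' @export
glance.rsa_result <- function(x, ...) {
  tibble::tibble(kind = x$attractor$kind,
                 attractor_size = length(x$attractor$states),
                 n_components = nrow(x$steady_state))
}

#' Plot a time-dependent FBA trajectory
#'
#' Cell density and each tracked external concentration against time,
#' reproducing the usual diauxic-growth panel.
#'
#' @param object an `fba_trajectory` from [time_dependent_fba()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fba_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), -"mu"),
    -"t", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)",
                  y = "cell density (g/l) / concentration (mmol/l)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phenotypic phase grid
#'
#' One varied flux: objective against the flux, coloured by phase. Two varied
#' fluxes: phase map as a tile plot.
#'
#' @param object a `phase_grid` from [phenotype_phases()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phase_grid <- function(object, ...) {
  axes <- setdiff(names(object), c("objective", "shadow_price_1",
                                   "shadow_price_2", "phase", "status"))
  df <- tibble::as_tibble(object)
  df$phase <- factor(df$phase)
  if (length(axes) == 1L) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                     y = .data$objective,
                                     colour = .data$phase)) +
      ggplot2::geom_point() +
      ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey50") +
      ggplot2::labs(x = paste(axes[1], "flux (mmol/(gDW h))"),
                    y = "objective") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[axes[1]]],
                                     y = .data[[axes[2]]],
                                     fill = .data$phase)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = axes[1], y = axes[2]) +
      ggplot2::theme_minimal()
  }
}

#' Plot an attractor census
#'
#' Frequencies of the most common attractors, the long tail grouped as
#' "other".
#'
#' @param object an `attractor_census` from [multi_rsa_census()].
#' @param top number of attractors shown individually.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.attractor_census <- function(object, top = 12, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) > top) {
    head_df <- df[seq_len(top), c("attractor_id", "frequency")]
    rest <- sum(df$frequency[-seq_len(top)])
    head_df <- dplyr::bind_rows(head_df,
                                tibble::tibble(attractor_id = "other",
                                               frequency = rest))
  } else {
    head_df <- df[, c("attractor_id", "frequency")]
  }
  head_df$attractor_id <- factor(head_df$attractor_id,
                                 levels = head_df$attractor_id)
  ggplot2::ggplot(head_df, ggplot2::aes(x = .data$attractor_id,
                                        y = .data$frequency)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "frequency of initial conditions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
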