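#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a woven system
#'
#' @param x A `cw_woven`.
#' @param ... Unused.
#' @return One row per part of the woven flow: position, compartment path,
#'   type, name, coded molecule, regulators and provenance.
#' @export
tidy.cw_woven <- function(x, ...) {
  parts <- flow_parts(x$flow)
  tibble::tibble(
    flow_index = parts$flow_index,
    compartment = vapply(parts$path, paste, character(1), collapse = "."),
    part_type = parts$part_type,
    name = parts$name,
    codes_for = parts$codes_for,
    regulators = vapply(parts$regulation, function(rs) {
      paste(vapply(rs, `[[`, character(1), "molecule"), collapse = ",")
    }, character(1)),
    provenance = parts$provenance
  )
}

#' @rdname tidy.cw_woven
#' @export
glance.cw_woven <- function(x, ...) {
  parts <- flow_parts(x$flow)
  tibble::tibble(
    n_parts = nrow(parts),
    n_design = sum(parts$provenance == "design"),
    n_advised = sum(parts$provenance != "design"),
    n_molecules = sum(x$flow$kind == "molecule"),
    n_properties = nrow(x$properties),
    aspects = paste(x$aspects, collapse = ",")
  )
}

#' Tidy a reaction model
#'
#' @param x A `cw_reaction_model`.
#' @param ... Unused.
#' @return One row per reaction with formatted reactant/product sides, rate
#'   law, parameter name and value.
#' @export
tidy.cw_reaction_model <- function(x, ...) {
  tibble::tibble(
    reaction = x$reactions$name,
    reactants = vapply(x$reactions$reactants, format_side, character(1)),
    products = vapply(x$reactions$products, format_side, character(1)),
    rate_law = x$reactions$rate_law,
    parameter = x$reactions$parameter,
    value = vapply(x$reactions$parameter, function(p) {
      if (is.na(p)) NA_real_ else x$parameters[[p]]
    }, numeric(1)),
    category = x$reactions$category
  )
}

#' @rdname tidy.cw_reaction_model
#' @export
glance.cw_reaction_model <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy,
    n_species = nrow(x$species),
    n_reactions = nrow(x$reactions),
    n_parameters = length(x$parameters),
    n_observables = length(x$observables)
  )
}

#' Tidy a trajectory into long format
#'
#' @param x A `cw_trajectory`.
#' @param ... Unused.
#' @return Long tibble with columns `time`, `species`, `value`.
#' @export
tidy.cw_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "species", values_to = "value")
}

#' Plot a trajectory
#'
#' @param object A `cw_trajectory`.
#' @param species Optional character vector restricting the columns shown.
#' @param ... Unused.
#' @return A ggplot: one line per species over time.
#' @export
autoplot.cw_trajectory <- function(object, species = NULL, ...) {
  long <- tidy.cw_trajectory(object)
  if (!is.null(species)) long <- long[long$species %in% species, , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname tidy.cw_woven
#' @param object A `cw_woven` (for `autoplot`).
#' @export
autoplot.cw_woven <- function(object, ...) {
  df <- tidy.cw_woven(object)
  df$glyph <- factor(df$part_type)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flow_index, y = 0,
                                   shape = .data$glyph,
                                   colour = .data$provenance)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), angle = 45,
                       nudge_y = 0.08, size = 3, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(-0.2, 0.3), breaks = NULL) +
    ggplot2::labs(x = "flow position", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname run_switchable_scenario
#' @param x A `cw_switch_report` (for `tidy`).
#' @param ... Unused.
#' @export
tidy.cw_switch_report <- function(x, ...) {
  tibble::tibble(
    window = c("pre", "post"),
    oscillating = c(x$pre$oscillating, x$post$oscillating),
    n_peaks = c(x$pre$n_peaks, x$post$n_peaks),
    period = c(x$pre$period, x$post$period),
    switch_level = c(x$switch_level_pre, x$switch_level_post)
  )
}

#' @importFrom rlang .data
NULL
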