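#' Formatted stage-pKa report
#'
#' Renders the macroscopic pKa ladder (stages 0-3 and delta pKa) for one or
#' more parameter sets, rounded half-up to one decimal for display, and
#' optionally writes the full-precision values to CSV.
#'
#' @param params A [thermo_params] or list of them.
#' @param csv Optional path; if given, the full-precision table is written
#'   there.
#' @return The full-precision [pka_table()] tibble, invisibly; the rounded
#'   table is printed.
#' @export
report_pka_table <- function(params, csv = NULL) {
  tbl <- pka_table(params)
  if (!is.null(csv)) readr::write_csv(tbl, csv)
  if (nrow(tbl) > 0) {
    disp <- tbl
    num <- vapply(disp, is.numeric, logical(1))
    disp[num] <- lapply(disp[num], round_half_up, digits = 1)
    print(as.data.frame(disp), row.names = FALSE)
  } else {
    message("no proteins given; empty pKa table")
  }
  invisible(tbl)
}

# round half away from zero (display convention; base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Formatted thermodynamic-parameter matrix
#'
#' Renders the parameters as an upper-triangular matrix: oxidation and
#' deprotonation energies on the diagonal (marked with `*`), interaction
#' energies off-diagonal, standard errors in parentheses when available.
#' Values in meV, rounded to integers for display.
#'
#' @param x A [thermo_params] or a `redox_fit`.
#' @return A character matrix (also printed), invisibly.
#' @export
report_params_table <- function(x) {
  if (inherits(x, "redox_fit")) {
    params <- x$params
    se <- x$std_error
  } else {
    stopifnot(inherits(x, "thermo_params"))
    params <- x
    se <- NULL
  }
  labs <- c("Heme I", "Heme III", "Heme IV", "Redox-Bohr center")
  m <- matrix("", 4, 4, dimnames = list(labs, labs))
  fmt <- function(value, se_name, diag = FALSE) {
    s <- sprintf("%d", round(value))
    if (!is.null(se) && !is.na(se[se_name])) {
      s <- sprintf("%s (%d)", s, max(1L, as.integer(round(se[se_name]))))
    }
    if (diag) paste0("*", s, "*") else s
  }
  m[1, 1] <- fmt(params$g_ox["I"], "g_ox_I", diag = TRUE)
  m[2, 2] <- fmt(params$g_ox["III"], "g_ox_III", diag = TRUE)
  m[3, 3] <- fmt(params$g_ox["IV"], "g_ox_IV", diag = TRUE)
  m[4, 4] <- fmt(params$g_h, "g_H", diag = TRUE)
  m[1, 2] <- fmt(params$i_redox["I-III"], "i_redox_I-III")
  m[1, 3] <- fmt(params$i_redox["I-IV"], "i_redox_I-IV")
  m[2, 3] <- fmt(params$i_redox["III-IV"], "i_redox_III-IV")
  m[1, 4] <- fmt(params$i_bohr["I"], "i_bohr_I")
  m[2, 4] <- fmt(params$i_bohr["III"], "i_bohr_III")
  m[3, 4] <- fmt(params$i_bohr["IV"], "i_bohr_IV")
  if (!is.null(params$protein)) cat(params$protein, "(energies in meV)\n")
  print(m, quote = FALSE)
  invisible(m)
}

#' Export oxidation and microstate curves, with route annotation
#'
#' Evaluates [oxidation_curves()] on a grid, optionally writes the CSV, and
#' attaches the dominant-microstate route as an attribute.
#'
#' @inheritParams oxidation_curves
#' @param csv Optional output CSV path.
#' @return The curves tibble with attribute `"route"` (character vector of
#'   microstate labels).
#' @export
report_curves <- function(params, ph = 7,
                          potentials = seq(-300, 150, by = 1), csv = NULL) {
  curves <- oxidation_curves(params, ph = ph, potentials = potentials)
  route <- tryCatch(
    dominant_microstate_route(params, ph = ph, e_grid = potentials),
    error = function(e) NULL)
  if (!is.null(csv)) readr::write_csv(curves, csv)
  if (!is.null(route)) {
    message("dominant microstate route: ", paste(route, collapse = " -> "))
  }
  attr(curves, "route") <- route
  curves
}

#' Plot per-heme oxidation curves
#'
#' @inheritParams oxidation_curves
#' @return A ggplot object: oxidation fraction of each heme vs solution
#'   potential.
#' @export
plot_oxidation_curves <- function(params, ph = 7,
                                  potentials = seq(-300, 150, by = 2)) {
  curves <- oxidation_curves(params, ph = ph, potentials = potentials)
  long <- tidyr::pivot_longer(
    curves[, c("potential_mV", "frac_ox_I", "frac_ox_III", "frac_ox_IV")],
    -"potential_mV", names_to = "heme", values_to = "fraction",
    names_prefix = "frac_ox_")
  ggplot2::ggplot(long, ggplot2::aes(.data$potential_mV, .data$fraction,
                                     colour = .data$heme)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "solution potential (mV vs SHE)",
                  y = "oxidized fraction",
                  colour = "heme",
                  title = params$protein %||% NULL,
                  subtitle = sprintf("pH %g", ph)) +
    ggplot2::theme_minimal()
}

#' Plot microstate molar fractions vs solution potential
#'
#' @inheritParams oxidation_curves
#' @param min_fraction Microstates whose fraction never reaches this value
#'   are dropped from the plot for clarity.
#' @return A ggplot object; protonated microstates as solid lines,
#'   deprotonated as dashed.
#' @export
plot_microstate_fractions <- function(params, ph = 7,
                                      potentials = seq(-300, 150, by = 2),
                                      min_fraction = 0.05) {
  ens <- ensemble(params, potentials, ph)
  keep <- dplyr::group_by(ens, .data$label)
  keep <- dplyr::filter(keep, max(.data$fraction) >= min_fraction)
  keep <- dplyr::ungroup(keep)
  ggplot2::ggplot(keep, ggplot2::aes(.data$potential_mV, .data$fraction,
                                     colour = .data$label,
                                     linetype = .data$deprotonated)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed")) +
    ggplot2::labs(x = "solution potential (mV vs SHE)",
                  y = "molar fraction", colour = "microstate",
                  linetype = "deprotonated",
                  title = params$protein %||% NULL,
                  subtitle = sprintf("pH %g", ph)) +
    ggplot2::theme_minimal()
}

#' Plot a fit against its data
#'
#' @param object A `redox_fit`.
#' @param ... Unused.
#' @return A ggplot object with two panels: chemical shift vs pH per stage
#'   and probe (points: data; lines: fitted model) and reduced fraction vs
#'   potential per pH.
#' @export
autoplot.redox_fit <- function(object, ...) {
  problem <- object$problem
  nmr <- problem$nmr
  ph_grid <- seq(min(nmr$pH), max(nmr$pH), length.out = 61)
  pred <- tidyr::expand_grid(probe_id = unique(nmr$probe_id),
                             stage = sort(unique(nmr$stage)), pH = ph_grid)
  pred$shift_ppm <- predicted_shift(object$params, object$probes,
                                    pred$probe_id, pred$stage, pred$pH)
  p1 <- ggplot2::ggplot(nmr, ggplot2::aes(.data$pH, .data$shift_ppm,
                                          colour = factor(.data$stage))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = pred) +
    ggplot2::facet_wrap(~probe_id, scales = "free_y") +
    ggplot2::labs(y = "chemical shift (ppm)", colour = "stage") +
    ggplot2::theme_minimal()
  if (is.null(problem$vis)) return(p1)
  vis <- problem$vis
  e_grid <- seq(min(vis$potential_mV), max(vis$potential_mV),
                length.out = 121)
  vpred <- tidyr::expand_grid(pH = unique(vis$pH), potential_mV = e_grid)
  vpred$reduced_fraction <- predicted_reduced_fraction(
    object$params, vpred$potential_mV, vpred$pH)
  p2 <- ggplot2::ggplot(vis, ggplot2::aes(.data$potential_mV,
                                          .data$reduced_fraction,
                                          colour = factor(.data$pH))) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = vpred) +
    ggplot2::labs(x = "solution potential (mV vs SHE)",
                  y = "reduced fraction", colour = "pH") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 1)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
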