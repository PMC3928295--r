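## Tidy (broom-style) accessors and plotting for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an energy report into a term table
#'
#' @param x an `energy_report`.
#' @param ... unused.
#' @return a tibble with one row per term (`term`, `fragments`, `hartree`,
#'   `kcal_mol`).
#' @export
tidy.energy_report <- function(x, ...) {
  tibble::as_tibble(x$breakdown)
}

#' One-row summary of an energy report
#'
#' @param x an `energy_report`.
#' @param ... unused.
#' @return a one-row tibble with the assembled totals in Hartree.
#' @export
glance.energy_report <- function(x, ...) {
  tibble::tibble(level = x$level, monomer_sum = x$monomer_sum,
                 qm_dimer_sum = x$qm_dimer_sum,
                 pair_pol_correction = x$pair_pol_correction,
                 far_pair_sum = x$far_pair_sum,
                 total_classical_pol = x$total_classical_pol,
                 mp2_correction = x$mp2_correction, total = x$total)
}

#' Tidy a reaction path into a path table
#'
#' @param x a `reaction_path` from [scan_reaction_path()].
#' @param ... unused.
#' @return a tibble with `scan_index`, `r1_target`, `r2_target`,
#'   `reaction_coordinate` (Angstrom), `energy_hartree`, `delta_kcal`
#'   (relative to the first point), `n_steps` and `converged`.
#' @export
tidy.reaction_path <- function(x, ...) {
  e <- vapply(x$points, function(p) p$energy_report$total, 1.0)
  tibble::tibble(
    scan_index = vapply(x$points, function(p) p$scan_index, 1L),
    r1_target = x$scan_targets$r1_target,
    r2_target = x$scan_targets$r2_target,
    reaction_coordinate = vapply(x$points,
                                 function(p) p$reaction_coordinate, 1.0),
    energy_hartree = e,
    delta_kcal = hartree_to_kcal(e - e[1]),
    n_steps = vapply(x$points, function(p) p$n_steps, 1L),
    converged = vapply(x$points, function(p) p$converged, TRUE))
}

#' One-row summary of a reaction path
#'
#' @param x a `reaction_path`.
#' @param ... unused.
#' @return a one-row tibble with the barrier, reaction energy (kcal/mol),
#'   transition-state coordinate and convergence counts.
#' @export
glance.reaction_path <- function(x, ...) {
  b <- barrier_and_reaction_energy(x)
  tibble::tibble(n_points = length(x$points),
                 barrier_kcal = b$barrier_kcal,
                 reaction_energy_kcal = b$reaction_energy_kcal,
                 ts_coordinate = b$ts_coordinate,
                 n_converged = sum(vapply(x$points,
                                          function(p) p$converged, TRUE)))
}

#' Plot a reaction path profile
#'
#' Electronic energy (relative to the first point, kcal/mol) versus the
#' reaction coordinate.
#'
#' @param object a `reaction_path`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.reaction_path <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reaction_coordinate,
                                   y = .data$delta_kcal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::labs(x = "reaction coordinate R (Å)",
                  y = expression(Delta * E ~ "(kcal/mol)"),
                  shape = "converged") +
    ggplot2::theme_minimal()
}

#' @export
print.reaction_path <- function(x, ...) {
  cat(sprintf("<reaction_path> %d points\n", length(x$points)))
  print(tidy(x))
  invisible(x)
}

#' @export
print.path_point <- function(x, ...) {
  cat(sprintf(
    "<path_point> scan %s: E = %.10f Hartree, R = %s, %d steps, %s\n",
    ifelse(is.na(x$scan_index), "-", as.character(x$scan_index)),
    x$energy_report$total,
    ifelse(is.na(x$reaction_coordinate), "NA",
           sprintf("%.3f A", x$reaction_coordinate)),
    x$n_steps, ifelse(x$converged, "converged", "NOT converged")))
  invisible(x)
}
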