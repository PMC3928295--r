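## Run configuration: levels of theory, dimer cutoff, restraint and
## convergence settings.  Validated eagerly so misconfiguration fails before
## any computation starts.

#' Create a run configuration
#'
#' @param rhf_basis basis label used for every RHF fragment calculation.
#' @param mp2_basis basis label for the MP2 treatment of the high-level
#'   fragment; defaults to `rhf_basis`.
#' @param dimer_cutoff unitless relative-distance dimer cutoff: a fragment
#'   pair is computed quantum mechanically when the minimum interatomic
#'   distance divided by the sum of Bondi van der Waals radii is at most this
#'   value (default 1.5); beyond it the pair interacts classically.
#' @param polarization_enabled include classical induced-dipole polarization.
#' @param fdd_enabled frozen-domain-and-dimers caching: frozen-domain records
#'   are computed at most once per run.
#' @param hybrid_enabled add the MP2 correlation energy/gradient of the
#'   high-level fragment on top of the RHF expansion.
#' @param gradient_tolerance optimizer convergence threshold on the gradient
#'   (Hartree/Bohr), applied to the measure chosen by `convergence_measure`.
#' @param convergence_measure `"max"` (default) or `"rms"` gradient component.
#' @param max_opt_steps maximum quasi-Newton steps per restrained optimization.
#' @param restraint_force_constant harmonic distance-restraint force constant
#'   in kcal mol^-1 Angstrom^-2 (default 500).
#' @param pol_tolerance induced-dipole Jacobi solver tolerance (a.u.).
#' @param pol_max_iter maximum Jacobi iterations.
#' @param pol_damping optional Thole-style exponential damping parameter;
#'   `NULL` (default) disables damping.
#' @param pol_domain `"all"` (polarization spans F, b and A; default) or
#'   `"active_buffer"` (spans b and A only).
#' @param backend backend registry key (default `"mock"`).
#' @param random_seed integer seed for any stochastic option (none are on by
#'   default); kept for reproducibility bookkeeping.
#' @return an object of class `run_config`.
#' @export
run_config <- function(rhf_basis = "6-31G(d)",
                       mp2_basis = rhf_basis,
                       dimer_cutoff = 1.5,
                       polarization_enabled = TRUE,
                       fdd_enabled = TRUE,
                       hybrid_enabled = TRUE,
                       gradient_tolerance = 1.0e-4,
                       convergence_measure = c("max", "rms"),
                       max_opt_steps = 200L,
                       restraint_force_constant = 500,
                       pol_tolerance = 1.0e-10,
                       pol_max_iter = 200L,
                       pol_damping = NULL,
                       pol_domain = c("all", "active_buffer"),
                       backend = "mock",
                       random_seed = 1L) {
  cfg <- list(rhf_basis = rhf_basis, mp2_basis = mp2_basis,
              dimer_cutoff = dimer_cutoff,
              polarization_enabled = isTRUE(polarization_enabled),
              fdd_enabled = isTRUE(fdd_enabled),
              hybrid_enabled = isTRUE(hybrid_enabled),
              gradient_tolerance = gradient_tolerance,
              convergence_measure = match.arg(convergence_measure),
              max_opt_steps = as.integer(max_opt_steps),
              restraint_force_constant = restraint_force_constant,
              pol_tolerance = pol_tolerance,
              pol_max_iter = as.integer(pol_max_iter),
              pol_damping = pol_damping,
              pol_domain = match.arg(pol_domain),
              backend = backend,
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) abort_config(msg)
  chk(is.character(cfg$rhf_basis) && nzchar(cfg$rhf_basis),
      "rhf_basis must be a non-empty string")
  chk(is.character(cfg$mp2_basis) && nzchar(cfg$mp2_basis),
      "mp2_basis must be a non-empty string")
  chk(is.numeric(cfg$dimer_cutoff) && cfg$dimer_cutoff > 0,
      "dimer_cutoff must be > 0")
  chk(is.numeric(cfg$gradient_tolerance) && cfg$gradient_tolerance > 0,
      "gradient_tolerance must be > 0")
  chk(is.numeric(cfg$restraint_force_constant) &&
        cfg$restraint_force_constant >= 0,
      "restraint_force_constant must be >= 0")
  chk(cfg$max_opt_steps >= 1L, "max_opt_steps must be >= 1")
  chk(cfg$pol_tolerance > 0, "pol_tolerance must be > 0")
  chk(cfg$pol_max_iter >= 1L, "pol_max_iter must be >= 1")
  chk(is.null(cfg$pol_damping) ||
        (is.numeric(cfg$pol_damping) && cfg$pol_damping > 0),
      "pol_damping must be NULL or a positive number")
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are rejected so
#' typos fail fast.  An optional `scan:` block (used by [run_scan()]) carries
#' `breaking_pair` and `forming_pair` as 0-based atom index pairs plus a
#' `targets` list of `[r1, r2]` distances in Angstrom.
#'
#' @param path path to a YAML config file.
#' @return a list with `config` (a [run_config()]) and `scan` (list or `NULL`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("no such config file: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_config(conditionMessage(e)))
  raw <- raw %||% list()
  scan <- raw$scan
  raw$scan <- NULL
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    abort_config(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  cfg <- do.call(run_config, raw)
  if (!is.null(scan)) {
    for (key in c("breaking_pair", "forming_pair", "targets"))
      if (is.null(scan[[key]]))
        abort_config(sprintf("scan block lacks '%s'", key))
    scan$breaking_pair <- as.integer(scan$breaking_pair) + 1L  # 0-based on disk
    scan$forming_pair <- as.integer(scan$forming_pair) + 1L
    scan$targets <- do.call(rbind, lapply(scan$targets, as.numeric))
    colnames(scan$targets) <- c("r1_target", "r2_target")
  }
  list(config = cfg, scan = scan)
}
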