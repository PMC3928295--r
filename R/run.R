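## Pipeline runners: read inputs, execute, write reports + a run manifest.
## These are the programmatic core of the command-line driver.

write_energy_report_files <- function(report, out_dir, prefix = "energy") {
  tsv <- file.path(out_dir, paste0(prefix, "_terms.tsv"))
  utils::write.table(tidy(report), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  txt <- file.path(out_dir, paste0(prefix, "_report.txt"))
  con <- file(txt, "w"); on.exit(close(con))
  sink(con); print(report); sink()
  c(tsv, txt)
}

write_manifest <- function(out_dir, config, inputs, outputs, backend_name,
                           timings = list()) {
  manifest <- list(
    package = "fragopt",
    version = as.character(utils::packageVersion("fragopt")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    backend = backend_name,
    config = unclass(config),
    input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = basename(outputs),
    timings = timings)
  path <- file.path(out_dir, "manifest.json")
  ## outputs are all written before the manifest is finalized
  stopifnot(all(file.exists(outputs)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

load_run_inputs <- function(geometry_file, fragments_file, config_file) {
  cfg_raw <- if (is.null(config_file)) list(config = run_config(), scan = NULL)
             else read_run_config(config_file)
  geometry <- if (grepl("\\.pdb$", geometry_file, ignore.case = TRUE))
    read_pdb_geometry(geometry_file)$geometry else read_xyz(geometry_file)
  if (is.null(fragments_file))
    abort_config("a fragment spec file is required")
  spec <- read_fragment_spec(fragments_file, geometry)
  partition <- spec$partition
  if (is.null(partition)) {
    hl <- spec$high_level %||% 1L
    partition <- domain_partition(integer(0), integer(0), spec$fragments$id,
                                  hl, spec$fragments)
  }
  list(geometry = geometry, fragments = spec$fragments,
       partition = partition, config = cfg_raw$config, scan = cfg_raw$scan)
}

#' Run a single-point energy (and gradient) calculation
#'
#' Reads a geometry (XYZ or PDB), a fragment/domain spec and an optional
#' YAML config, assembles the hybrid (or RHF) EFMO energy and gradient, and
#' writes the term table, the report, the gradient table and a run manifest
#' to `out_dir`.
#'
#' @param geometry_file path to an XYZ or PDB file.
#' @param fragments_file path to a fragment/domain spec (YAML).
#' @param config_file optional YAML run config.
#' @param out_dir output directory (created if missing).
#' @param backend backend registry key override (default: from config).
#' @return invisibly, a list with `report` and `gradient`.
#' @export
run_single_point <- function(geometry_file, fragments_file,
                             config_file = NULL, out_dir = ".",
                             backend = NULL) {
  t0 <- Sys.time()
  inp <- load_run_inputs(geometry_file, fragments_file, config_file)
  be <- get_backend(backend %||% inp$config$backend)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache <- new_fdd_cache()
  res <- efmo_assemble(inp$geometry, inp$fragments, inp$partition,
                       inp$config, cache, be, want_gradient = TRUE,
                       hybrid = inp$config$hybrid_enabled)
  outputs <- write_energy_report_files(res$report, out_dir)
  gtsv <- file.path(out_dir, "gradient.tsv")
  gdf <- data.frame(atom = seq_len(inp$geometry$atom_count),
                    element = inp$geometry$elements,
                    gx = res$gradient$gradient[, 1],
                    gy = res$gradient$gradient[, 2],
                    gz = res$gradient$gradient[, 3])
  utils::write.table(format(gdf, digits = 10), gtsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, gtsv)
  write_manifest(out_dir, inp$config,
                 c(geometry_file, fragments_file, config_file %||% character(0)),
                 outputs, be$name,
                 list(seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(report = res$report, gradient = res$gradient))
}

#' Run a restrained geometry optimization
#'
#' @inheritParams run_single_point
#' @param restraints optional tibble of [restraint()] rows.
#' @return invisibly, the converged `path_point`.
#' @export
run_optimize <- function(geometry_file, fragments_file, config_file = NULL,
                         out_dir = ".", backend = NULL, restraints = NULL) {
  t0 <- Sys.time()
  inp <- load_run_inputs(geometry_file, fragments_file, config_file)
  be <- get_backend(backend %||% inp$config$backend)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pt <- optimize_active(inp$geometry, inp$fragments, inp$partition,
                        restraints, inp$config, new_fdd_cache(), be,
                        verbose = TRUE)
  outputs <- write_energy_report_files(pt$energy_report, out_dir, "final")
  xyz <- file.path(out_dir, "optimized.xyz")
  write_xyz(pt$geometry, xyz, comment = sprintf(
    "optimized E = %.10f Hartree (%s)", pt$energy_report$total,
    ifelse(pt$converged, "converged", "not converged")))
  outputs <- c(outputs, xyz)
  write_manifest(out_dir, inp$config,
                 c(geometry_file, fragments_file, config_file %||% character(0)),
                 outputs, be$name,
                 list(seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      opt_steps = pt$n_steps))
  if (!pt$converged)
    warning("optimization did not converge within max_opt_steps", call. = FALSE)
  invisible(pt)
}

#' Run an adiabatic-mapping scan
#'
#' Requires a `scan:` block in the config file (breaking/forming pairs and
#' the list of `[r1, r2]` targets).  Writes the tab-separated path table, the
#' multi-frame XYZ trajectory of converged structures, and the manifest.
#'
#' @inheritParams run_single_point
#' @return invisibly, the `reaction_path`.
#' @export
run_scan <- function(geometry_file, fragments_file, config_file,
                     out_dir = ".", backend = NULL) {
  t0 <- Sys.time()
  inp <- load_run_inputs(geometry_file, fragments_file, config_file)
  if (is.null(inp$scan))
    abort_config("run_scan requires a 'scan:' block in the config file")
  be <- get_backend(backend %||% inp$config$backend)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- scan_reaction_path(inp$geometry, inp$fragments, inp$partition,
                             inp$scan$breaking_pair, inp$scan$forming_pair,
                             inp$scan$targets, inp$config,
                             new_fdd_cache(), be, verbose = TRUE)
  tab <- tidy(path)
  tsv <- file.path(out_dir, "path.tsv")
  utils::write.table(format(as.data.frame(tab), digits = 10), tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  xyz <- file.path(out_dir, "trajectory.xyz")
  write_xyz(lapply(path$points, function(p) p$geometry), xyz,
            comment = sprintf("scan point %d R=%.4f E=%.10f",
                              tab$scan_index, tab$reaction_coordinate,
                              tab$energy_hartree))
  outputs <- c(tsv, xyz)
  write_manifest(out_dir, inp$config,
                 c(geometry_file, fragments_file, config_file),
                 outputs, be$name,
                 list(seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  if (!all(tab$converged))
    warning(sprintf("%d scan point(s) did not converge",
                    sum(!tab$converged)), call. = FALSE)
  invisible(path)
}
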