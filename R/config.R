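# Configuration and file I/O: structured run configurations (JSON or YAML),
# bundled parameter fixtures, CSV/JSON outputs with provenance metadata.
#
# Surface units follow the bench conventions (mm, um, degrees, seconds);
# everything is converted to SI when the domain objects are built.

.config_schema <- list(
  canal = c("major_radius_mm", "duct_radius_mm", "duct_span_deg",
            "upright_ampulla_elevation_deg"),
  materials = c("fluid_kinematic_viscosity_m2_s", "fluid_density_kg_m3",
                "particle_diameter_um", "particle_density_kg_m3", "regime"),
  scaling = c("geometric_factor", "reference_endolymph_density_kg_m3",
              "reference_otoconia_density_kg_m3"),
  maneuver = c("extension_angle_deg", "maneuver_velocity_deg_s",
               "resting_time_s", "final_observation_s", "pivot_offset_m",
               "ramp_time_s"),
  noise = c("stop_angle_sd_deg", "velocity_fraction_sd", "resting_time_sd_s",
            "ramp_time_s", "seed"),
  protocol = c("start_s", "step_s", "max_s", "drag_correction",
               "calibration_target_s"),
  unscaled_reference = c("major_radius_mm", "duct_radius_mm",
                         "fluid_viscosity_m2_s", "fluid_density_kg_m3",
                         "particle_diameter_um", "particle_density_kg_m3"),
  seed = NULL,
  output = NULL)

.validate_config <- function(x, path) {
  unknown <- setdiff(names(x), names(.config_schema))
  if (length(unknown) > 0L) {
    stop("config validation error in ", path, ": unknown key `",
         unknown[1L], "`", call. = FALSE)
  }
  for (section in intersect(names(x), names(.config_schema))) {
    allowed <- .config_schema[[section]]
    if (is.null(allowed)) next
    unknown <- setdiff(names(x[[section]]), allowed)
    if (length(unknown) > 0L) {
      stop("config validation error in ", path, ": unknown key `", section,
           ".", unknown[1L], "`", call. = FALSE)
    }
  }
  required <- list(
    canal = c("major_radius_mm", "duct_radius_mm"),
    materials = c("fluid_kinematic_viscosity_m2_s", "fluid_density_kg_m3",
                  "particle_diameter_um", "particle_density_kg_m3"))
  for (section in names(required)) {
    if (is.null(x[[section]])) {
      stop("config validation error in ", path, ": missing required ",
           "section `", section, "`", call. = FALSE)
    }
    miss <- setdiff(required[[section]], names(x[[section]]))
    if (length(miss) > 0L) {
      stop("config validation error in ", path, ": missing required field `",
           section, ".", miss[1L], "`", call. = FALSE)
    }
  }
  invisible(x)
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration (format chosen by file extension),
#' validates it against the documented schema (unknown keys are rejected,
#' required fields are checked, with errors naming the offending key), and
#' builds the corresponding domain objects.  The bundled fixture
#' `scc_model_parameters.json` (under `inst/extdata`) holds the full bench
#' model parameter set and loads without overrides.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param particle_diameter_um Which particle diameter to select when the
#'   configuration lists several; defaults to the largest.
#' @return An object of class `run_config`: list with `canal`, `materials`,
#'   `scaling`, `maneuver` (raw template list or `NULL`), `noise`,
#'   `protocol`, `seed`, and `raw` (the parsed file content).
#' @examples
#' cfg <- load_config(system.file("extdata", "scc_model_parameters.json",
#'                                package = "canalith"))
#' cfg$materials
#' @export
load_config <- function(path, particle_diameter_um = NULL) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  ext <- tolower(file_ext(path))
  raw <- switch(ext,
                json = read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = read_yaml(path),
                stop("config format not supported: `.", ext,
                     "` (use .json or .yaml)", call. = FALSE))
  .validate_config(raw, path)
  cn <- raw$canal
  canal <- canal_geometry(
    major_radius = cn$major_radius_mm * 1e-3,
    duct_radius = cn$duct_radius_mm * 1e-3,
    duct_span_deg = cn$duct_span_deg %||% 240,
    upright_ampulla_elevation_deg = cn$upright_ampulla_elevation_deg %||% 32)
  mt <- raw$materials
  diam <- unlist(mt$particle_diameter_um)
  d_sel <- particle_diameter_um %||% max(diam)
  if (!any(abs(diam - d_sel) < 1e-9)) {
    stop("config validation error in ", path, ": `particle_diameter_um` ",
         d_sel, " is not among the listed diameters (",
         paste(diam, collapse = ", "), ")", call. = FALSE)
  }
  materials <- material_spec(
    fluid_kinematic_viscosity = mt$fluid_kinematic_viscosity_m2_s,
    fluid_density = mt$fluid_density_kg_m3,
    particle_diameter = d_sel * 1e-6,
    particle_density = mt$particle_density_kg_m3,
    regime = mt$regime %||% "scaled_model")
  sc <- raw$scaling
  scaling <- if (is.null(sc)) scaling_spec() else scaling_spec(
    geometric_factor = sc$geometric_factor %||% 5,
    reference_endolymph_density = sc$reference_endolymph_density_kg_m3 %||%
      1000,
    reference_otoconia_density = sc$reference_otoconia_density_kg_m3 %||%
      2700)
  noise <- if (!is.null(raw$noise)) {
    do.call(operator_noise, raw$noise)
  }
  structure(
    list(canal = canal, materials = materials, scaling = scaling,
         maneuver = raw$maneuver, noise = noise, protocol = raw$protocol,
         seed = raw$seed, raw = raw, path = path),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration file
#'
#' Serializes a raw configuration list back to JSON or YAML; loading the
#' written file reproduces the configuration exactly.
#'
#' @param config A raw configuration list (e.g. the `raw` element of a
#'   [load_config()] result).
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  ext <- tolower(file_ext(path))
  switch(ext,
         json = write_json(config, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE),
         yaml = ,
         yml = write_yaml(config, path),
         stop("config format not supported: `.", ext, "`", call. = FALSE))
  invisible(path)
}

#' The bundled experimental configuration grid
#'
#' The grid of experimental cells (setup, particle diameter, extension
#' angle, maneuver velocity) together with the critical resting times
#' observed on the bench (`reference_critical_time_s`; NA marks cells where
#' no successful repositioning was possible, and `reference_onset_time_s`
#' is the onset of the inconclusive band of the manually operated lever-arm
#' runs).
#'
#' @param setup `"stepper"`, `"lever"`, or `"all"`.
#' @return A data frame, one row per experimental cell.
#' @export
experiment_grid <- function(setup = c("stepper", "lever", "all")) {
  setup <- match.arg(setup)
  path <- system.file("extdata", "experiment_configurations.csv",
                      package = "canalith")
  grid <- read.csv(path, stringsAsFactors = FALSE)
  if (setup != "all") grid <- grid[grid$setup == setup, , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

# md5 of the canonical JSON serialization of an R object (provenance hash)
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(toJSON(x, auto_unbox = TRUE, digits = NA)), tf)
  unname(md5sum(tf))
}

#' Write analysis outputs with provenance metadata
#'
#' Data frames in `results` are written as CSV tables; everything else is
#' collected into a `summary.json` carrying the scalar results plus run
#' metadata (package version, seed, configuration hash).  Output content is
#' deterministic for deterministic runs and for stochastic runs under a
#' fixed seed.
#'
#' @param results Named list; data frames become `<name>.csv`, other
#'   elements go into the JSON summary.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the metadata (or `NULL`).
#' @param config Configuration (raw list or `run_config`) hashed into the
#'   metadata, or `NULL`.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(results, dir, seed = NULL, config = NULL) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(config, "run_config")) config <- config$raw
  files <- character()
  summary <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".csv"))
      write.csv(x, f, row.names = FALSE)
      files <- c(files, f)
    } else {
      summary[[nm]] <- x
    }
  }
  meta <- list(package = "canalith",
               version = as.character(packageVersion("canalith")),
               seed = seed,
               config_md5 = if (!is.null(config)) .config_hash(config))
  f <- file.path(dir, "summary.json")
  write_json(list(metadata = meta, results = summary), f, auto_unbox = TRUE,
             digits = NA, pretty = TRUE, null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Export an orientation trace as CSV
#'
#' Writes the uniformly sampled series with columns `time_s`, `beta_deg`,
#' `omega_deg_s`, `alpha_deg_s2`, `phase` -- the exchange format consumed by
#' the particle-transport integrator and external plotting tools.
#'
#' @param trace An `orientation_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "orientation_trace"))
  write.csv(trace$samples, path, row.names = FALSE)
  invisible(path)
}

#' Generate a batch of synthetic manual-operator traces
#'
#' Samples `n` noisy maneuver realizations, writes each as a CSV trace, and
#' records a manifest JSON with the noise specification and the realized
#' parameters of every replicate.
#'
#' @param spec A [maneuver_spec()].
#' @param noise An [operator_noise()].
#' @param n Number of replicates.
#' @param dir Output directory.
#' @param stem File-name stem for the trace CSVs.
#' @param sample_step Trace sampling step (s).
#' @return The manifest path, invisibly.
#' @export
generate_operator_batch <- function(spec, noise, n, dir, stem = "trace",
                                    sample_step = 0.01) {
  stopifnot(inherits(spec, "maneuver_spec"), inherits(noise, "operator_noise"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- sample_manual_trace(spec, noise, replicate_index = i,
                              sample_step = sample_step)
    f <- file.path(dir, sprintf("%s_%03d.csv", stem, i))
    write_trace_csv(tr, f)
    entries[[i]] <- c(list(file = basename(f)), tr$realized)
  }
  manifest <- file.path(dir, "manifest.json")
  write_json(list(n = n, seed = noise$seed,
                  noise = unclass(noise),
                  nominal = unclass(spec),
                  replicates = entries),
             manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
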