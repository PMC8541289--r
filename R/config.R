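#' Default run configuration
#'
#' The full configuration schema with its defaults: the reference device
#' (190 x 95 um x 40 mm channel), water at 20 C, 4 um polystyrene beads,
#' the half-wave resonant drive at 7.25 J/m^3, and the standard acquisition
#' spec. All physical quantities carry explicit unit suffixes in their key
#' names.
#'
#' @return A nested list (the `RunConfig` schema).
#' @export
default_run_config <- function() {
  list(
    medium = list(density_kg_m3 = 998, sound_speed_m_s = 1481,
                  viscosity_pa_s = 1.002e-3, label = "water (20 C)"),
    species = list(list(diameter_um = 4, density_kg_m3 = 1050,
                        compressibility_per_pa = 2.16e-10,
                        label = "4 um polystyrene")),
    geometry = list(width_um = 190, height_um = 95, length_mm = 40,
                    band_fraction = 1 / 3),
    drive = list(Eac_j_m3 = 7.25, Vpp_v = NULL,
                 kappa_v_j_m3_v2 = 7.25 / 52.92^2),
    simulation = list(flow_rate_ul_min = 1, n_particles = 200,
                      t_max_s = 600, dt_s = NULL, seed = 1,
                      streaming = FALSE),
    acquisition = list(frame_interval_s = 0.5, duration_s = 120,
                       pixel_size_um = 1.63, noise_px = 1, n_particles = 20)
  )
}

# deep-merge user config over defaults, erroring on unknown keys; the
# species list is replaced wholesale (entries validated against the record
# schema of the default species)
merge_config <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration field: %s", full))
    }
    if (key == "species") {
      record <- names(default_run_config()$species[[1]])
      for (sp in user$species) {
        bad <- setdiff(names(sp), record)
        if (length(bad)) {
          stop(sprintf("unknown configuration field: species$%s", bad[1]))
        }
      }
      defaults$species <- user$species
    } else if (is.list(user[[key]]) && is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]],
                                      paste0(full, "$"))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a run configuration file
#'
#' Loads a YAML or JSON configuration (by file extension), validates it
#' against the schema of [default_run_config()] (unknown fields are an
#' error naming the field), and fills unset fields with the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; `NULL` returns the
#'   defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("config must be a .yaml/.yml or .json file")
  }
  merge_config(user, defaults)
}

# realise physical objects from a configuration
config_objects <- function(config) {
  med <- baw_medium(density = config$medium$density_kg_m3,
                    sound_speed = config$medium$sound_speed_m_s,
                    viscosity = config$medium$viscosity_pa_s,
                    label = config$medium$label)
  geo <- baw_geometry(width = config$geometry$width_um * 1e-6,
                      height = config$geometry$height_um * 1e-6,
                      length = config$geometry$length_mm * 1e-3,
                      band_fraction = config$geometry$band_fraction)
  species <- lapply(config$species, function(s) {
    baw_species(radius = s$diameter_um * 1e-6 / 2,
                density = s$density_kg_m3,
                compressibility = s$compressibility_per_pa,
                label = s$label)
  })
  kappa <- config$drive$kappa_v_j_m3_v2
  Eac <- if (!is.null(config$drive$Vpp_v)) {
    eac_from_voltage(config$drive$Vpp_v, kappa)
  } else {
    config$drive$Eac_j_m3
  }
  field <- resonant_drive(geo, med, Eac = Eac, kappa_V = kappa)
  list(medium = med, geometry = geo, species = species, field = field)
}

#' Run a pipeline command
#'
#' Dispatches the analysis subcommands on a validated configuration:
#' \describe{
#'   \item{`design`}{half-wave design width, critical diameter and a
#'     pressure-amplitude table for the configured medium/drive.}
#'   \item{`synth`}{writes a synthetic trajectory CSV + manifest.}
#'   \item{`estimate`}{estimates Eac (mean, sd, n, pressure amplitude) from a
#'     trajectory CSV.}
#'   \item{`simulate`}{runs the population simulator and reports both
#'     focusing metrics.}
#'   \item{`streaming`}{solves the cross-section streaming flow and writes
#'     the grid CSV.}
#' }
#' Every run writes the report JSON plus a manifest (config echo, seed,
#' package version) into `out_dir`.
#'
#' @param config A configuration list (see [read_run_config()]).
#' @param command One of `"design"`, `"synth"`, `"estimate"`, `"simulate"`,
#'   `"streaming"`.
#' @param out_dir Output directory (created if missing).
#' @param input Input CSV path (for `estimate`).
#' @return The report, invisibly; artifacts are written to `out_dir`.
#' @export
run_pipeline <- function(config, command, out_dir = tempfile("baw_run_"),
                         input = NULL) {
  command <- match.arg(command,
                       c("design", "synth", "estimate", "simulate", "streaming"))
  obj <- config_objects(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- switch(
    command,
    design = {
      phi <- contrast_factor(obj$species[[1]], obj$medium)
      eacs <- c(1, 2, 5, 7.25, 10)
      list(design_width_um = design_width(obj$medium, obj$field$frequency) * 1e6,
           resonant_frequency_mhz = obj$field$frequency / 1e6,
           contrast_factor = phi,
           critical_diameter_um =
             critical_diameter(phi, obj$medium, obj$field) * 1e6,
           pressure_amplitude_table = list(
             Eac_j_m3 = eacs,
             pa_mpa = pressure_amplitude(eacs, obj$medium) / 1e6))
    },
    synth = {
      acq <- acquisition_spec(
        frame_interval_s = config$acquisition$frame_interval_s,
        duration_s = config$acquisition$duration_s,
        pixel_size_um = config$acquisition$pixel_size_um,
        noise_px = config$acquisition$noise_px,
        n_particles = config$acquisition$n_particles)
      csv <- file.path(out_dir, "trajectories.csv")
      generate_trajectories(obj$field$Eac, obj$species[[1]], obj$medium,
                            obj$geometry, acq,
                            seed = config$simulation$seed, path = csv)
      list(trajectories_csv = csv, true_Eac_j_m3 = obj$field$Eac,
           n_particles = acq$n_particles)
    },
    estimate = {
      if (is.null(input)) stop("estimate requires an input trajectory CSV")
      trajs <- load_trajectories(input)
      est <- estimate_energy_density(
        trajs, obj$species[[1]], obj$medium, obj$geometry,
        pixel_size_um = config$acquisition$pixel_size_um)
      list(Eac_mean_j_m3 = est$mean, Eac_sd_j_m3 = est$sd, n = est$n,
           pressure_amplitude_mpa = est$pressure_amplitude / 1e6)
    },
    simulate = {
      streaming <- NULL
      if (isTRUE(config$simulation$streaming)) {
        f1 <- first_order_field(obj$field, obj$geometry, obj$medium)
        streaming <- solve_streaming(limiting_velocity(f1), obj$geometry,
                                     obj$medium)
      }
      part <- simulate_population(
        obj$species, config$simulation$n_particles, obj$medium, obj$field,
        obj$geometry, config$simulation$flow_rate_ul_min,
        streaming = streaming, seed = config$simulation$seed,
        t_max = config$simulation$t_max_s, dt = config$simulation$dt_s)
      frac <- focusing_fraction_outlet(part)
      band <- vapply(part$exit_positions, function(ey) {
        if (length(ey)) focusing_fraction_band(ey, obj$geometry) else NA_real_
      }, numeric(1))
      list(outlet_fraction = as.list(frac),
           exit_band_fraction = as.list(stats::setNames(band, names(frac))),
           tally = part$tally)
    },
    streaming = {
      f1 <- first_order_field(obj$field, obj$geometry, obj$medium)
      sol <- solve_streaming(limiting_velocity(f1), obj$geometry, obj$medium)
      csv <- file.path(out_dir, "streaming_grid.csv")
      utils::write.csv(streaming_grid(sol), csv, row.names = FALSE)
      list(grid_csv = csv,
           max_speed_um_s = max(sqrt(sol$v2y^2 + sol$v2z^2)) * 1e6,
           divergence = streaming_divergence(sol))
    })
  jsonlite::write_json(report, file.path(out_dir, paste0(command, "_report.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(command = command, config = config,
                   seed = config$simulation$seed,
                   package_version = as.character(utils::packageVersion("acoustofocus")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
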