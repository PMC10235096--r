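# Round-trip-safe tab-separated IO, velocity-field serialization, run
# configuration, and the end-to-end station-context orchestrator.

#' Write a table as UTF-8 tab-separated values
#'
#' Dates are serialized ISO-8601; numeric columns keep full precision;
#' missing-value tokens ("nav", "npr", "nac", "nap") in character columns
#' are emitted verbatim; NA in numeric columns is written as an empty field.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_context_table <- function(x, path) {
  y <- as.data.frame(x)
  for (cl in names(y)) {
    if (inherits(y[[cl]], "Date")) y[[cl]] <- format(y[[cl]], "%Y-%m-%d")
    else if (inherits(y[[cl]], "POSIXct")) {
      y[[cl]] <- format(y[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    } else if (is.numeric(y[[cl]])) {
      y[[cl]] <- ifelse(is.na(y[[cl]]), NA,
                        format(y[[cl]], digits = 17, trim = TRUE,
                               scientific = FALSE))
    }
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table written by [write_context_table()]
#'
#' Columns consisting solely of numbers (and empty fields) are restored as
#' numeric, all-logical columns as logical, ISO dates as `Date`; columns
#' containing missing-value tokens stay character with the tokens intact.
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_context_table <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (!nrow(raw)) {
    for (cl in names(raw)) raw[[cl]] <- character(0)
    return(raw)
  }
  for (cl in names(raw)) {
    v <- raw[[cl]]
    empty <- v == ""
    if (any(v %in% MISSING_TOKENS)) next # token column: keep verbatim
    if (all(empty)) { raw[[cl]] <- rep(NA_real_, length(v)); next }
    body <- v[!empty]
    if (all(grepl("^\\d{4}-\\d{2}-\\d{2}$", body))) {
      d <- as.Date(v); d[empty] <- NA
      raw[[cl]] <- d
    } else if (all(body %in% c("TRUE", "FALSE"))) {
      b <- as.logical(v); b[empty] <- NA
      raw[[cl]] <- b
    } else if (!anyNA(suppressWarnings(as.numeric(body)))) {
      num <- suppressWarnings(as.numeric(v)); num[empty] <- NA
      raw[[cl]] <- num
    } else {
      v[empty] <- NA_character_
      raw[[cl]] <- v
    }
  }
  raw
}

#' Serialize a velocity field to a gridded long-format table
#'
#' One row per (lon, lat, time) node with `u`, `v` in m s^-1; the regular
#' grid is reconstructed on read.
#'
#' @param field A `velocity_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  g <- expand.grid(lon = field$lon, lat = field$lat, time = field$time)
  g$u <- as.numeric(field$u)
  g$v <- as.numeric(field$v)
  write_context_table(g, path)
}

#' Read a velocity field written by [write_velocity_field()]
#'
#' @param path Input path.
#' @return A `velocity_field` (with `steady = FALSE`; truth fields are not
#'   serialized).
#' @export
read_velocity_field <- function(path) {
  g <- read_context_table(path)
  lon <- sort(unique(g$lon)); lat <- sort(unique(g$lat))
  time <- sort(unique(g$time))
  g <- g[order(g$time, g$lat, g$lon), ]
  dims <- c(length(lon), length(lat), length(time))
  structure(list(lon = lon, lat = lat, time = time,
                 u = array(g$u, dims), v = array(g$v, dims),
                 steady = length(time) == 1L, truth = NULL, scenario = NULL),
            class = "velocity_field")
}

#' Read a plain-text run configuration
#'
#' YAML-style key-value file; see [run_station_context()] for the recognized
#' keys.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

stage_seed <- function(master, stage) {
  # derive per-stage seeds from the master; offsets keep stages independent
  offsets <- c(sst = 101L, flow = 211L, sources = 307L, plankton = 401L)
  (as.integer(master) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic station-context pipeline
#'
#' Generates every input from the configured scenarios (all randomness
#' derived from one master seed), runs the thermal, flow, merge and NBSS
#' stages, and writes one tab-separated table per granularity plus a JSON
#' manifest recording seeds and parameter values. Stages can be disabled
#' individually; reruns with the same config are byte-identical.
#'
#' @param config Named list (or path to a YAML file) with optional entries:
#'   `seed` (master seed, default 1), `out_dir` (default "."), logical
#'   `thermal`, `flow`, `merge`, `nbss` stage switches (default TRUE),
#'   `sampling_date` (default "2016-06-30"), and parameter overrides
#'   `stadium` (list: lon, lat, radius, spacing), `tau_list`,
#'   `flow_kind`, `flow_params`.
#' @return Named list of output paths, invisibly.
#' @export
run_station_context <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(
    list(seed = 1L, out_dir = ".", thermal = TRUE, flow = TRUE, merge = TRUE,
         nbss = TRUE, sampling_date = "2016-06-30",
         stadium = list(lon = 0, lat = 0, radius = 0.1, spacing = 0.02),
         tau_list = c(5, 10), flow_kind = "solid_body",
         flow_params = list(omega = 0.1)),
    config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  manifest <- list(package = "reefcontext",
                   version = as.character(utils::packageVersion("reefcontext")),
                   master_seed = cfg$seed, parameters = cfg[setdiff(names(cfg), "out_dir")])

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (isTRUE(cfg$thermal)) {
    run_stage("thermal", {
      sc <- sst_scenario(seed = stage_seed(cfg$seed, "sst"))
      series <- generate_sst_series(sc)
      idx <- assemble_indices(series)
      paths$thermal_indices <- file.path(cfg$out_dir, "thermal_indices.tsv")
      write_context_table(idx, paths$thermal_indices)
      sm <- summarize_site(idx, cfg$sampling_date)
      paths$thermal_summary <- file.path(cfg$out_dir, "thermal_summary.tsv")
      write_context_table(cbind(site_id = sc$site_id, sm$stats),
                          paths$thermal_summary)
    })
  }
  if (isTRUE(cfg$flow)) {
    run_stage("flow", {
      fsc <- flow_scenario(cfg$flow_kind, params = cfg$flow_params)
      field <- generate_velocity_field(fsc)
      spec <- stadium_spec(c(cfg$stadium$lon, cfg$stadium$lat),
                           radius = cfg$stadium$radius,
                           spacing = cfg$stadium$spacing)
      sd_tab <- station_diagnostics(spec, field, t0 = max(cfg$tau_list),
                                    tau_list = cfg$tau_list)
      paths$station_diagnostics <- file.path(cfg$out_dir,
                                             "station_diagnostics.tsv")
      write_context_table(sd_tab, paths$station_diagnostics)
    })
  }
  if (isTRUE(cfg$merge)) {
    run_stage("merge", {
      ms <- generate_multisource(source_scenario(seed = stage_seed(cfg$seed, "sources")))
      bc <- bias_correct_source(ms$satellite$value, ms$insitu$value)
      merged <- merge_sources(list(insitu = ms$insitu$value,
                                   satellite = bc$corrected,
                                   model = ms$model$value),
                              accepted = c(insitu = TRUE,
                                           satellite = bc$accepted,
                                           model = FALSE))
      merged <- cbind(station = ms$truth$station, merged)
      paths$site_merged <- file.path(cfg$out_dir, "site_merged.tsv")
      write_context_table(merged, paths$site_merged)
    })
  }
  if (isTRUE(cfg$nbss)) {
    run_stage("nbss", {
      sm <- generate_plankton_sample(seed = stage_seed(cfg$seed, "plankton"))
      sp <- compute_nbss(sm)
      paths$nbss <- file.path(cfg$out_dir, "nbss.tsv")
      write_context_table(sp, paths$nbss)
    })
  }
  paths$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
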