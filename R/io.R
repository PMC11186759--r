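#' Read and write AFM force curves as tab-separated text
#'
#' The on-disk format mirrors typical AFM text exports: `#`-prefixed header
#' lines carrying probe metadata (`spring_constant_N_per_m`,
#' `bead_radius_um`, `speed_um_per_s`, `timestamp_s` on the AFM clock),
#' then tab-separated columns `time_s`, `height_um`, `deflection_nm`,
#' `segment`. Real exports with different column names can be mapped onto
#' this layout before reading.
#'
#' @param curve A `force_curve` tibble.
#' @param path File path.
#' @return `write_force_curve()` returns `path` invisibly;
#'   `read_force_curve()` returns a `force_curve`.
#' @export
write_force_curve <- function(curve, path) {
  hdr <- c(
    sprintf("# spring_constant_N_per_m: %.17g", attr(curve, "spring_constant")),
    sprintf("# bead_radius_um: %.17g", attr(curve, "bead_radius")),
    sprintf("# speed_um_per_s: %.17g", attr(curve, "speed")),
    sprintf("# timestamp_s: %.17g", attr(curve, "timestamp"))
  )
  body <- sprintf(
    "%.9g\t%.6f\t%.6f\t%s",
    curve$time_s, curve$height_um, curve$deflection_nm, curve$segment
  )
  writeLines(
    c(hdr, "time_s\theight_um\tdeflection_nm\tsegment", body),
    path
  )
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = NA_real_) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(default)
    as.numeric(sub(paste0("^# ", key, ":\\s*"), "", ln[1]))
  }
  k <- meta("spring_constant_N_per_m")
  if (!is.finite(k) || k <= 0) abort("force-curve file lacks a valid spring constant.")
  df <- readr::read_tsv(I(lines[!grepl("^#", lines)]),
    show_col_types = FALSE, progress = FALSE
  )
  df$force_nn <- k * df$deflection_nm
  new_force_curve(
    df[, c("time_s", "height_um", "deflection_nm", "force_nn", "segment")],
    spring_constant = k, bead_radius = meta("bead_radius_um"),
    speed = meta("speed_um_per_s"), timestamp = meta("timestamp_s")
  )
}

#' Write a synthetic experiment bundle to plain-text files
#'
#' Lays out one directory per bundle: `force_curves/curve_NNN.txt`
#' ([write_force_curve()] format), `spikes.csv` (`unit_id`, `time_s`),
#' `templates.csv` (long per-electrode per-epoch templates with electrode
#' coordinates), `calcium.csv` (`frame_time_s` on the camera clock, `dff`),
#' `ttl_events.csv` (`stream`, `event_time_s`, `label`), `schedule.json`
#' and `manifest.json`. With a fixed config seed the files are
#' byte-identical across runs.
#'
#' @param bundle An `experiment_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(file.path(dir, "force_curves"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bundle$force_curves)) {
    write_force_curve(
      bundle$force_curves[[i]],
      file.path(dir, "force_curves", sprintf("curve_%03d.txt", i))
    )
  }
  readr::write_csv(bundle$spikes, file.path(dir, "spikes.csv"), progress = FALSE)
  if (!is.null(bundle$footprint)) {
    readr::write_csv(
      as_tibble(bundle$footprint),
      file.path(dir, "templates.csv"),
      progress = FALSE
    )
  }
  cam <- tibble(
    frame_time_s = to_stream_time(bundle$config, bundle$calcium$frame_time_s, "camera"),
    dff = bundle$calcium$dff
  )
  readr::write_csv(cam, file.path(dir, "calcium.csv"), progress = FALSE)
  readr::write_csv(
    bundle$ttl_events[, c("stream", "event_time_s", "label", "source_stream")],
    file.path(dir, "ttl_events.csv"),
    progress = FALSE
  )
  jsonlite::write_json(bundle$schedule, file.path(dir, "schedule.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read an experiment bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A list with elements `force_curves`, `spikes`, `templates`,
#'   `calcium`, `ttl_events`, `schedule`, `manifest`. Missing artefacts
#'   load as `NULL`, so downstream stages can fail individually instead of
#'   the whole bundle.
#' @export
read_bundle <- function(dir) {
  curve_files <- sort(list.files(file.path(dir, "force_curves"),
    pattern = "\\.txt$", full.names = TRUE
  ))
  safe_csv <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  safe_json <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    jsonlite::read_json(p, simplifyVector = TRUE)
  }
  list(
    force_curves = map(curve_files, read_force_curve),
    spikes = safe_csv("spikes.csv"),
    templates = safe_csv("templates.csv"),
    calcium = safe_csv("calcium.csv"),
    ttl_events = safe_csv("ttl_events.csv"),
    schedule = safe_json("schedule.json"),
    manifest = safe_json("manifest.json")
  )
}
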