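# File interfaces: schema-validated CSV readers/writers (comma separator,
# header row, '.' decimal, unit-suffixed column names so hours/seconds can
# never be confused inside a file), JSON metadata sidecars, and YAML/JSON run
# configuration.

read_csv_checked <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra))
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  for (col in required)
    if (anyNA(df[[col]]))
      stop("NA values in required column '", col, "' of ", basename(path))
  df
}

#' Read / write a head-foot track table
#'
#' CSV schema: `time_s, head_x_mm, head_y_mm, foot_x_mm, foot_y_mm`
#' (optional `head_z_mm`, `foot_z_mm`); time strictly increasing with
#' near-uniform spacing. Unknown extra columns are preserved with a warning.
#'
#' @param path CSV file path.
#' @return `read_track_table()`: a validated track data.frame.
#' @export
read_track_table <- function(path) {
  df <- read_csv_checked(path,
                         required = c("time_s", "head_x_mm", "head_y_mm",
                                      "foot_x_mm", "foot_y_mm"),
                         optional = c("head_z_mm", "foot_z_mm"))
  validate_track(df)
  df
}

#' @rdname read_track_table
#' @param track a track data.frame.
#' @export
write_track_table <- function(track, path) {
  validate_track(track)
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

validate_track <- function(track) {
  stopifnot(is.data.frame(track))
  req <- c("time_s", "head_x_mm", "head_y_mm", "foot_x_mm", "foot_y_mm")
  missing <- setdiff(req, names(track))
  if (length(missing))
    stop("track table lacks column(s): ", paste(missing, collapse = ", "))
  t <- track$time_s
  if (length(t) >= 2L) {
    if (is.unsorted(t, strictly = TRUE))
      stop("track time must be strictly increasing")
    dt <- diff(t)
    if (max(dt) > 1.1 * stats::median(dt) || min(dt) < 0.9 * stats::median(dt))
      stop("track frame spacing deviates more than 10% from uniform")
  }
  coords <- unlist(track[intersect(c(req[-1], "head_z_mm", "foot_z_mm"),
                                   names(track))], use.names = FALSE)
  if (any(!is.finite(coords))) stop("track coordinates must be finite")
  invisible(TRUE)
}

#' Read / write a velocity-magnitude profile
#'
#' CSV schema: `distance_mm, speed_mm_s`, distances strictly increasing from
#' the surface outward.
#'
#' @param path CSV file path.
#' @param surface_speed_mm_s,freestream_speed_mm_s see [velocity_profile()];
#'   read from the sidecar-free CSV as defaults if not given.
#' @return `read_velocity_profile()`: a [velocity_profile()].
#' @export
read_velocity_profile <- function(path, surface_speed_mm_s = NULL,
                                  freestream_speed_mm_s = 0) {
  df <- read_csv_checked(path, required = c("distance_mm", "speed_mm_s"))
  velocity_profile(df$distance_mm, df$speed_mm_s,
                   surface_speed_mm_s = surface_speed_mm_s %||% df$speed_mm_s[1],
                   freestream_speed_mm_s = freestream_speed_mm_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_velocity_profile
#' @param profile a [velocity_profile()].
#' @export
write_velocity_profile <- function(profile, path) {
  stopifnot(inherits(profile, "velocity_profile"))
  utils::write.csv(data.frame(distance_mm = profile$distance_mm,
                              speed_mm_s = profile$speed_mm_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a contraction schedule
#'
#' CSV schema: `event_index, time_s` (one row per post-zero contraction
#' event); the horizon travels in a `horizon_s` column repeated per row so
#' the file is self-contained.
#'
#' @param path CSV file path.
#' @return `read_schedule()`: a [contraction_schedule()].
#' @export
read_schedule <- function(path) {
  df <- read_csv_checked(path, required = c("event_index", "time_s",
                                            "horizon_s"))
  if (nrow(df) && any(diff(df$time_s) <= 0))
    stop("schedule event times must be strictly increasing")
  contraction_schedule(df$time_s, df$horizon_s[1])
}

#' @rdname read_schedule
#' @param schedule a [contraction_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "contraction_schedule"))
  ev <- schedule$event_times_s
  utils::write.csv(data.frame(event_index = seq_along(ev), time_s = ev,
                              horizon_s = rep(schedule$horizon_s,
                                              length(ev))),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write inter-contraction intervals
#'
#' CSV schema: `interval_s, censored` (logical; a censored interval ends at
#' the horizon rather than at a contraction). Negative or zero gaps are
#' rejected.
#'
#' @param path CSV file path.
#' @return `read_intervals()`: data.frame with `interval_s`, `censored`.
#' @export
read_intervals <- function(path) {
  df <- read_csv_checked(path, required = "interval_s", optional = "censored")
  if (any(df$interval_s <= 0)) stop("intervals must be positive")
  if (is.null(df$censored)) df$censored <- FALSE
  df$censored <- as.logical(df$censored)
  df
}

#' @rdname read_intervals
#' @param intervals_s numeric intervals, s.
#' @param censored logical flags (recycled).
#' @export
write_intervals <- function(intervals_s, path, censored = FALSE) {
  stopifnot(all(intervals_s > 0))
  utils::write.csv(data.frame(interval_s = intervals_s,
                              censored = rep_len(censored,
                                                 length(intervals_s))),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep result with a JSON metadata sidecar
#'
#' The CSV carries the [sweep_uptake()] columns; `<path>.json` records the
#' full parameterization (seed included) so any figure built from the CSV is
#' regenerable without re-running the Monte Carlo.
#'
#' @param sweep a `sweep_result`.
#' @param path CSV output path.
#' @param meta named list of run metadata (seed, parameters, notes).
#' @return The CSV path, invisibly.
#' @export
write_sweep <- function(sweep, path, meta = list()) {
  stopifnot(inherits(sweep, "data.frame"))
  utils::write.csv(sweep, path, row.names = FALSE)
  meta$package_version <- as.character(utils::packageVersion("shedflux"))
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a run configuration (YAML or JSON)
#'
#' Round-trips a named list of run parameters losslessly; the format follows
#' the file extension (`.yml`/`.yaml` or `.json`).
#'
#' @param path configuration file path.
#' @return `read_run_config()`: a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname read_run_config
#' @param config named list of parameters.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
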