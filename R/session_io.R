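## Session container: in-memory objects and on-disk round trip.
##
## A session bundles a multichannel recording (uV, channel x time), an
## optional head-speed trace aligned to the recording time base, optional
## tracking and trial tables, the species profile, and free-form metadata.
## On disk a session is a directory holding meta.json, raw little-endian
## float64 arrays (lfp.f64, speed.f64), a packed logical mask, and CSV
## tables -- a neutral, vendor-independent layout.

#' Construct a recording
#'
#' @param samples channel x time numeric matrix, microvolts
#' @param fs sampling rate, Hz
#' @param channel_depth per-channel depth, micrometres, strictly increasing
#' @param cortical_flag logical per channel
#' @param valid_mask logical channel x time; FALSE where artifact-masked
#'   (masked samples carry NA in `samples`)
#' @return object of class `tq_recording`
#' @export
new_recording <- function(samples, fs, channel_depth,
                          cortical_flag = rep(FALSE, nrow(samples)),
                          valid_mask = NULL) {
  if (!is.matrix(samples) || nrow(samples) < 1 || ncol(samples) < 1)
    stop("samples must be a non-empty channel x time matrix", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  if (length(channel_depth) != nrow(samples))
    stop("channel_depth length must match channel count", call. = FALSE)
  if (any(diff(channel_depth) <= 0))
    stop("channel_depth must be strictly increasing", call. = FALSE)
  if (is.null(valid_mask))
    valid_mask <- !is.na(samples)
  stopifnot(identical(dim(valid_mask), dim(samples)),
            length(cortical_flag) == nrow(samples))
  structure(list(samples = samples, fs = fs,
                 channel_depth = as.numeric(channel_depth),
                 cortical_flag = as.logical(cortical_flag),
                 valid_mask = valid_mask),
            class = "tq_recording")
}

#' Construct a session
#'
#' @param recording a `tq_recording` (required, non-empty)
#' @param tracking optional data frame of per-frame LED positions
#' @param speed optional numeric vector, cm/s, sampled at `recording$fs`
#'   and no longer than the recording
#' @param trials optional data frame of trial records
#' @param species_profile a [species_profile()]
#' @param meta named list; `drug` must be `"none"` or `"atropine"`
#' @return object of class `tq_session`
#' @export
new_session <- function(recording, tracking = NULL, speed = NULL,
                        trials = NULL, species_profile, meta = list()) {
  if (!inherits(recording, "tq_recording"))
    stop("recording must be a tq_recording", call. = FALSE)
  if (!inherits(species_profile, "tq_species_profile"))
    stop("species_profile must be a tq_species_profile", call. = FALSE)
  if (!is.null(speed) && length(speed) > ncol(recording$samples))
    stop("speed trace extends beyond the recording time span", call. = FALSE)
  drug <- meta$drug %||% "none"
  if (!drug %in% c("none", "atropine"))
    stop("meta$drug must be 'none' or 'atropine'", call. = FALSE)
  meta$drug <- drug
  structure(list(recording = recording, tracking = tracking, speed = speed,
                 trials = trials, species_profile = species_profile,
                 meta = meta),
            class = "tq_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tq_session <- function(x, ...) {
  r <- x$recording
  cat(sprintf("tq_session: %d channels x %.1f s @ %g Hz (%s, drug=%s)\n",
              nrow(r$samples), ncol(r$samples) / r$fs, r$fs,
              x$species_profile$name, x$meta$drug))
  cat(sprintf("  speed: %s  trials: %s  masked: %.2f%%\n",
              if (is.null(x$speed)) "none" else "present",
              if (is.null(x$trials)) 0 else nrow(x$trials),
              100 * mean(!r$valid_mask)))
  invisible(x)
}

write_f64 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_f64 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n, size = 8, endian = "little")
}

SCHEMA_VERSION <- "tq-session-1"

#' Save a session to disk
#'
#' Writes the directory container (meta.json + raw arrays + CSV tables).
#' Refuses to overwrite an existing container unless `overwrite = TRUE`.
#'
#' @param session a `tq_session`
#' @param path destination directory
#' @param overwrite logical
#' @return `path`, invisibly
#' @export
save_session <- function(session, path, overwrite = FALSE) {
  stopifnot(inherits(session, "tq_session"))
  if (dir.exists(path) || file.exists(path)) {
    if (!overwrite)
      stop("destination exists; use overwrite = TRUE", call. = FALSE)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  r <- session$recording
  samples <- r$samples
  samples[!r$valid_mask] <- NA_real_   # masked samples carry the sentinel
  write_f64(samples, file.path(path, "lfp.f64"))
  writeLines(as.character(as.integer(r$valid_mask)),
             file.path(path, "valid_mask.txt"))
  meta <- list(schema = SCHEMA_VERSION, fs = r$fs,
               n_channels = nrow(samples), n_samples = ncol(samples),
               channel_depth = r$channel_depth,
               cortical_flag = r$cortical_flag,
               species = session$species_profile$name,
               has_speed = !is.null(session$speed),
               meta = session$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$speed))
    write_f64(session$speed, file.path(path, "speed.f64"))
  if (!is.null(session$trials))
    utils::write.csv(session$trials, file.path(path, "trials.csv"),
                     row.names = FALSE)
  if (!is.null(session$tracking))
    utils::write.csv(session$tracking, file.path(path, "tracking.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Load a session from disk
#'
#' @param path a directory written by [save_session()]
#' @return a `tq_session`; units are microvolts / seconds / cm/s
#' @export
load_session <- function(path) {
  if (!dir.exists(path))
    stop("no session container at ", path, call. = FALSE)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("schema error: missing dataset meta.json", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, SCHEMA_VERSION))
    stop("unrecognised container schema: ", meta$schema, call. = FALSE)
  if (!file.exists(file.path(path, "lfp.f64")))
    stop("schema error: missing dataset lfp.f64", call. = FALSE)
  if (meta$fs <= 0) stop("validation error: fs must be > 0", call. = FALSE)
  nch <- meta$n_channels
  ns <- meta$n_samples
  samples <- matrix(read_f64(file.path(path, "lfp.f64"), nch * ns), nch, ns)
  vm <- matrix(as.logical(as.integer(
    readLines(file.path(path, "valid_mask.txt")))), nch, ns)
  rec <- new_recording(samples, meta$fs, meta$channel_depth,
                       as.logical(meta$cortical_flag), vm)
  speed <- if (isTRUE(meta$has_speed))
    read_f64(file.path(path, "speed.f64"), ns) else NULL
  trials <- if (file.exists(file.path(path, "trials.csv")))
    utils::read.csv(file.path(path, "trials.csv")) else NULL
  tracking <- if (file.exists(file.path(path, "tracking.csv")))
    utils::read.csv(file.path(path, "tracking.csv")) else NULL
  new_session(rec, tracking = tracking, speed = speed, trials = trials,
              species_profile = species_profile(meta$species),
              meta = meta$meta)
}

#' Export an epoch table to CSV
#'
#' One row per epoch; undefined values (e.g. rejected sinusoid matches)
#' are written as empty cells, not zeros. The export round-trips through
#' `read.csv` to an identical table.
#'
#' @param epochs data frame of epoch records (see [epoch_pipeline()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
export_epoch_table <- function(epochs, path) {
  if (is.null(epochs) || nrow(epochs) == 0)
    stop("empty epoch table", call. = FALSE)
  utils::write.csv(epochs, path, row.names = FALSE, na = "")
  invisible(path)
}
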