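#' Read a session directory
#'
#' A session lives in one directory holding three tab-delimited tables plus
#' a small JSON header: \code{kinematics.tsv} (per-frame coordinates, mm),
#' \code{spikes.tsv} (\code{unit_id}, \code{time_s}), \code{units.tsv}
#' (\code{unit_id}, \code{region}, \code{sublabel}) and \code{meta.json}
#' (\code{session_id}, \code{frame_rate}, \code{duration}). Optional
#' generator ground-truth sidecars (\code{bouts_truth.tsv},
#' \code{phase_truth.tsv}, \code{speed_truth.tsv}, \code{ground_truth.tsv})
#' are read back into the \code{groundTruth} slot when present.
#'
#' @param path session directory.
#' @return A validated \linkS4class{GaitSession}.
#' @seealso [writeSession()]
#' @export
readSession <- function(path) {
  if (!dir.exists(path)) stop("session directory not found: ", path)
  need <- c("kinematics.tsv", "spikes.tsv", "units.tsv", "meta.json")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss))
    stop("session directory is missing file(s): ", paste(miss, collapse = ", "))

  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  for (k in c("session_id", "frame_rate", "duration"))
    if (is.null(meta[[k]])) stop("meta.json is missing key '", k, "'")

  kin <- as.data.frame(data.table::fread(file.path(path, "kinematics.tsv")))
  miss <- setdiff(KIN_COLUMNS, names(kin))
  if (length(miss))
    stop("kinematics.tsv is missing column(s): ", paste(miss, collapse = ", "))

  sp <- as.data.frame(data.table::fread(file.path(path, "spikes.tsv")))
  if (nrow(sp) == 0L) sp <- data.frame(unit_id = character(0), time_s = numeric(0))
  miss <- setdiff(c("unit_id", "time_s"), names(sp))
  if (length(miss))
    stop("spikes.tsv is missing column(s): ", paste(miss, collapse = ", "))

  ut <- as.data.frame(data.table::fread(file.path(path, "units.tsv"),
                                        colClasses = "character"))
  if (nrow(ut) == 0L)
    ut <- data.frame(unit_id = character(0), region = character(0),
                     sublabel = character(0))
  miss <- setdiff(c("unit_id", "region", "sublabel"), names(ut))
  if (length(miss))
    stop("units.tsv is missing column(s): ", paste(miss, collapse = ", "))

  unk <- setdiff(unique(sp$unit_id), ut$unit_id)
  if (length(unk))
    stop("spikes.tsv references unit(s) absent from units.tsv: ",
         paste(unk, collapse = ", "))

  units <- lapply(seq_len(nrow(ut)), function(i) {
    st <- sp$time_s[sp$unit_id == ut$unit_id[i]]
    if (is.unsorted(st))
      stop("spike times are not sorted for unit ", ut$unit_id[i])
    sub <- ut$sublabel[i]
    if (!nzchar(sub) || identical(sub, "NA")) sub <- NA_character_
    SpikeTrain(ut$unit_id[i], st, ut$region[i], sub)
  })

  gt <- list()
  for (f in c("bouts_truth", "phase_truth", "speed_truth", "ground_truth")) {
    p <- file.path(path, paste0(f, ".tsv"))
    if (file.exists(p)) {
      key <- sub("_truth$", "", sub("^ground_truth$", "profiles", f))
      gt[[key]] <- as.data.frame(data.table::fread(p))
    }
  }

  GaitSession(meta$session_id, kin, units, frameRate = meta$frame_rate,
              duration = meta$duration, groundTruth = gt)
}

#' Write a session directory
#'
#' Inverse of [readSession()]: writes the three delimited tables and
#' \code{meta.json}; ground-truth components that are data.frames are written
#' as \code{*_truth.tsv} sidecars (profiles as \code{ground_truth.tsv}).
#' Output is deterministic: the same session always produces byte-identical
#' files.
#'
#' @param session a valid \linkS4class{GaitSession}.
#' @param path target directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "GaitSession"))
  validObject(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)

  fwrite0 <- function(x, f)
    data.table::fwrite(x, file.path(path, f), sep = "\t", quote = FALSE)

  fwrite0(session@kinematics[KIN_COLUMNS], "kinematics.tsv")

  sp <- data.table::rbindlist(lapply(session@units, function(u)
    data.frame(unit_id = rep(u@unitId, length(u@spikeTimes)),
               time_s = u@spikeTimes)))
  if (nrow(sp) == 0L) sp <- data.frame(unit_id = character(0), time_s = numeric(0))
  fwrite0(sp, "spikes.tsv")

  ut <- data.frame(
    unit_id = vapply(session@units, slot, character(1), "unitId"),
    region = vapply(session@units, slot, character(1), "region"),
    sublabel = vapply(session@units, slot, character(1), "sublabel"))
  fwrite0(ut, "units.tsv")

  jsonlite::write_json(list(session_id = session@sessionId,
                            frame_rate = session@frameRate,
                            duration = session@duration),
                       file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)

  gt <- session@groundTruth
  for (key in names(gt)) if (is.data.frame(gt[[key]])) {
    f <- if (key == "profiles") "ground_truth.tsv" else paste0(key, "_truth.tsv")
    fwrite0(gt[[key]], f)
  }
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All analysis parameters with their defaults: 0.2 s decoder bins over the
#' plus/minus 1.5 s onset window (15 classes), 25 ms base bins smoothed with a
#' 0.1 s-sd Gaussian kernel, 0.1 s modulation bins over plus/minus 1 s with a
#' -1..-0.9 s baseline, speed bins of 20 mm/s from 50 to 310 mm/s for tuning
#' and four 50 mm/s classes (50-250 mm/s) for decoding, 24 x 15-degree phase
#' histogram bins and 12 x 30-degree phase classes, spike jitter of plus/minus
#' 0.15 s with 1000 surrogates, 50 unit draws and 50 evaluation iterations
#' with 200 (time/phase) or 100 (speed) units per draw.
#'
#' @return Named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    random_seed = 1L,
    frame_rate = 80,
    # rate estimation
    base_bin = 0.025, kernel_sd = 0.1,
    time_bin = 0.2, decode_window = 1.5,
    mod_bin = 0.1, mod_window = 1.0,
    baseline_window = c(-1.0, -0.9), alpha = 0.05,
    # kinematics
    sg_window = 7, sg_order = 3,
    band_low = 0.5, band_high = 8,
    speed_threshold = 50, speed_sustain = 0.5,
    accel_prominence = 1000, onset_search_frames = 50,
    min_bout_duration = 1.0, min_bout_gap = 1.0, offset_below = 0.25,
    # unit statistics
    speed_bin_width = 20, speed_bin_min = 50, speed_bin_max = 310,
    phase_hist_bins = 24, jitter_s = 0.15, jitter_iterations = 1000,
    # decoding
    speed_class_min = 50, speed_class_max = 250, speed_class_width = 50,
    phase_classes = 12,
    n_units_time = 200, n_units_speed = 100, n_units_phase = 200,
    n_draws = 50, n_eval_iterations = 50,
    held_out_time = 1, held_out_speed = 2, held_out_phase = 4,
    quota_time = 50, quota_speed = 100, quota_phase = 200,
    n_shuffles = 50,
    svm_cost = 10, svm_gamma_scale = 1, svm_tune = FALSE,
    sweep_sizes = c(25, 50, 100, 150, 200)
  )
}

#' Load a run configuration file
#'
#' Flat \code{key: value} file (a YAML subset; \code{#} comments allowed).
#' Unspecified keys take the documented defaults; unknown keys are an error
#' rather than silently ignored, and values are type-checked against the
#' default they override. Vector-valued keys take comma-separated values.
#'
#' @param path config file, or \code{NULL} for pure defaults.
#' @return Named list with every effective value (see [defaultConfig()]).
#' @export
loadConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("malformed config line (expected 'key: value'): ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    old <- cfg[[key]]
    if (is.numeric(old)) {
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(parts))
      if (any(is.na(num)))
        stop("config key '", key, "' expects numeric value(s), got: ", val)
      if (is.integer(old)) num <- as.integer(num)
      cfg[[key]] <- num
    } else if (is.logical(old)) {
      if (!toupper(val) %in% c("TRUE", "FALSE", "YES", "NO"))
        stop("config key '", key, "' expects a logical value, got: ", val)
      cfg[[key]] <- toupper(val) %in% c("TRUE", "YES")
    } else cfg[[key]] <- val
  }
  cfg
}
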