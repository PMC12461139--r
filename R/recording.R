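#' Construct a dyad recording
#'
#' A `dyad_recording` bundles the sample matrix of one dyad (both
#' participants' channels side by side) with the sampling rate and the
#' channel bookkeeping: which participant each channel belongs to (its
#' *role*, Model or Imitator) and which cortical region it samples (e.g.
#' `"M1"`, `"PMC"`, `"PMC/M1"`, or `"SDC"` for short-distance nuisance
#' channels).
#'
#' @param samples numeric matrix, time in rows, channels in columns.
#' @param fs sampling frequency in Hz.
#' @param channel_labels character vector naming the columns.
#' @param role_map named character vector, channel label -> `"Model"` or
#'   `"Imitator"`.
#' @param region_map named character vector, channel label -> region name.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return an object of class `dyad_recording`.
#' @export
dyad_recording <- function(samples, fs, channel_labels,
                           role_map, region_map, chromophore = "HbO") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(samples))
    stop("channel_labels length must equal the number of columns")
  colnames(samples) <- channel_labels
  missing_role <- setdiff(channel_labels, names(role_map))
  if (length(missing_role))
    stop("channels without a role: ", paste(missing_role, collapse = ", "))
  missing_region <- setdiff(channel_labels, names(region_map))
  if (length(missing_region))
    stop("channels without a region: ", paste(missing_region, collapse = ", "))
  bad_role <- setdiff(unique(role_map[channel_labels]), .ROLES)
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  chromophore <- match.arg(chromophore, c("HbO", "HbR"))
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         role_map = role_map[channel_labels],
         region_map = region_map[channel_labels],
         chromophore = chromophore),
    class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> %d samples x %d channels @ %.4g Hz (%s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$chromophore))
  tab <- table(x$region_map, x$role_map)
  print(tab)
  invisible(x)
}

#' Construct an event table
#'
#' One row per experimental interval, BIDS-events style: onset and duration
#' in seconds plus a condition label and trial index. Onsets must be
#' strictly increasing and durations positive.
#'
#' @param onset numeric vector, seconds from recording start.
#' @param duration numeric vector, seconds.
#' @param condition character vector (e.g. `"hand"`, `"foot"`, `"baseline"`).
#' @param trial_index integer vector.
#' @return a `data.frame` with class `event_table`.
#' @export
event_table <- function(onset, duration, condition, trial_index) {
  if (any(diff(onset) <= 0)) stop("onsets must be strictly increasing")
  if (any(duration <= 0)) stop("durations must be positive")
  out <- data.frame(onset = as.numeric(onset),
                    duration = as.numeric(duration),
                    condition = as.character(condition),
                    trial_index = as.integer(trial_index),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Read a dyad recording from a CSV file plus channel-map config
#'
#' The CSV must have a header row naming the channels; an optional column
#' named `"time"` (seconds) is dropped (sampling is taken as uniform at
#' `fs` from the config). The config is a YAML or JSON file (or an
#' already-parsed list) with keys `fs`, `roles` (channel -> Model/Imitator),
#' `regions` (channel -> region), and optionally `chromophore`.
#'
#' @param path CSV file of the time series.
#' @param config path to a YAML/JSON config, or a list.
#' @return a [dyad_recording()].
#' @export
read_recording <- function(path, config) {
  cfg <- read_config(config)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if ("time" %in% names(dt)) dt <- dt[setdiff(names(dt), "time")]
  labels <- names(dt)
  for (nm in labels) {
    if (!is.numeric(dt[[nm]]))
      stop("non-numeric values in channel column '", nm, "'")
  }
  unknown <- setdiff(names(cfg$roles), labels)
  if (length(unknown))
    stop("config references absent channel(s): ",
         paste(unknown, collapse = ", "))
  dyad_recording(as.matrix(dt), fs = cfg$fs, channel_labels = labels,
                 role_map = unlist(cfg$roles),
                 region_map = unlist(cfg$regions),
                 chromophore = cfg$chromophore %||% "HbO")
}

read_config <- function(config) {
  if (is.list(config)) return(config)
  if (grepl("\\.json$", config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config)
  }
}

#' Write a dyad recording (and its config) to CSV/YAML
#'
#' Values are written at full double precision so that
#' `read_recording(write_recording(...))` round-trips exactly.
#'
#' @param rec a [dyad_recording()].
#' @param path output CSV path.
#' @param config_path optional YAML path for the channel map; defaults to
#'   `path` with a `.yaml` extension.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(rec, path, config_path = NULL) {
  stopifnot(inherits(rec, "dyad_recording"))
  if (is.null(config_path)) config_path <- sub("\\.[^.]+$", ".yaml", path)
  # %.17g guarantees the doubles survive the text round trip bit-exactly
  txt <- as.data.frame(apply(rec$samples, 2L, sprintf, fmt = "%.17g"),
                       stringsAsFactors = FALSE)
  data.table::fwrite(txt, path, quote = FALSE)
  cfg <- list(fs = rec$fs,
              roles = as.list(rec$role_map),
              regions = as.list(rec$region_map),
              chromophore = rec$chromophore,
              sdc_channels = rec$channel_labels[rec$region_map == "SDC"])
  yaml::write_yaml(cfg, config_path)
  invisible(c(path, config_path))
}

#' Read / write an event table (CSV)
#'
#' @param path CSV with columns onset, duration, condition, trial_index.
#' @return an [event_table()].
#' @export
read_events <- function(path) {
  ev <- data.table::fread(path, data.table = FALSE)
  event_table(ev$onset, ev$duration, ev$condition, ev$trial_index)
}

#' @rdname read_events
#' @param events an [event_table()].
#' @export
write_events <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

#' Construct a dyad epoch
#'
#' The unit of causal analysis: one task or baseline interval of one
#' region's channels for both participants, columns ordered Model block
#' first, Imitator block second, both blocks of equal width `N`.
#'
#' @param data numeric `L x 2N` matrix with no missing values.
#' @param n_per_participant channels per participant (`N`).
#' @param fs sampling frequency (Hz).
#' @param condition,region,dyad_id,trial_index epoch metadata.
#' @return an object of class `dyad_epoch`.
#' @export
dyad_epoch <- function(data, n_per_participant, fs, condition = NA_character_,
                       region = NA_character_, dyad_id = NA_character_,
                       trial_index = NA_integer_) {
  data <- as.matrix(data)
  N <- as.integer(n_per_participant)
  if (ncol(data) != 2L * N)
    stop("epoch must have 2N columns (Model block then Imitator block)")
  if (anyNA(data))
    stop("epoch contains missing values; causal estimates are lag-sensitive, ",
         "missing data must be handled upstream")
  structure(
    list(data = data, N = N, L = nrow(data), fs = fs, condition = condition,
         region = region, dyad_id = dyad_id, trial_index = trial_index),
    class = "dyad_epoch")
}

#' Extract fixed-length epochs around event onsets
#'
#' For each event, takes `epoch_length` samples starting `pre_onset` samples
#' before the onset (half-open window, 0-based sample indexing). Only the
#' requested region's channels are kept, Model block first. Events whose
#' window does not fit inside the recording are skipped with a warning.
#'
#' @param rec a [dyad_recording()].
#' @param events an [event_table()].
#' @param region region name to extract (e.g. `"M1"`, `"SDC"`).
#' @param epoch_length window length in samples (default 204, i.e. a 20 s
#'   task interval at 10.17 Hz).
#' @param pre_onset samples taken before the onset (default 10, i.e. 1 s).
#' @param conditions optional subset of conditions to keep.
#' @return list of [dyad_epoch()] objects, in event order.
#' @export
extract_epochs <- function(rec, events, region, epoch_length = 204L,
                           pre_onset = 10L, conditions = NULL) {
  stopifnot(inherits(rec, "dyad_recording"))
  keep <- rec$channel_labels[rec$region_map == region]
  if (!length(keep)) stop("no channels mapped to region '", region, "'")
  m_ch <- keep[rec$role_map[keep] == "Model"]
  i_ch <- keep[rec$role_map[keep] == "Imitator"]
  if (length(m_ch) != length(i_ch))
    stop("region '", region, "' has unequal Model/Imitator channel counts")
  L_total <- nrow(rec$samples)
  if (!is.null(conditions)) events <- events[events$condition %in% conditions, ]
  out <- list()
  for (r in seq_len(nrow(events))) {
    start <- round(events$onset[r] * rec$fs) - pre_onset   # 0-based
    if (start < 0 || start + epoch_length > L_total) {
      warning(sprintf(
        "event %d (onset %.2f s): window [%d, %d) outside recording; skipped",
        r, events$onset[r], start, start + epoch_length))
      next
    }
    rows <- seq.int(start + 1L, start + epoch_length)
    out[[length(out) + 1L]] <- dyad_epoch(
      data = rec$samples[rows, c(m_ch, i_ch), drop = FALSE],
      n_per_participant = length(m_ch), fs = rec$fs,
      condition = events$condition[r], region = region,
      trial_index = events$trial_index[r])
  }
  out
}

#' Write causal results to disk
#'
#' Writes a summary CSV (one row per epoch: dyad, trial, region, condition,
#' signed band value, intensity, decision) and a companion per-frequency
#' CSV holding the directed spectra and the causal spectrum of every epoch.
#'
#' @param results a `data.frame` of per-epoch results as produced by
#'   [run_analysis()] (its `$summary` element), or a list with elements
#'   `summary` and `spectra`.
#' @param path output CSV path; the spectra file gets suffix
#'   `_spectra.csv`.
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, path) {
  if (is.data.frame(results)) results <- list(summary = results)
  if (is.null(results$summary) || nrow(results$summary) == 0L)
    stop("no results to write")
  data.table::fwrite(results$summary, path)
  paths <- path
  if (!is.null(results$spectra)) {
    spath <- sub("\\.csv$", "_spectra.csv", path)
    data.table::fwrite(results$spectra, spath)
    paths <- c(paths, spath)
  }
  invisible(paths)
}
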