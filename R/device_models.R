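#' Device specification for a triaxial accelerometer logger
#'
#' A `device_spec` captures everything the pipeline needs to know about a
#' logger: its sampling regime (fixed-length high-frequency bursts at a set
#' recording interval, or continuous 1 Hz "heartbeat" sampling), the integer
#' encoding range of the raw unit-free digital numbers it emits, and how its
#' raw x/y/z channels map onto the semantic body axes sway (lateral), surge
#' (anterior-posterior) and heave (dorso-ventral). The mapping differs between
#' devices because the sensor is a fixed part of the housing; see
#' [burst_device()] and [continuous_device()] for the two deployments
#' supported out of the box.
#'
#' @param name identifier for the device.
#' @param mode `"burst"` or `"continuous"`.
#' @param sample_rate sampling frequency in Hz within a burst (burst mode) or
#'   overall (continuous mode).
#' @param burst_duration burst length in seconds (burst mode only).
#' @param recording_interval seconds between burst starts (burst mode only).
#' @param raw_min,raw_max integer bounds of the raw encoding.
#' @param axis_map named character vector mapping raw axis labels
#'   (`x`, `y`, `z`) onto semantic axes (`sway`, `surge`, `heave`); must be a
#'   bijection.
#' @param zero_offset raw count corresponding to 0 g (used when deriving
#'   orientation features from raw counts).
#' @param counts_per_g raw counts per 1 g, used by the simulator's affine
#'   g-to-count rendering.
#' @return an object of class `device_spec`.
#' @export
device_spec <- function(name, mode = c("burst", "continuous"), sample_rate,
                        burst_duration = NA_real_, recording_interval = NA_real_,
                        raw_min, raw_max, axis_map,
                        zero_offset = 0, counts_per_g = 1) {
  mode <- match.arg(mode)
  if (!is.numeric(raw_min) || !is.numeric(raw_max) || raw_min >= raw_max)
    stop("raw_min must be strictly less than raw_max")
  axis_map <- unlist(axis_map)
  if (!setequal(names(axis_map), c("x", "y", "z")) ||
      !setequal(unname(axis_map), c("sway", "surge", "heave")) ||
      anyDuplicated(axis_map))
    stop("axis_map must be a bijection from {x,y,z} onto {sway,surge,heave}")
  if (mode == "burst") {
    if (!is.finite(burst_duration) || !is.finite(recording_interval))
      stop("burst mode requires burst_duration and recording_interval")
  }
  structure(
    list(name = name, mode = mode, sample_rate = sample_rate,
         burst_duration = burst_duration,
         recording_interval = recording_interval,
         raw_min = raw_min, raw_max = raw_max,
         axis_map = axis_map[c("x", "y", "z")],
         zero_offset = zero_offset, counts_per_g = counts_per_g),
    class = "device_spec")
}

#' Built-in device specifications
#'
#' `burst_device()` is the burst-mode logger configuration used in the study
#' design this package targets: bursts of 2.43 s at 33.8 Hz (82 samples per
#' axis) every 20 s, encoded as unit-free digital numbers in 0..4095, with the
#' raw x axis measuring heave, y sway and z surge. `continuous_device()` is
#' the continuous logger: 1 Hz "heartbeat" sampling, signed counts in
#' -32000..32000, raw x measuring surge, y sway and z heave.
#'
#' The `zero_offset`/`counts_per_g` calibration constants (2048 and 512 counts
#' for the burst device; 0 and 8192 for the continuous one) fix the affine
#' g-to-count map used by the simulator and the count-to-orientation offset
#' used by the feature extractor. The raw values are unit-free, so any fixed
#' documented affine serves; these place +/-2 g comfortably inside each
#' encoding range.
#'
#' @return a `device_spec`.
#' @export
burst_device <- function() {
  device_spec("burst_logger", "burst", sample_rate = 33.8,
              burst_duration = 2.43, recording_interval = 20,
              raw_min = 0, raw_max = 4095,
              axis_map = c(x = "heave", y = "sway", z = "surge"),
              zero_offset = 2048, counts_per_g = 512)
}

#' @rdname burst_device
#' @export
continuous_device <- function() {
  device_spec("continuous_logger", "continuous", sample_rate = 1.0,
              raw_min = -32000, raw_max = 32000,
              axis_map = c(x = "surge", y = "sway", z = "heave"),
              zero_offset = 0, counts_per_g = 8192)
}

#' Number of samples per axis in one burst
#'
#' `floor(sample_rate * burst_duration)`; 82 for the default burst device.
#'
#' @param spec a burst-mode `device_spec`.
#' @return integer sample count.
#' @export
samples_per_burst <- function(spec) {
  stopifnot(inherits(spec, "device_spec"), spec$mode == "burst")
  as.integer(floor(spec$sample_rate * spec$burst_duration))
}

#' Permute a raw x/y/z triple onto semantic axes
#'
#' Pure permutation: values are moved, never transformed.
#'
#' @param raw numeric of length 3 (order x, y, z) or named.
#' @param axis_map bijection as in [device_spec()].
#' @return named numeric `c(sway=, surge=, heave=)`.
#' @export
to_semantic_axes <- function(raw, axis_map) {
  if (is.null(names(raw))) names(raw) <- c("x", "y", "z")
  out <- c(sway = NA_real_, surge = NA_real_, heave = NA_real_)
  for (r in c("x", "y", "z")) out[[axis_map[[r]]]] <- raw[[r]]
  out
}

# Inverse of axis_map: named vector semantic -> raw label.
invert_axis_map <- function(axis_map) {
  stats::setNames(names(axis_map), unname(axis_map))
}

#' Construct a burst
#'
#' A burst is one window of triaxial samples on the semantic axes, tagged with
#' the individual, device, start time and (optionally) a behavior label.
#' Burst-mode windows have a fixed length (82 for the default device);
#' continuous-mode behavior sections have variable length.
#'
#' @param individual individual identifier.
#' @param device device name (a `device_spec$name`).
#' @param start_time start time in seconds.
#' @param sway,surge,heave equal-length numeric sample vectors.
#' @param label behavior code, or `"mixed"` / `"unlabeled"`.
#' @return an object of class `acc_burst`.
#' @export
acc_burst <- function(individual, device, start_time, sway, surge, heave,
                      label = "unlabeled") {
  n <- length(sway)
  if (n < 1 || length(surge) != n || length(heave) != n)
    stop("sway, surge and heave must have identical length >= 1")
  structure(
    list(individual = as.character(individual), device = as.character(device),
         start_time = as.numeric(start_time),
         sway = as.numeric(sway), surge = as.numeric(surge),
         heave = as.numeric(heave), label = as.character(label)),
    class = "acc_burst")
}

#' @export
print.acc_burst <- function(x, ...) {
  cat(sprintf("<acc_burst> %s/%s t=%.2f n=%d label=%s\n",
              x$individual, x$device, x$start_time, length(x$sway), x$label))
  invisible(x)
}

burst_length <- function(burst) length(burst$sway)

# Sample timestamps of a burst at the given rate.
burst_times <- function(burst, sample_rate) {
  burst$start_time + (seq_len(burst_length(burst)) - 1) / sample_rate
}

#' Construct a raw sample stream
#'
#' Time-ordered raw triaxial samples from one continuous-mode device on one
#' individual. Values stay on the raw x/y/z axes (the device dialect); use
#' [segment_continuous()] to obtain semantic-axis behavior sections.
#'
#' @param individual individual identifier.
#' @param device device name.
#' @param samples data frame with columns `timestamp`, `x`, `y`, `z`.
#' @param spec the `device_spec`, used to validate value bounds.
#' @return an object of class `acc_stream`.
#' @export
acc_stream <- function(individual, device, samples, spec = NULL) {
  stopifnot(all(c("timestamp", "x", "y", "z") %in% names(samples)))
  if (is.unsorted(samples$timestamp, strictly = TRUE))
    stop("sample timestamps must be strictly increasing")
  if (!is.null(spec)) {
    vals <- c(samples$x, samples$y, samples$z)
    if (any(vals < spec$raw_min | vals > spec$raw_max))
      stop(sprintf("sample value outside [%s, %s]", spec$raw_min, spec$raw_max))
  }
  structure(list(individual = as.character(individual),
                 device = as.character(device),
                 samples = samples[, c("timestamp", "x", "y", "z")]),
            class = "acc_stream")
}

#' @export
print.acc_stream <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<acc_stream> %s/%s %d samples spanning %.0f s\n",
              x$individual, x$device, n,
              if (n) diff(range(x$samples$timestamp)) + 1 else 0))
  invisible(x)
}

iso8601 <- function(t) {
  op <- options(digits.secs = 3); on.exit(options(op))
  format(as.POSIXct(round(t, 3), origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%OS3Z")
}

parse_iso8601 <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(t)) stop("unparseable ISO-8601 timestamp: ", s[which(is.na(t))[1]])
  round(as.numeric(t), 3)
}

#' Write bursts in the canonical long-form burst CSV dialect
#'
#' Columns `tag_id,individual,burst_start_iso8601,axis,sample_index,value`;
#' one row per sample, with `axis` given as the device's raw axis label (the
#' semantic values are mapped back through the inverse axis map so the file
#' matches what the logger would export).
#'
#' @param bursts list of [acc_burst()] objects.
#' @param path output file.
#' @param spec the device's `device_spec`.
#' @export
write_burst_csv <- function(bursts, path, spec) {
  inv <- invert_axis_map(spec$axis_map)
  rows <- lapply(bursts, function(b) {
    n <- burst_length(b)
    data.frame(
      tag_id = b$device, individual = b$individual,
      burst_start_iso8601 = iso8601(b$start_time),
      axis = rep(c("x", "y", "z"), each = n),
      sample_index = rep(seq_len(n) - 1L, 3L),
      value = c(b[[spec$axis_map[["x"]]]], b[[spec$axis_map[["y"]]]],
                b[[spec$axis_map[["z"]]]]),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read the canonical burst CSV dialect
#'
#' Parses the long-form dialect written by [write_burst_csv()], remaps raw
#' axes onto semantic axes and returns one unlabeled [acc_burst()] per
#' recorded burst. Malformed rows, out-of-range values and bursts whose
#' per-axis sample count differs from the device's nominal count are hard
#' errors.
#'
#' @param path input file.
#' @param spec a burst-mode `device_spec`.
#' @return list of `acc_burst`.
#' @export
read_burst_csv <- function(path, spec) {
  stopifnot(spec$mode == "burst")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  need <- c("tag_id", "individual", "burst_start_iso8601", "axis",
            "sample_index", "value")
  if (!all(need %in% names(df)))
    stop("burst CSV must have columns ", paste(need, collapse = ","))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) | val != round(val) | !(df$axis %in% c("x", "y", "z")))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path))
  out_of_range <- which(val < spec$raw_min | val > spec$raw_max)
  if (length(out_of_range))
    stop(sprintf("value %s at line %d outside [%s, %s]",
                 df$value[out_of_range[1]], out_of_range[1] + 1L,
                 spec$raw_min, spec$raw_max))
  df$value <- val
  n_expect <- samples_per_burst(spec)
  key <- paste(df$individual, df$burst_start_iso8601, sep = "\r")
  bursts <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    axes <- split(g, g$axis)
    lens <- vapply(axes, nrow, integer(1))
    if (length(axes) != 3L || any(lens != n_expect))
      stop(sprintf("burst %s/%s has %s samples per axis, expected %d",
                   g$individual[1], g$burst_start_iso8601[1],
                   paste(lens, collapse = "/"), n_expect))
    vals <- lapply(axes, function(a) a$value[order(a$sample_index)])
    acc_burst(g$individual[1], spec$name,
              parse_iso8601(g$burst_start_iso8601[1]),
              sway = vals[[invert_axis_map(spec$axis_map)[["sway"]]]],
              surge = vals[[invert_axis_map(spec$axis_map)[["surge"]]]],
              heave = vals[[invert_axis_map(spec$axis_map)[["heave"]]]])
  })
  unname(bursts)
}

#' Write a continuous-mode sample stream as CSV
#'
#' Columns `individual,timestamp_iso8601,x,y,z`; gaps remain absent rows.
#'
#' @param stream an [acc_stream()].
#' @param path output file.
#' @export
write_continuous_csv <- function(stream, path) {
  df <- data.frame(individual = stream$individual,
                   timestamp_iso8601 = iso8601(stream$samples$timestamp),
                   x = stream$samples$x, y = stream$samples$y,
                   z = stream$samples$z, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a continuous-mode export
#'
#' Accepts CSV with columns `timestamp_iso8601,x,y,z` plus optional
#' `individual`, `pitch` and `roll` columns. Vendor-supplied pitch/roll are
#' ignored (orientation is always recomputed downstream so both devices share
#' one definition). Gaps in the 1 Hz cadence are preserved, never
#' interpolated. Non-monotone timestamps and out-of-range values are errors.
#'
#' @param path input file.
#' @param spec a continuous-mode `device_spec`.
#' @param individual identifier; required unless the file has an
#'   `individual` column.
#' @return an `acc_stream`.
#' @export
read_continuous_csv <- function(path, spec, individual = NULL) {
  stopifnot(spec$mode == "continuous")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_iso8601", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("continuous CSV must have columns ", paste(need, collapse = ","))
  if (is.null(individual)) {
    if (!"individual" %in% names(df))
      stop("individual must be given or present as a column")
    individual <- unique(df$individual)
    if (length(individual) != 1L)
      stop("continuous CSV mixes individuals; read them separately")
  }
  samples <- data.frame(timestamp = parse_iso8601(df$timestamp_iso8601),
                        x = df$x, y = df$y, z = df$z)
  acc_stream(individual, spec$name, samples, spec = spec)
}

#' Read / write ethogram interval files
#'
#' Observation protocols as timed behavior intervals: CSV columns
#' `individual,start_iso8601,end_iso8601,behavior_code`. Internally an
#' ethogram is a data frame with numeric `start`/`end` seconds and a
#' `behavior` column; intervals of one individual must not overlap.
#'
#' @param path file path.
#' @param ethogram data frame with columns `individual`, `start`, `end`,
#'   `behavior`.
#' @return `read_ethogram_csv`: the validated ethogram data frame.
#' @export
read_ethogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "start_iso8601", "end_iso8601", "behavior_code")
  if (!all(need %in% names(df)))
    stop("ethogram CSV must have columns ", paste(need, collapse = ","))
  out <- data.frame(individual = df$individual,
                    start = parse_iso8601(df$start_iso8601),
                    end = parse_iso8601(df$end_iso8601),
                    behavior = df$behavior_code, stringsAsFactors = FALSE)
  validate_ethogram(out)
}

#' @rdname read_ethogram_csv
#' @export
write_ethogram_csv <- function(ethogram, path) {
  df <- data.frame(individual = ethogram$individual,
                   start_iso8601 = iso8601(ethogram$start),
                   end_iso8601 = iso8601(ethogram$end),
                   behavior_code = ethogram$behavior, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

validate_ethogram <- function(ethogram) {
  stopifnot(all(c("individual", "start", "end", "behavior") %in% names(ethogram)))
  if (any(ethogram$start >= ethogram$end))
    stop("ethogram intervals must satisfy start < end")
  for (ind in unique(ethogram$individual)) {
    e <- ethogram[ethogram$individual == ind, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping ethogram intervals for individual ", ind)
  }
  ethogram[order(ethogram$individual, ethogram$start), , drop = FALSE]
}
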