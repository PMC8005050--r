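#' Behavior signal signature
#'
#' The generator models the head-mounted accelerometer signal of one behavior
#' as a static gravity projection per semantic axis (encoding the typical
#' head/neck posture: head-down behaviors such as ground feeding or drinking
#' load the surge axis, head-up behaviors the heave axis), plus zero or more
#' sinusoidal components (chewing or gait oscillations), plus white Gaussian
#' sensor noise.
#'
#' @param code behavior code (e.g. `"STA"`, `"FEG"`, `"WAL"`).
#' @param static_g named numeric `c(sway=, surge=, heave=)`, mean gravity
#'   projection in g.
#' @param periodic list of `list(axis=, amplitude=, frequency=)` components;
#'   frequencies must lie below the burst-mode Nyquist limit (16.9 Hz).
#' @param noise_sd per-axis Gaussian noise sd in g (scalar).
#' @param dwell mean bout duration in seconds.
#' @return object of class `behavior_signature`.
#' @export
behavior_signature <- function(code, static_g, periodic = list(),
                               noise_sd = 0.05, dwell = 60) {
  stopifnot(setequal(names(static_g), c("sway", "surge", "heave")),
            noise_sd >= 0, dwell > 0)
  for (p in periodic) {
    stopifnot(p$axis %in% c("sway", "surge", "heave"), p$amplitude >= 0)
    if (p$frequency >= 33.8 / 2)
      stop("periodic frequency must be below the burst-mode Nyquist rate")
  }
  structure(list(code = code,
                 static_g = static_g[c("sway", "surge", "heave")],
                 periodic = periodic, noise_sd = noise_sd, dwell = dwell),
            class = "behavior_signature")
}

sig <- function(code, sway, surge, heave, periodic = list(),
                noise_sd = 0.05, dwell = 60) {
  behavior_signature(code, c(sway = sway, surge = surge, heave = heave),
                     periodic, noise_sd, dwell)
}

#' Default behavior signature set
#'
#' Eight behavior categories analyzable on both devices (standing, three
#' feeding heights plus ground feeding, rumination, drinking, walking), plus
#' the quiet-standing reference micro-behavior `STA_STILL` used for
#' calibration. Static gravity projections are mutually separated by at least
#' three noise standard deviations (minimum pairwise gap 0.2 g at
#' `noise_sd = 0.05` g), so the classes are separable in principle while the
#' posture-similar pairs (rumination vs. mid-level feeding, drinking vs.
#' ground feeding) stay the closest, mirroring the confusion structure real
#' head-mounted data shows. Chewing and gait oscillations sit at 0.9-2.4 Hz.
#'
#' @return named list of [behavior_signature()] objects.
#' @export
default_signatures <- function() {
  sigs <- list(
    sig("STA",  0.00,  0.00, 1.00, dwell = 120),
    sig("FEA",  0.00, -0.50, 0.87, dwell = 90),
    sig("FTM",  0.00,  0.20, 0.98, dwell = 90,
        periodic = list(list(axis = "surge", amplitude = 0.12, frequency = 1.0))),
    sig("FED",  0.00,  0.50, 0.87, dwell = 60),
    sig("FEG",  0.00,  0.80, 0.60, dwell = 60),
    sig("RUM",  0.20,  0.00, 0.98, dwell = 150,
        periodic = list(list(axis = "sway", amplitude = 0.12, frequency = 0.9))),
    sig("DRI",  0.15,  0.90, 0.44, dwell = 60),
    sig("WAL", -0.20,  0.10, 0.97, dwell = 60,
        periodic = list(list(axis = "surge", amplitude = 0.35, frequency = 1.2),
                        list(axis = "heave", amplitude = 0.15, frequency = 2.4))),
    sig("STA_STILL", 0.00, 0.00, 1.00, noise_sd = 0.01, dwell = 60))
  stats::setNames(sigs, vapply(sigs, `[[`, "", "code"))
}

#' Synthetic scenario configuration
#'
#' Describes one simulated observation campaign: the individuals, the
#' behavior signature set, optional per-individual additive axis offsets (in
#' g) modeling attachment/orientation shifts between deployments, the session
#' length, dropout behavior of the continuous device, and the master seed.
#' Output is bit-reproducible for a fixed configuration.
#'
#' @param individuals character vector of identifiers.
#' @param signatures named list of [behavior_signature()]; defaults to
#'   [default_signatures()].
#' @param axis_offsets optional named list (by individual) of
#'   `c(sway=, surge=, heave=)` offsets in g; missing individuals get zero.
#' @param session_length session duration in seconds (default 28800 s, one
#'   8 h observation day).
#' @param seed integer master seed.
#' @param dropout_rate per-second probability that a continuous-device sample
#'   is lost in transmission.
#' @param dropout_intervals optional list of `c(start, end)` intervals during
#'   which the continuous device records nothing.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(individuals = c("giraffe1", "giraffe2", "giraffe3"),
                            signatures = default_signatures(),
                            axis_offsets = NULL,
                            session_length = 28800, seed = 1,
                            dropout_rate = 0.02, dropout_intervals = NULL) {
  stopifnot(length(individuals) >= 1, session_length > 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, `[[`, "", "code")
  offs <- lapply(individuals, function(ind) {
    o <- axis_offsets[[ind]]
    if (is.null(o)) c(sway = 0, surge = 0, heave = 0)
    else o[c("sway", "surge", "heave")]
  })
  names(offs) <- individuals
  structure(list(individuals = individuals, signatures = signatures,
                 axis_offsets = offs, session_length = session_length,
                 seed = as.integer(seed), dropout_rate = dropout_rate,
                 dropout_intervals = dropout_intervals),
            class = "scenario_config")
}

# Deterministic sub-seed for a stream of randomness, kept inside 32-bit range.
derive_seed <- function(seed, ind_index, stream) {
  as.integer((as.numeric(seed) * 97 + ind_index * 7919 + stream) %% 2147483629)
}

#' Draw the ground-truth behavior sequence
#'
#' Behavior bouts form a renewal process: codes are chosen by a uniform
#' Markov chain excluding self-transitions, bout durations are exponential
#' with each signature's mean dwell, and the final bout is truncated at the
#' session end. The returned ethogram exactly matches the emitted bouts, so
#' downstream labeling can be checked against it. The physical signal is
#' evaluated lazily via [truth_signal()].
#'
#' @param config a [scenario_config()].
#' @return object of class `acc_truth` with elements `ethogram` (data frame
#'   `individual,start,end,behavior`) and `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  codes <- names(config$signatures)
  bouts <- list()
  for (i in seq_along(config$individuals)) {
    ind <- config$individuals[i]
    set.seed(derive_seed(config$seed, i, 1L))
    t <- 0
    start <- numeric(0); end <- numeric(0); behavior <- character(0)
    current <- sample(codes, 1)
    while (t < config$session_length) {
      d <- stats::rexp(1, rate = 1 / config$signatures[[current]]$dwell)
      e <- min(t + d, config$session_length)
      start <- c(start, t); end <- c(end, e); behavior <- c(behavior, current)
      t <- e
      if (length(codes) > 1)
        current <- sample(setdiff(codes, current), 1)
    }
    bouts[[ind]] <- data.frame(individual = ind, start = start, end = end,
                               behavior = behavior, stringsAsFactors = FALSE)
  }
  ethogram <- do.call(rbind, bouts)
  rownames(ethogram) <- NULL
  structure(list(ethogram = validate_ethogram(ethogram), config = config),
            class = "acc_truth")
}

#' Evaluate the physical truth signal at arbitrary times
#'
#' Returns the semantic-axis acceleration in g at the requested times:
#' per-bout static gravity projection plus sinusoids (phase anchored at bout
#' start) plus the individual's attachment offset, and optionally Gaussian
#' sensor noise. Noise is drawn from a seed derived from the scenario seed,
#' the individual and `noise_stream`, so repeated identical calls are
#' bit-identical.
#'
#' @param truth an `acc_truth`.
#' @param individual which individual.
#' @param times numeric vector of seconds within the session.
#' @param noise add sensor noise? (`TRUE` for rendering, `FALSE` to inspect
#'   the deterministic component).
#' @param noise_stream integer distinguishing independent noise draws (each
#'   rendered device uses its own stream).
#' @return data frame with columns `time`, `sway`, `surge`, `heave` (g).
#' @export
truth_signal <- function(truth, individual, times, noise = TRUE,
                         noise_stream = 2L) {
  cfg <- truth$config
  i <- match(individual, cfg$individuals)
  if (is.na(i)) stop("unknown individual: ", individual)
  eth <- truth$ethogram[truth$ethogram$individual == individual, ]
  idx <- findInterval(times, eth$start)
  if (any(idx < 1 | times >= cfg$session_length))
    stop("times must lie within [0, session_length)")
  out <- matrix(0, nrow = length(times), ncol = 3,
                dimnames = list(NULL, c("sway", "surge", "heave")))
  for (b in unique(idx)) {
    s <- cfg$signatures[[eth$behavior[b]]]
    in_b <- idx == b
    tt <- times[in_b] - eth$start[b]
    for (ax in c("sway", "surge", "heave")) {
      v <- rep(s$static_g[[ax]], sum(in_b))
      for (p in s$periodic)
        if (p$axis == ax)
          v <- v + p$amplitude * sin(2 * pi * p$frequency * tt)
      out[in_b, ax] <- v
    }
    if (noise && s$noise_sd > 0) {
      set.seed(derive_seed(cfg$seed, i, noise_stream * 100000L + b))
      out[in_b, ] <- out[in_b, ] +
        matrix(stats::rnorm(3 * sum(in_b), sd = s$noise_sd), ncol = 3)
    }
  }
  off <- cfg$axis_offsets[[individual]]
  data.frame(time = times,
             sway = out[, "sway"] + off[["sway"]],
             surge = out[, "surge"] + off[["surge"]],
             heave = out[, "heave"] + off[["heave"]])
}

# Affine g -> integer counts with clipping into the encoding range.
g_to_counts <- function(g, spec) {
  pmin(pmax(round(spec$zero_offset + spec$counts_per_g * g),
            spec$raw_min), spec$raw_max)
}

#' Render the truth through a device model
#'
#' Burst mode: windows of `burst_duration` seconds sampled at `sample_rate`
#' every `recording_interval` seconds, affine-mapped from g to raw counts,
#' clipped into the encoding range and integer-quantized; returns unlabeled
#' semantic-axis bursts. Continuous mode: 1 Hz sampling with configured
#' dropout seconds removed; returns an [acc_stream()] on the device's raw
#' axes, as a real export would look.
#'
#' @param truth an `acc_truth` from [generate_truth()].
#' @param individual which individual to render.
#' @param spec the target `device_spec`.
#' @return list of `acc_burst` (burst mode) or an `acc_stream` (continuous).
#' @export
render_device <- function(truth, individual, spec) {
  cfg <- truth$config
  i <- match(individual, cfg$individuals)
  if (is.na(i)) stop("unknown individual: ", individual)
  if (spec$mode == "burst") {
    n <- samples_per_burst(spec)
    starts <- seq(0, cfg$session_length - spec$burst_duration,
                  by = spec$recording_interval)
    times <- rep(starts, each = n) + (seq_len(n) - 1) / spec$sample_rate
    g <- truth_signal(truth, individual, times, noise_stream = 2L)
    lapply(seq_along(starts), function(k) {
      rows <- ((k - 1) * n + 1):(k * n)
      acc_burst(individual, spec$name, starts[k],
                sway = g_to_counts(g$sway[rows], spec),
                surge = g_to_counts(g$surge[rows], spec),
                heave = g_to_counts(g$heave[rows], spec))
    })
  } else {
    times <- seq(0, floor(cfg$session_length) - 1)
    keep <- rep(TRUE, length(times))
    for (iv in cfg$dropout_intervals)
      keep <- keep & !(times >= iv[1] & times < iv[2])
    if (cfg$dropout_rate > 0) {
      set.seed(derive_seed(cfg$seed, i, 3L))
      keep <- keep & (stats::runif(length(times)) >= cfg$dropout_rate)
    }
    times <- times[keep]
    g <- truth_signal(truth, individual, times, noise_stream = 4L)
    sem <- list(sway = g_to_counts(g$sway, spec),
                surge = g_to_counts(g$surge, spec),
                heave = g_to_counts(g$heave, spec))
    acc_stream(individual, spec$name,
               data.frame(timestamp = times,
                          x = sem[[spec$axis_map[["x"]]]],
                          y = sem[[spec$axis_map[["y"]]]],
                          z = sem[[spec$axis_map[["z"]]]]),
               spec = spec)
  }
}
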