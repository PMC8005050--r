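#' Label bursts from an ethogram
#'
#' Assigns each burst the behavior observed while it was recorded. Interval
#' containment is half-open `[start, end)` with no tolerance slack: a burst
#' belongs to an interval iff every sample timestamp falls inside it. A burst
#' with any sample outside all observed intervals is `"unlabeled"`; a fully
#' observed burst spanning two or more behaviors is `"mixed"`. Labeling is
#' exhaustive and exclusive: every burst receives exactly one of
#' behavior code / mixed / unlabeled.
#'
#' @param bursts list of [acc_burst()].
#' @param ethogram data frame `individual,start,end,behavior` (see
#'   [read_ethogram_csv()]).
#' @param spec the `device_spec` (supplies the sample rate used to place the
#'   burst's samples in time).
#' @return the bursts, relabeled.
#' @export
label_bursts <- function(bursts, ethogram, spec) {
  ethogram <- validate_ethogram(ethogram)
  by_ind <- split(ethogram, ethogram$individual)
  lapply(bursts, function(b) {
    e <- by_ind[[b$individual]]
    b$label <- if (is.null(e)) "unlabeled" else {
      tt <- burst_times(b, spec$sample_rate)
      idx <- findInterval(tt, e$start)
      covered <- idx >= 1 & tt < e$end[pmax(idx, 1)]
      if (!all(covered)) "unlabeled"
      else {
        beh <- unique(e$behavior[idx])
        if (length(beh) > 1) "mixed" else beh
      }
    }
    b
  })
}

#' Segment a continuous stream into labeled behavior sections
#'
#' The continuous device's 1 Hz stream is cut into behavior sections: one
#' burst per maximal run of consecutive (1 s apart) samples that fall inside
#' a single ethogram interval (half-open `[start, end)`). Transmission gaps
#' split sections; samples in unobserved time are dropped. Sections have
#' variable length and carry their behavior label; raw axes are remapped onto
#' semantic axes here.
#'
#' @param stream an [acc_stream()].
#' @param ethogram ethogram data frame.
#' @param spec the continuous-mode `device_spec`.
#' @return list of labeled `acc_burst` (variable length).
#' @export
segment_continuous <- function(stream, ethogram, spec) {
  stopifnot(spec$mode == "continuous")
  ethogram <- validate_ethogram(ethogram)
  e <- ethogram[ethogram$individual == stream$individual, ]
  if (nrow(e) == 0) return(list())
  s <- stream$samples
  idx <- findInterval(s$timestamp, e$start)
  covered <- idx >= 1 & s$timestamp < e$end[pmax(idx, 1)]
  # a new section starts on a gap > 1 s, an interval change, or coverage edge
  run <- cumsum(c(TRUE, diff(s$timestamp) != 1 | diff(idx) != 0 |
                    diff(covered) != 0))
  keep <- which(covered)
  if (!length(keep)) return(list())
  sections <- split(keep, run[keep])
  unname(lapply(sections, function(rows) {
    sem <- lapply(c("sway", "surge", "heave"), function(ax) {
      raw <- invert_axis_map(spec$axis_map)[[ax]]
      s[[raw]][rows]
    })
    acc_burst(stream$individual, stream$device, s$timestamp[rows[1]],
              sway = sem[[1]], surge = sem[[2]], heave = sem[[3]],
              label = e$behavior[idx[rows[1]]])
  }))
}

#' Filter to pure-behavior bursts
#'
#' Only bursts during which exactly one observed behavior occurred enter the
#' analysis data set; mixed and unlabeled bursts are excluded. Per-category
#' counts are recorded on the returned dataset.
#'
#' @param bursts labeled bursts (from [label_bursts()] or
#'   [segment_continuous()]).
#' @param device device name recorded in the provenance (taken from the
#'   first burst if omitted).
#' @return object of class `acc_dataset`: list with `bursts`, `counts`
#'   (table by individual x label) and `provenance`.
#' @export
filter_pure <- function(bursts, device = NULL) {
  labels <- vapply(bursts, `[[`, "", "label")
  keep <- !(labels %in% c("mixed", "unlabeled"))
  kept <- bursts[keep]
  if (!length(kept)) warning("no pure-behavior bursts retained")
  inds <- vapply(kept, `[[`, "", "individual")
  counts <- table(individual = inds, label = labels[keep])
  if (is.null(device))
    device <- if (length(kept)) kept[[1]]$device else NA_character_
  structure(list(bursts = kept, counts = counts,
                 provenance = list(device = device,
                                   individuals = sort(unique(inds)),
                                   n = length(kept))),
            class = "acc_dataset")
}

#' @export
print.acc_dataset <- function(x, ...) {
  cat(sprintf("<acc_dataset> %d bursts, device %s\n", length(x$bursts),
              x$provenance$device))
  print(x$counts)
  invisible(x)
}

dataset_labels <- function(dataset) vapply(dataset$bursts, `[[`, "", "label")
dataset_individuals <- function(dataset)
  vapply(dataset$bursts, `[[`, "", "individual")

#' Drop bursts with a given label from a dataset
#'
#' Used to remove the quiet-standing calibration reference bursts before
#' classification.
#'
#' @param dataset an `acc_dataset`.
#' @param label label to remove.
#' @return filtered `acc_dataset`.
#' @export
drop_label <- function(dataset, label) {
  filter_pure(dataset$bursts[dataset_labels(dataset) != label],
              device = dataset$provenance$device)
}

#' Balanced per-category subsample
#'
#' Draws, for every individual and behavior category with at least `min_n`
#' pure bursts, exactly `n_per_category` bursts without replacement;
#' categories below the threshold are dropped entirely and reported (the
#' n < 30 exclusion rule). Deterministic under `seed`.
#'
#' @param dataset an `acc_dataset`.
#' @param n_per_category bursts to keep per individual and category
#'   (default 30).
#' @param seed RNG seed for the draw.
#' @param min_n minimum available count for a category to be analyzed
#'   (default `n_per_category`).
#' @return an `acc_dataset`; dropped (individual, category) pairs are in
#'   `$dropped`.
#' @export
balanced_subsample <- function(dataset, n_per_category = 30, seed = 1,
                               min_n = n_per_category) {
  stopifnot(n_per_category >= 1, min_n >= n_per_category)
  labels <- dataset_labels(dataset)
  inds <- dataset_individuals(dataset)
  key <- paste(inds, labels, sep = "\r")
  set.seed(seed)
  picked <- integer(0)
  dropped <- character(0)
  for (k in sort(unique(key))) {
    rows <- which(key == k)
    if (length(rows) >= min_n) {
      picked <- c(picked, sort(sample(rows, n_per_category)))
    } else {
      dropped <- c(dropped, sub("\r", "/", k))
    }
  }
  out <- filter_pure(dataset$bursts[picked],
                     device = dataset$provenance$device)
  out$dropped <- dropped
  out$provenance$subsample <- list(n_per_category = n_per_category,
                                   min_n = min_n, seed = seed)
  out
}
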