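#' Per-individual reference offsets from quiet standing
#'
#' Device attachment differs slightly between deployments, shifting each
#' axis's values. Because values vary little while an animal stands without
#' any movement, the per-axis arithmetic mean over all samples of all
#' quiet-standing reference bursts serves as that individual's orientation
#' reference. The reference micro-behavior must be annotated in the ethogram
#' (default code `"STA_STILL"`); stillness is never inferred from the signal.
#'
#' @param dataset an `acc_dataset` containing reference-labeled bursts.
#' @param reference_code label of the reference micro-behavior.
#' @return data frame with columns `individual`, `sway`, `surge`, `heave`
#'   (mean raw counts), one row per individual in the dataset; the device
#'   name is attached as attribute `"device"`.
#' @export
reference_offsets <- function(dataset, reference_code = "STA_STILL") {
  labels <- dataset_labels(dataset)
  inds <- dataset_individuals(dataset)
  out <- lapply(sort(unique(inds)), function(ind) {
    ref <- dataset$bursts[labels == reference_code & inds == ind]
    if (!length(ref))
      stop("no '", reference_code, "' reference bursts for individual ", ind,
           "; annotate quiet-standing intervals in the ethogram")
    data.frame(individual = ind,
               sway = mean(unlist(lapply(ref, `[[`, "sway"))),
               surge = mean(unlist(lapply(ref, `[[`, "surge"))),
               heave = mean(unlist(lapply(ref, `[[`, "heave"))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "device") <- dataset$provenance$device
  out
}

#' Harmonize a dataset onto a common orientation reference
#'
#' Applies the additive per-axis correction: every sample value `v` on axis
#' `a` of individual `A` becomes `v + (ref[a] - offsets[A, a])`, where `ref`
#' is the reference individual's quiet-standing mean (or an explicit named
#' target). Labels are untouched. Corrected values may leave the integer
#' encoding range; they are kept as real numbers and not re-clipped, since
#' clipping would distort the moment features. Harmonizing an already
#' harmonized dataset against the same reference is the identity.
#'
#' @param dataset an `acc_dataset`.
#' @param offsets per-individual offsets from [reference_offsets()], computed
#'   on the same device encoding.
#' @param reference either the name of the reference individual (a row of
#'   `offsets`) or a named numeric `c(sway=, surge=, heave=)` target.
#' @return the harmonized `acc_dataset`.
#' @export
harmonize <- function(dataset, offsets, reference) {
  dev <- attr(offsets, "device")
  if (!is.null(dev) && !is.na(dev) && !identical(dev, dataset$provenance$device))
    stop("offsets were computed on device '", dev, "' but dataset is from '",
         dataset$provenance$device, "'")
  if (is.character(reference)) {
    row <- offsets[offsets$individual == reference, ]
    if (nrow(row) != 1) stop("reference individual not found in offsets")
    ref <- c(sway = row$sway, surge = row$surge, heave = row$heave)
  } else {
    ref <- reference[c("sway", "surge", "heave")]
  }
  dataset$bursts <- lapply(dataset$bursts, function(b) {
    row <- offsets[offsets$individual == b$individual, ]
    if (nrow(row) != 1)
      stop("no offsets for individual ", b$individual)
    b$sway <- b$sway + (ref[["sway"]] - row$sway)
    b$surge <- b$surge + (ref[["surge"]] - row$surge)
    b$heave <- b$heave + (ref[["heave"]] - row$heave)
    b
  })
  dataset
}
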