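#' Segment nuclei from the DAPI-like channel
#'
#' Classical segmentation: Gaussian smoothing, global threshold (Otsu by
#' default), 8-connected component labelling, then an area filter. An
#' all-zero channel yields zero nuclei, not an error. Externally produced
#' label maps (from any segmentation tool) can bypass this step entirely
#' via [labeled_puncta()].
#'
#' @param channel 2-D numeric matrix, intensities >= 0.
#' @param min_area Minimum object area, pixels.
#' @param sigma Smoothing sigma, pixels.
#' @param threshold `"otsu"` or `"absolute"`.
#' @param threshold_value Cutoff for `threshold = "absolute"`.
#' @return A `labeled_puncta` object (channel tag "nuclei").
#' @export
segment_nuclei <- function(channel, min_area = 50, sigma = 3,
                           threshold = c("otsu", "absolute"),
                           threshold_value = NULL) {
  segment_blobs(channel, sigma, match.arg(threshold), threshold_value,
                min_area, tag = "nuclei")
}

#' Segment fluorescent puncta from a marker channel
#'
#' Same classical operator chain as [segment_nuclei()] with punctum-scale
#' defaults. Deterministic for fixed inputs.
#'
#' @inheritParams segment_nuclei
#' @param sigma_smooth Smoothing sigma, pixels.
#' @param threshold_rule `"otsu"` or `"absolute"`.
#' @param channel_tag Label recorded on the output ("pts1", "pmp70", ...).
#' @return A `labeled_puncta` object.
#' @export
segment_puncta <- function(channel, sigma_smooth = 1,
                           threshold_rule = c("otsu", "absolute"),
                           threshold_value = NULL, min_area = 4,
                           channel_tag = "puncta") {
  segment_blobs(channel, sigma_smooth, match.arg(threshold_rule),
                threshold_value, min_area, tag = channel_tag)
}

segment_blobs <- function(channel, sigma, threshold, threshold_value,
                          min_area, tag) {
  stopifnot(is.matrix(channel), length(channel) > 0)
  if (max(channel) == min(channel))  # blank or constant field
    return(labeled_puncta(matrix(0L, nrow(channel), ncol(channel)), tag))
  sm <- channel
  if (sigma > 0)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(channel), sigma = sigma))
  cut <- if (threshold == "otsu") {
    rng <- range(sm)
    EBImage::otsu((sm - rng[1]) / diff(rng), range = c(0, 1)) *
      diff(rng) + rng[1]
  } else {
    if (is.null(threshold_value)) stop("'threshold_value' required")
    threshold_value
  }
  lab <- label_components8(sm > cut)
  # area filter + relabel to consecutive ids
  areas <- tabulate(lab)
  keep <- which(areas >= min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  labeled_puncta(lab, tag)
}

# 8-connected labelling: EBImage::bwlabel (4-connected) then union-find
# merge of components touching diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n < 2) return(matrix(as.integer(lab), nrow(mask)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
  prs <- rbind(cbind(a1[a1 > 0 & b1 > 0 & a1 != b1],
                     b1[a1 > 0 & b1 > 0 & a1 != b1]),
               cbind(a2[a2 > 0 & b2 > 0 & a2 != b2],
                     b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(prs)) {
    for (k in seq_len(nrow(prs))) {
      ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  remap <- match(roots, sort(unique(roots)))
  out <- matrix(0L, h, w)
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Labeled objects (puncta or nuclei) with geometry table
#'
#' Wraps an integer label map (0 = background; labels consecutive positive
#' integers) with per-object area and centroid. Use this constructor to
#' import label maps produced by external segmentation tools.
#'
#' @param label_map Integer matrix.
#' @param channel Channel tag.
#' @return A `labeled_puncta`: list(label_map, objects = data.frame(id,
#'   area, row, col), channel). Centroids are 0-based (row, col) pixel
#'   coordinates.
#' @export
labeled_puncta <- function(label_map, channel = "puncta") {
  stopifnot(is.matrix(label_map))
  label_map <- matrix(as.integer(label_map), nrow(label_map))
  ids <- sort(unique(label_map[label_map > 0]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    stop("labels must be consecutive positive integers")
  objects <- if (length(ids)) {
    idx <- which(label_map > 0, arr.ind = TRUE)
    l <- label_map[label_map > 0]
    data.frame(id = ids,
               area = as.integer(tabulate(l, length(ids))),
               row = as.numeric(tapply(idx[, 1], l, mean)) - 1,
               col = as.numeric(tapply(idx[, 2], l, mean)) - 1,
               row.names = NULL)
  } else data.frame(id = integer(), area = integer(), row = numeric(),
                    col = numeric())
  structure(list(label_map = label_map, objects = objects,
                 channel = channel),
            class = "labeled_puncta")
}

#' @export
print.labeled_puncta <- function(x, ...) {
  cat("labeled_puncta (", x$channel, "): ", nrow(x$objects),
      " object(s)\n", sep = "")
  invisible(x)
}

#' Classify peroxisomes as functional or ghost by PTS1 overlap
#'
#' Peroxisomes are defined by PMP70 puncta. For each PMP70 punctum the
#' overlap fraction is the share of its pixels covered by any PTS1
#' punctum; puncta at or above `min_overlap_fraction` import the PTS1
#' reporter and are functional, the rest are ghosts (import-defective).
#' PTS1-only puncta never create peroxisome calls. Functional + ghost
#' always equals the number of PMP70 puncta.
#'
#' @param pmp70 `labeled_puncta` for the PMP70 channel.
#' @param pts1 `labeled_puncta` for the PTS1 channel (same shape).
#' @param nuclei Optional `labeled_puncta` for nuclei (for field totals).
#' @param min_overlap_fraction Functional-call threshold on the overlap
#'   fraction (default 0.1; any value > 0 with a shared pixel can be
#'   requested by passing a tiny threshold).
#' @return A `peroxisome_calls`: list(puncta = data.frame(id, area,
#'   overlap_fraction, class), n_functional, n_ghost, n_nuclei,
#'   min_overlap_fraction).
#' @export
classify_peroxisomes <- function(pmp70, pts1, nuclei = NULL,
                                 min_overlap_fraction = 0.1) {
  stopifnot(inherits(pmp70, "labeled_puncta"),
            inherits(pts1, "labeled_puncta"))
  if (!identical(dim(pmp70$label_map), dim(pts1$label_map)))
    stop("label maps differ in shape")
  n <- nrow(pmp70$objects)
  pm <- pmp70$label_map
  covered <- pts1$label_map > 0
  ov <- if (n) {
    hit <- tabulate(pm[pm > 0 & covered], n)
    hit / pmp70$objects$area
  } else numeric()
  cls <- ifelse(ov >= min_overlap_fraction, "functional", "ghost")
  structure(list(
    puncta = data.frame(id = pmp70$objects$id, area = pmp70$objects$area,
                        overlap_fraction = ov, class = cls,
                        row.names = NULL),
    n_functional = sum(cls == "functional"),
    n_ghost = sum(cls == "ghost"),
    n_nuclei = if (is.null(nuclei)) NA_integer_ else nrow(nuclei$objects),
    min_overlap_fraction = min_overlap_fraction),
    class = "peroxisome_calls")
}

#' @export
print.peroxisome_calls <- function(x, ...) {
  cat("peroxisome_calls:", x$n_functional, "functional +", x$n_ghost,
      "ghost peroxisomes;", x$n_nuclei, "nuclei\n")
  invisible(x)
}

#' Fraction of functional peroxisomes with Wilson interval
#'
#' @param calls A `peroxisome_calls` with >= 1 PMP70 punctum.
#' @param conf_level Confidence level for the Wilson score interval.
#' @return list(estimate, lower, upper, n).
#' @export
functional_fraction <- function(calls, conf_level = 0.95) {
  n <- calls$n_functional + calls$n_ghost
  if (n < 1L) stop("no PMP70 puncta in the field")
  # Wilson score interval; the chi-square continuity warning does not
  # concern the interval itself
  pt <- suppressWarnings(
    stats::prop.test(calls$n_functional, n, conf.level = conf_level,
                     correct = FALSE))
  list(estimate = calls$n_functional / n,
       lower = pt$conf.int[1], upper = pt$conf.int[2], n = n)
}

#' Peroxisomes per cell
#'
#' Total PMP70 puncta normalised by the number of nuclei in the field.
#'
#' @param calls A `peroxisome_calls` with `n_nuclei` >= 1.
#' @return Puncta per nucleus.
#' @export
peroxisomes_per_cell <- function(calls) {
  if (is.na(calls$n_nuclei) || calls$n_nuclei < 1L)
    stop("field has no segmented nuclei")
  (calls$n_functional + calls$n_ghost) / calls$n_nuclei
}

#' Punctum count and size statistics
#'
#' @param puncta A `labeled_puncta`.
#' @param pixel_size Micrometres per pixel (> 0).
#' @return list(count, mean_area_um2, median_area_um2, sd_area_um2); area
#'   statistics are NA when no puncta exist.
#' @export
puncta_size_stats <- function(puncta, pixel_size) {
  stopifnot(inherits(puncta, "labeled_puncta"))
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  a <- puncta$objects$area * pixel_size^2
  list(count = nrow(puncta$objects),
       mean_area_um2 = if (length(a)) mean(a) else NA_real_,
       median_area_um2 = if (length(a)) stats::median(a) else NA_real_,
       sd_area_um2 = if (length(a) > 1) stats::sd(a) else NA_real_)
}

#' Quantify a whole field end to end
#'
#' Convenience wrapper: segments nuclei and both punctum channels,
#' classifies peroxisomes, and returns the field-level summary row.
#'
#' @param image A `multichannel_image`.
#' @param min_overlap_fraction Passed to [classify_peroxisomes()].
#' @param punctum_min_area,nucleus_min_area Area filters, pixels.
#' @param threshold_rule Threshold rule for the punctum channels.
#' @param threshold_value Absolute cutoff when
#'   `threshold_rule = "absolute"`.
#' @return list(calls, summary = data.frame(n_functional, n_ghost,
#'   fraction, n_nuclei, puncta_per_cell, mean_area_um2)).
#' @export
quantify_field <- function(image, min_overlap_fraction = 0.1,
                           punctum_min_area = 4, nucleus_min_area = 50,
                           threshold_rule = "absolute",
                           threshold_value = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  nuc <- segment_nuclei(image$channels$nuclei, min_area = nucleus_min_area)
  pts1 <- segment_puncta(image$channels$pts1, threshold_rule = threshold_rule,
                         threshold_value = threshold_value,
                         min_area = punctum_min_area, channel_tag = "pts1")
  pmp70 <- segment_puncta(image$channels$pmp70,
                          threshold_rule = threshold_rule,
                          threshold_value = threshold_value,
                          min_area = punctum_min_area,
                          channel_tag = "pmp70")
  calls <- classify_peroxisomes(pmp70, pts1, nuc, min_overlap_fraction)
  n_tot <- calls$n_functional + calls$n_ghost
  size <- puncta_size_stats(pmp70, image$pixel_size)
  list(calls = calls, summary = data.frame(
    n_functional = calls$n_functional, n_ghost = calls$n_ghost,
    fraction = if (n_tot) calls$n_functional / n_tot else NA_real_,
    n_nuclei = calls$n_nuclei,
    puncta_per_cell = if (!is.na(calls$n_nuclei) && calls$n_nuclei > 0)
      n_tot / calls$n_nuclei else NA_real_,
    mean_area_um2 = size$mean_area_um2))
}
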