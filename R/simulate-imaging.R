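#' Ground-truth scene for a peroxisome imaging field
#'
#' Describes nuclei (filled discs) and puncta (isotropic Gaussian spots)
#' with per-channel amplitudes and an import class: `functional` puncta
#' emit in both the PTS1 reporter and PMP70 membrane-marker channels,
#' `ghost` puncta (import-defective) only in PMP70, and `pts1_only` spots
#' only in PTS1.
#'
#' @param image_shape Integer c(height, width) in pixels, each >= 16.
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param nuclei data.frame (row, col, radius) in pixels; may be empty.
#' @param puncta data.frame (row, col, sigma, amp_pts1, amp_pmp70, class)
#'   with class in functional/ghost/pts1_only; amplitudes must be
#'   consistent with the class.
#' @return A `scene_truth`.
#' @export
scene_truth <- function(image_shape, pixel_size, nuclei, puncta) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 16L))
    stop("'image_shape' must be height, width with both >= 16")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  stopifnot(all(c("row", "col", "radius") %in% names(nuclei)),
            all(c("row", "col", "sigma", "amp_pts1", "amp_pmp70",
                  "class") %in% names(puncta)))
  inside <- function(r, c) all(r >= 1 & r <= image_shape[1] &
                               c >= 1 & c <= image_shape[2])
  if (nrow(nuclei) && !inside(nuclei$row, nuclei$col))
    stop("nucleus centers must lie inside the image")
  if (nrow(puncta)) {
    if (!inside(puncta$row, puncta$col))
      stop("punctum centers must lie inside the image")
    if (any(puncta$sigma <= 0)) stop("punctum sigma must be > 0")
    cls <- puncta$class
    if (!all(cls %in% c("functional", "ghost", "pts1_only")))
      stop("unknown punctum class")
    bad <- (cls == "functional" & !(puncta$amp_pts1 > 0 & puncta$amp_pmp70 > 0)) |
           (cls == "ghost" & !(puncta$amp_pmp70 > 0 & puncta$amp_pts1 == 0)) |
           (cls == "pts1_only" & !(puncta$amp_pts1 > 0 & puncta$amp_pmp70 == 0))
    if (any(bad)) stop("punctum amplitudes inconsistent with class")
  }
  structure(list(image_shape = image_shape, pixel_size = pixel_size,
                 nuclei = nuclei, puncta = puncta),
            class = "scene_truth")
}

#' Random peroxisome scene with known composition
#'
#' Places the requested numbers of functional, ghost and PTS1-only puncta
#' plus nuclei at random positions with a minimum pairwise separation, so
#' that segmentation can recover every object.
#'
#' @param n_functional,n_ghost,n_pts1_only Punctum counts by class.
#' @param n_nuclei Nucleus count.
#' @param image_shape c(height, width) pixels.
#' @param pixel_size Micrometres per pixel.
#' @param sigma Punctum Gaussian sigma, pixels.
#' @param amplitude Spot peak amplitude, intensity units.
#' @param nucleus_radius Nucleus disc radius, pixels.
#' @param min_sep Minimum centre-to-centre separation between puncta,
#'   pixels.
#' @param seed Integer RNG seed.
#' @return A `scene_truth`.
#' @export
simulate_scene <- function(n_functional, n_ghost, n_pts1_only = 0L,
                           n_nuclei = 3L, image_shape = c(192L, 192L),
                           pixel_size = 0.2, sigma = 1.5, amplitude = 2000,
                           nucleus_radius = 12, min_sep = 10, seed = 1L) {
  set.seed(seed)
  n_p <- n_functional + n_ghost + n_pts1_only
  margin <- ceiling(4 * sigma) + 1
  pos <- place_separated(n_p, image_shape, margin, min_sep)
  cls <- rep(c("functional", "ghost", "pts1_only"),
             c(n_functional, n_ghost, n_pts1_only))
  puncta <- data.frame(
    row = pos[, 1], col = pos[, 2], sigma = sigma,
    amp_pts1 = ifelse(cls == "ghost", 0, amplitude),
    amp_pmp70 = ifelse(cls == "pts1_only", 0, amplitude),
    class = cls)
  # nuclei are smoothed at a coarser scale than puncta downstream, so
  # they need a wider clearance to stay separable
  npos <- place_separated(n_nuclei, image_shape, nucleus_radius + 2,
                          2 * nucleus_radius + 16)
  nuclei <- data.frame(row = npos[, 1], col = npos[, 2],
                       radius = nucleus_radius)
  scene_truth(image_shape, pixel_size, nuclei, puncta)
}

place_separated <- function(n, shape, margin, min_sep, max_tries = 20000L) {
  pos <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pos) < n) {
    if ((tries <- tries + 1L) > max_tries)
      stop("could not place objects with the requested separation")
    cand <- c(stats::runif(1, margin, shape[1] - margin),
              stats::runif(1, margin, shape[2] - margin))
    if (!nrow(pos) ||
        min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) >= min_sep)
      pos <- rbind(pos, cand)
  }
  pos
}

#' Acquisition noise model for rendered fields
#'
#' @param gaussian_sd Additive Gaussian noise SD, intensity units.
#' @param background Constant background level, intensity units.
#' @param poisson_scale Photons per intensity unit for shot noise; 0
#'   disables the Poisson stage.
#' @return A `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 0, background = 0, poisson_scale = 0) {
  if (gaussian_sd < 0 || background < 0 || poisson_scale < 0)
    stop("noise parameters must be >= 0")
  structure(list(gaussian_sd = gaussian_sd, background = background,
                 poisson_scale = poisson_scale), class = "noise_model")
}

#' Render a three-channel peroxisome field from a scene truth
#'
#' Channels: `nuclei` (filled discs), `pts1` (import reporter), `pmp70`
#' (membrane marker). Each punctum is an isotropic Gaussian spot truncated
#' at 4 sigma; noise is applied per [noise_model()]. Intensities are
#' clamped at zero.
#'
#' @param scene A [scene_truth()].
#' @param noise A [noise_model()].
#' @param nucleus_amplitude Disc intensity for the nuclei channel.
#' @param seed Integer RNG seed (used only when noise is stochastic).
#' @return A `multichannel_image`: list with `channels` (named list of
#'   H x W matrices) and `pixel_size`.
#' @export
render_peroxisome_field <- function(scene, noise = noise_model(),
                                    nucleus_amplitude = 3000, seed = 1L) {
  stopifnot(inherits(scene, "scene_truth"), inherits(noise, "noise_model"))
  set.seed(seed)
  h <- scene$image_shape[1]; w <- scene$image_shape[2]
  blank <- matrix(0, h, w)
  ch <- list(nuclei = blank, pts1 = blank, pmp70 = blank)
  if (nrow(scene$nuclei)) {
    for (i in seq_len(nrow(scene$nuclei))) {
      ch$nuclei <- ch$nuclei + disc_mask(h, w, scene$nuclei$row[i],
                                         scene$nuclei$col[i],
                                         scene$nuclei$radius[i]) *
        nucleus_amplitude
    }
    ch$nuclei <- pmin(ch$nuclei, nucleus_amplitude)
  }
  if (nrow(scene$puncta)) {
    for (i in seq_len(nrow(scene$puncta))) {
      g <- gaussian_spot(h, w, scene$puncta$row[i], scene$puncta$col[i],
                         scene$puncta$sigma[i])
      ch$pts1 <- ch$pts1 + scene$puncta$amp_pts1[i] * g
      ch$pmp70 <- ch$pmp70 + scene$puncta$amp_pmp70[i] * g
    }
  }
  ch <- lapply(ch, function(m) {
    m <- m + noise$background
    if (noise$poisson_scale > 0)
      m <- matrix(stats::rpois(length(m), m * noise$poisson_scale),
                  h, w) / noise$poisson_scale
    if (noise$gaussian_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, noise$gaussian_sd), h, w)
    pmax(m, 0)
  })
  structure(list(channels = ch, pixel_size = scene$pixel_size),
            class = "multichannel_image")
}

gaussian_spot <- function(h, w, r0, c0, sigma) {
  lim <- ceiling(4 * sigma)
  rows <- max(1L, floor(r0 - lim)):min(h, ceiling(r0 + lim))
  cols <- max(1L, floor(c0 - lim)):min(w, ceiling(c0 + lim))
  dr2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
  patch <- exp(-dr2 / (2 * sigma^2))
  patch[dr2 > lim^2] <- 0  # truncate at 4 sigma
  m <- matrix(0, h, w)
  m[rows, cols] <- patch
  m
}

disc_mask <- function(h, w, r0, c0, radius) {
  rows <- max(1L, floor(r0 - radius)):min(h, ceiling(r0 + radius))
  cols <- max(1L, floor(c0 - radius)):min(w, ceiling(c0 + radius))
  d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
  m <- matrix(0, h, w)
  m[rows, cols] <- (d2 <= radius^2) * 1
  m
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat("multichannel_image:", paste(names(x$channels), collapse = "/"),
      "channels,", nrow(x$channels[[1]]), "x", ncol(x$channels[[1]]),
      "px @", x$pixel_size, "um/px\n")
  invisible(x)
}
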