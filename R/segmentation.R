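#' Min-max normalize an image to the unit intensity interval
#'
#' Affine rescaling of a non-negative intensity raster to \[0, 1\], the
#' normalization applied to every scan before segmentation and feature
#' extraction. A constant image has no dynamic range: it is mapped to all
#' zeros and flagged via a `"degenerate"` attribute plus a warning.
#'
#' @param raw Numeric matrix of raw intensities (at least one pixel).
#' @param modality Optional modality tag stored as an attribute (e.g. `"PET-AC"`).
#' @return A numeric matrix in \[0, 1\] with attributes `modality` and
#'   `degenerate` (logical). Pixel order of intensities is preserved.
#' @examples
#' normalize_image(matrix(c(2, 4, 6), 1))
#' @export
normalize_image <- function(raw, modality = "PET-AC") {
  if (!is.matrix(raw) || length(raw) < 1L || !is.numeric(raw)) {
    stop("`raw` must be a non-empty numeric matrix", call. = FALSE)
  }
  rng <- range(raw)
  degenerate <- rng[1] == rng[2]
  out <- if (degenerate) {
    warning("constant image: normalization is degenerate, returning zeros",
            call. = FALSE)
    matrix(0, nrow(raw), ncol(raw))
  } else {
    (raw - rng[1]) / (rng[2] - rng[1])
  }
  structure(out, modality = modality, degenerate = degenerate)
}

#' Segment a lesion by 2D region growing with a relative threshold
#'
#' Grows a 4-connected region from a seed pixel, accepting every pixel whose
#' intensity is at least `threshold_fraction` times the seed intensity. The
#' default 0.40 is the usual PET "40% of SUVmax" delineation convention; the
#' seed defaults to the global intensity maximum (first in row-major order on
#' ties), standing in for a clinician pointing at the main lesion.
#'
#' @param image Numeric matrix of intensities (typically normalized).
#' @param seed `"auto"` (default) or an integer vector `c(row, col)`, 1-based.
#' @param threshold_fraction Relative threshold in (0, 1\]; default 0.40.
#' @return Logical matrix of the same shape: the lesion mask. The mask always
#'   contains the seed and is 4-connected by construction.
#' @export
region_grow <- function(image, seed = "auto", threshold_fraction = 0.40) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1L ||
      threshold_fraction <= 0 || threshold_fraction > 1) {
    stop("`threshold_fraction` must be a single value in (0, 1]", call. = FALSE)
  }
  nr <- nrow(image); nc <- ncol(image)
  if (identical(seed, "auto")) {
    ## row-major first maximum: scan transposed so rows are traversed first
    ti <- which.max(t(image))
    seed <- c((ti - 1L) %/% nc + 1L, (ti - 1L) %% nc + 1L)
  }
  seed <- as.integer(seed)
  if (length(seed) != 2L || seed[1] < 1L || seed[1] > nr ||
      seed[2] < 1L || seed[2] > nc) {
    stop("seed pixel outside image bounds", call. = FALSE)
  }
  sval <- image[seed[1], seed[2]]
  if (sval <= 0) stop("seed intensity is zero: no lesion at seed", call. = FALSE)
  thr <- threshold_fraction * sval

  mask <- matrix(FALSE, nr, nc)
  admissible <- image >= thr
  ## iterative BFS over the 4-neighbourhood (no recursion: images can be large)
  queue <- integer(nr * nc)
  queue[1] <- (seed[2] - 1L) * nr + seed[1]
  head <- 1L; tail <- 1L
  mask[queue[1]] <- TRUE
  while (head <= tail) {
    idx <- queue[head]; head <- head + 1L
    r <- (idx - 1L) %% nr + 1L
    cl <- (idx - 1L) %/% nr + 1L
    if (r > 1L) { j <- idx - 1L
      if (admissible[j] && !mask[j]) { mask[j] <- TRUE; tail <- tail + 1L; queue[tail] <- j } }
    if (r < nr) { j <- idx + 1L
      if (admissible[j] && !mask[j]) { mask[j] <- TRUE; tail <- tail + 1L; queue[tail] <- j } }
    if (cl > 1L) { j <- idx - nr
      if (admissible[j] && !mask[j]) { mask[j] <- TRUE; tail <- tail + 1L; queue[tail] <- j } }
    if (cl < nc) { j <- idx + nr
      if (admissible[j] && !mask[j]) { mask[j] <- TRUE; tail <- tail + 1L; queue[tail] <- j } }
  }
  structure(mask, seed = seed, threshold_fraction = threshold_fraction)
}
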