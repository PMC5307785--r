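#' Names of the 171 descriptor entries, in frozen order
#'
#' Block order is histogram (4), GLCM (22), GLRL (11), wavelets (28),
#' Gabor (48), LBP (58); total 171.
#'
#' @param prefix Optional prefix (e.g. `"pre."`) prepended to every name.
#' @return Character vector of length 171.
#' @export
feature_names <- function(prefix = "") {
  nm <- c(
    names(histogram_features(matrix(c(0, 1), 2, 2), matrix(TRUE, 2, 2))),
    names(glcm_statistics(diag(2) / 2, 2L)),
    c("glrl.sre", "glrl.lre", "glrl.gln", "glrl.rln", "glrl.rp", "glrl.lgre",
      "glrl.hgre", "glrl.srlge", "glrl.srhge", "glrl.lrlge", "glrl.lrhge"),
    as.vector(t(outer(c("wav.LH1", "wav.HL1", "wav.HH1", "wav.LH2", "wav.HL2",
                        "wav.HH2", "wav.LL2"),
                      c("mean_abs", "sd", "energy", "entropy"), paste, sep = "."))),
    as.vector(t(outer(names(gabor_bank()),
                      c("mean", "sd", "energy", "entropy"),
                      function(a, b) sprintf("gabor.%s.%s", a, b)))),
    sprintf("lbp.u%d", uniform_lbp_codes())
  )
  paste0(prefix, nm)
}

#' Sizes of the descriptor family blocks
#' @return Named integer vector summing to 171.
#' @export
feature_block_sizes <- function() {
  c(histogram = 4L, glcm = 22L, glrl = 11L, wavelets = 28L,
    gabor = 48L, lbp = 58L)
}

#' Extract the full 171-entry descriptor vector of a segmented lesion
#'
#' Crops the lesion bounding box, re-quantizes it to `G` gray levels for the
#' matrix families, and concatenates the six family blocks in frozen order:
#' histogram (4), GLCM (22), GLRL (11), Daubechies-4 wavelets (28), Gabor
#' (48), uniform LBP (58). Because every family operates on the cropped
#' bounding box, the vector is invariant to where the lesion sits in the
#' scan.
#'
#' @param image Normalized scan image (numeric matrix).
#' @param mask Logical lesion mask of the same shape (non-empty).
#' @param G Gray levels for GLCM/GLRL quantization (default 16).
#' @return Named numeric vector of length 171; all entries finite.
#' @export
extract_all <- function(image, mask, G = 16L) {
  roi <- crop_roi(image, mask)
  q <- quantize_roi(roi$image, roi$mask, G)
  v <- c(histogram_features(roi$image, roi$mask),
         glcm_features(q),
         glrl_features(q),
         wavelet_features(roi$image),
         gabor_features(roi$image),
         lbp_features(roi$image, roi$mask))
  if (length(v) != 171L) {
    stop("internal error: descriptor vector has length ", length(v), call. = FALSE)
  }
  if (!all(is.finite(v))) {
    bad <- names(v)[!is.finite(v)]
    stop("non-finite descriptor value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  v
}
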