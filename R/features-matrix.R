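## Gray-level matrix descriptors: quantization, histogram moments, GLCM, GLRL.
## All families operate on the lesion bounding box so that descriptors are
## invariant to where the lesion sits inside the scan.

#' Crop an image and mask to the mask's bounding box
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same shape with at least one TRUE pixel.
#' @return List with `image` and `mask` cropped to the tight bounding box.
#' @export
crop_roi <- function(image, mask) {
  stopifnot(is.matrix(image), is.matrix(mask),
            all(dim(image) == dim(mask)))
  if (!any(mask)) stop("empty mask: no ROI to crop", call. = FALSE)
  rw <- range(which(rowSums(mask) > 0))
  cw <- range(which(colSums(mask) > 0))
  list(image = image[rw[1]:rw[2], cw[1]:cw[2], drop = FALSE],
       mask = mask[rw[1]:rw[2], cw[1]:cw[2], drop = FALSE])
}

#' Re-quantize ROI intensities to G gray levels
#'
#' Linear binning of the bounding-box pixels into levels `1..G`, using the
#' intensity range of the in-mask pixels. Matrix descriptors (GLCM, GLRL)
#' consume the quantized levels; out-of-mask pixels get level `NA` so they
#' never contribute to pair or run counts.
#'
#' @param image,mask Bounding-box image and lesion mask (see [crop_roi()]).
#' @param G Number of gray levels (default 16).
#' @return Object of class `quantized_roi`: list with `levels` (integer matrix
#'   with NA outside the mask), `mask`, and `G`.
#' @export
quantize_roi <- function(image, mask, G = 16L) {
  stopifnot(all(dim(image) == dim(mask)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  G <- as.integer(G)
  v <- image[mask]
  rng <- range(v)
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  if (rng[1] == rng[2]) {
    lev[mask] <- 1L
  } else {
    q <- 1L + as.integer(floor((image[mask] - rng[1]) / (rng[2] - rng[1]) * G))
    lev[mask] <- pmin(q, G)
  }
  structure(list(levels = lev, mask = mask, G = G), class = "quantized_roi")
}

#' First-order gray-level histogram moments
#'
#' Mean, population variance, skewness and kurtosis of the in-mask
#' intensities. Skewness is m3 / m2^(3/2) and kurtosis m4 / m2^2 (Pearson,
#' not excess); a zero-variance ROI returns 0 for both by convention so flat
#' lesions still produce finite vectors.
#'
#' @param image,mask ROI image and mask.
#' @return Named numeric vector of length 4.
#' @export
histogram_features <- function(image, mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  v <- image[mask]
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    sk <- 0; ku <- 0
  } else {
    sk <- mean((v - m)^3) / m2^1.5
    ku <- mean((v - m)^4) / m2^2
  }
  c(hist.mean = m, hist.variance = m2, hist.skewness = sk, hist.kurtosis = ku)
}

## the four standard 2D offsets (dr, dc) for 0, 45, 90, 135 degrees
glcm_offsets <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L), `135` = c(-1L, -1L))
}

## raw symmetric co-occurrence counts for one offset; NULL if no valid pair
glcm_matrix_one <- function(lev, G, off) {
  nr <- nrow(lev); nc <- ncol(lev)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  P <- matrix(0, G, G)
  tb <- table(factor(a[ok], levels = 1:G), factor(b[ok], levels = 1:G))
  P <- P + tb + t(tb)          # symmetrize
  P / sum(P)
}

#' Gray-level co-occurrence matrix features
#'
#' Builds one symmetric, normalized GLCM per direction (0, 45, 90, 135
#' degrees at the given pixel distance), averages the available directional
#' matrices and evaluates a frozen list of 22 statistics on the average:
#' the 13 Haralick statistics (angular second moment, contrast, correlation,
#' sum of squares variance, inverse difference moment, sum average, sum
#' variance, sum entropy, entropy, difference variance, difference entropy,
#' and the two information measures of correlation) plus autocorrelation,
#' cluster shade, cluster prominence, dissimilarity, homogeneity
#' (sum of p/(1+|i-j|)), maximum probability, inverse difference
#' (off-diagonal sum of p/|i-j|), inverse difference normalized and inverse
#' difference moment normalized. Natural logarithms throughout; degenerate
#' denominators (zero marginal variance or entropy) yield 0 by convention.
#'
#' @param roi A [quantize_roi()] result.
#' @param distance Pixel offset distance (default 1).
#' @param directions Subset of `c(0, 45, 90, 135)`.
#' @return Named numeric vector of length 22 (prefix `glcm.`).
#' @export
glcm_features <- function(roi, distance = 1L, directions = c(0, 45, 90, 135)) {
  stopifnot(inherits(roi, "quantized_roi"))
  G <- roi$G
  offs <- glcm_offsets()[as.character(directions)]
  mats <- list()
  for (nm in names(offs)) {
    M <- glcm_matrix_one(roi$levels, G, offs[[nm]] * as.integer(distance))
    if (is.null(M)) {
      warning("no valid pixel pair for GLCM direction ", nm, call. = FALSE)
    } else {
      mats[[nm]] <- M
    }
  }
  if (length(mats) == 0L) stop("no valid pixel pair in any GLCM direction", call. = FALSE)
  P <- Reduce(`+`, mats) / length(mats)
  glcm_statistics(P, G)
}

## the frozen 22-statistic list, evaluated on an averaged normalized GLCM
glcm_statistics <- function(P, G) {
  i <- matrix(1:G, G, G)
  j <- t(i)
  px <- rowSums(P)                      # symmetric: px == py
  mu <- sum((1:G) * px)
  s2 <- sum(((1:G) - mu)^2 * px)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

  ## diagonal-band marginals
  psum <- vapply(2:(2 * G), function(k) sum(P[i + j == k]), 0)   # p_{x+y}
  pdif <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), 0) # p_{|x-y|}

  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (s2 > 0) (sum(i * j * P) - mu^2) / s2 else 0
  ssvar <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum((2:(2 * G)) * psum)
  sum_var <- sum(((2:(2 * G)) - sum_avg)^2 * psum)
  sum_ent <- -sum(xlogx(psum))
  ent <- -sum(xlogx(P))
  dmean <- sum((0:(G - 1)) * pdif)
  diff_var <- sum(((0:(G - 1)) - dmean)^2 * pdif)
  diff_ent <- -sum(xlogx(pdif))
  hx <- -sum(xlogx(px))
  pxpy <- outer(px, px)
  hxy1 <- -sum(P * ifelse(pxpy > 0, log(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  autocorr <- sum(i * j * P)
  csh <- sum((i + j - 2 * mu)^3 * P)
  cpr <- sum((i + j - 2 * mu)^4 * P)
  dissim <- sum(abs(i - j) * P)
  homog <- sum(P / (1 + abs(i - j)))
  maxp <- max(P)
  invdiff <- sum(P[i != j] / abs(i - j)[i != j])
  idn <- sum(P / (1 + abs(i - j) / G))
  idmn <- sum(P / (1 + (i - j)^2 / G^2))

  c(glcm.asm = asm, glcm.contrast = contrast, glcm.correlation = correlation,
    glcm.sum_of_squares_variance = ssvar, glcm.idm = idm,
    glcm.sum_average = sum_avg, glcm.sum_variance = sum_var,
    glcm.sum_entropy = sum_ent, glcm.entropy = ent,
    glcm.difference_variance = diff_var, glcm.difference_entropy = diff_ent,
    glcm.imc1 = imc1, glcm.imc2 = imc2, glcm.autocorrelation = autocorr,
    glcm.cluster_shade = csh, glcm.cluster_prominence = cpr,
    glcm.dissimilarity = dissim, glcm.homogeneity = homog,
    glcm.max_probability = maxp, glcm.inverse_difference = invdiff,
    glcm.idn = idn, glcm.idmn = idmn)
}

## enumerate maximal runs of equal level along one direction; runs are broken
## by out-of-mask (NA) pixels. Returns a G x Lmax count matrix.
glrl_matrix_one <- function(lev, G, direction, Lmax) {
  nr <- nrow(lev); nc <- ncol(lev)
  lines <- switch(as.character(direction),
    `0`   = lapply(seq_len(nr), function(r) lev[r, ]),
    `90`  = lapply(seq_len(nc), function(cl) lev[, cl]),
    `45`  = lapply(seq.int(2L, nr + nc), function(s) {
              ## anti-diagonals r + c = s, traversed bottom-left to top-right
              idx <- which(row(lev) + col(lev) == s)
              lev[idx[order(-row(lev)[idx])]]
            }),
    `135` = lapply(seq.int(-(nr - 1L), nc - 1L), function(d) {
              ## main diagonals c - r = d, traversed top-left to bottom-right
              idx <- which(col(lev) - row(lev) == d)
              lev[idx[order(row(lev)[idx])]]
            }),
    stop("unknown GLRL direction", call. = FALSE))
  R <- matrix(0, G, Lmax)
  for (ln in lines) {
    if (length(ln) == 0L) next
    r <- rle(as.vector(ln))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    for (k in which(keep)) {
      R[r$values[k], min(r$lengths[k], Lmax)] <-
        R[r$values[k], min(r$lengths[k], Lmax)] + 1
    }
  }
  R
}

#' Gray-level run-length features
#'
#' Run-length matrices are accumulated per direction (runs broken at
#' out-of-mask pixels), averaged over the requested directions, and the 11
#' classical statistics are evaluated on the average: SRE, LRE, GLN, RLN, RP,
#' LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE. Run percentage divides the number
#' of runs by the in-mask pixel count.
#'
#' @param roi A [quantize_roi()] result.
#' @param directions Subset of `c(0, 45, 90, 135)`.
#' @return Named numeric vector of length 11 (prefix `glrl.`).
#' @export
glrl_features <- function(roi, directions = c(0, 45, 90, 135)) {
  stopifnot(inherits(roi, "quantized_roi"))
  G <- roi$G
  Lmax <- max(dim(roi$levels))
  mats <- lapply(directions, function(d) glrl_matrix_one(roi$levels, G, d, Lmax))
  R <- Reduce(`+`, mats) / length(mats)
  Nr <- sum(R)
  if (Nr == 0) stop("no runs in ROI", call. = FALSE)
  Np <- sum(roi$mask)
  g <- matrix(1:G, G, Lmax)
  l <- matrix(1:Lmax, G, Lmax, byrow = TRUE)
  c(glrl.sre = sum(R / l^2) / Nr,
    glrl.lre = sum(R * l^2) / Nr,
    glrl.gln = sum(rowSums(R)^2) / Nr,
    glrl.rln = sum(colSums(R)^2) / Nr,
    glrl.rp = Nr / Np,
    glrl.lgre = sum(R / g^2) / Nr,
    glrl.hgre = sum(R * g^2) / Nr,
    glrl.srlge = sum(R / (g^2 * l^2)) / Nr,
    glrl.srhge = sum(R * g^2 / l^2) / Nr,
    glrl.lrlge = sum(R * l^2 / g^2) / Nr,
    glrl.lrhge = sum(R * g^2 * l^2) / Nr)
}
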