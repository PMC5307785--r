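## Filter-bank descriptors: Daubechies-4 wavelet subbands, Gabor filter
## responses and uniform local binary patterns. All operate on the lesion
## bounding-box image.

## Daubechies-4 (4-tap) analysis filters.
db4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))  # scaling (low-pass)
  g <- rev(h) * c(1, -1, 1, -1)                           # wavelet (high-pass)
  list(lo = h, hi = g)
}

## half-point symmetric extension indices for a signal of length n padded by p
sym_ext_idx <- function(n, p) {
  base <- c(seq_len(n), seq.int(n, 1L))    # period-2n reflection
  idx <- ((seq.int(-p, n + p - 1L)) %% (2L * n)) + 1L
  base[idx]
}

## one-level 1D analysis: filter with symmetric extension, keep even phases.
## Output length floor((n + L - 1) / 2), matching the usual symmetric DWT.
dwt_step_1d <- function(x, f) {
  n <- length(x); L <- length(f)
  xp <- x[sym_ext_idx(n, L - 1L)]
  full <- stats::filter(xp, rev(f), sides = 1)   # full convolution values
  conv <- full[L:length(xp)]                     # length n + 2(L-1) - (L-1)
  conv[seq.int(2L, n + L - 1L, by = 2L)]
}

## one-level 2D analysis returning LL, LH, HL, HH (rows then columns)
dwt2_step <- function(m, filt) {
  lo_r <- apply(m, 1, dwt_step_1d, f = filt$lo)   # columns of result: rows filtered
  hi_r <- apply(m, 1, dwt_step_1d, f = filt$hi)
  ## lo_r is (ncol') x nrow: filter its columns again along original columns
  LL <- apply(lo_r, 1, dwt_step_1d, f = filt$lo)
  LH <- apply(lo_r, 1, dwt_step_1d, f = filt$hi)
  HL <- apply(hi_r, 1, dwt_step_1d, f = filt$lo)
  HH <- apply(hi_r, 1, dwt_step_1d, f = filt$hi)
  ## apply() twice leaves rows indexing the vertical (original row) axis
  as_mat <- function(z) if (is.matrix(z)) z else matrix(z, nrow = 1L)
  list(LL = as_mat(LL), LH = as_mat(LH), HL = as_mat(HL), HH = as_mat(HH))
}

## the four subband statistics shared by wavelet and Gabor families.
## `ref` is the input-image scale: coefficients below 1e-12 * ref are
## numerical dust (FFT/filter roundoff) and are treated as exact zeros so
## that entropy does not pick up noise on analytically-null subbands.
subband_stats <- function(coef, ref = 1) {
  coef <- as.vector(coef)
  coef[abs(coef) < 1e-12 * ref] <- 0
  energy <- sum(coef^2)
  if (energy == 0) {
    c(mean_abs = 0, sd = 0, energy = 0, entropy = 0)
  } else {
    p <- coef^2 / energy
    c(mean_abs = mean(abs(coef)),
      sd = stats::sd(coef),
      energy = energy,
      entropy = -sum(ifelse(p > 0, p * log(p), 0)))
  }
}

#' Daubechies-4 wavelet subband features
#'
#' A 2-level 2D discrete wavelet transform (Daubechies 4-tap filters,
#' half-point symmetric border extension) decomposes the ROI into seven
#' subbands (LH1, HL1, HH1, LH2, HL2, HH2, LL2). For each subband four
#' statistics are reported: mean absolute coefficient, standard deviation,
#' energy (sum of squares), and the entropy of the normalized squared
#' coefficients — 28 values.
#'
#' @param image Bounding-box image (numeric matrix, at least 4x4).
#' @param levels Decomposition depth (fixed default 2).
#' @return Named numeric vector of length 28 (prefix `wav.`).
#' @export
wavelet_features <- function(image, levels = 2L) {
  if (nrow(image) < 4L || ncol(image) < 4L) {
    stop("ROI too small for the wavelet transform: minimum size is 4x4",
         call. = FALSE)
  }
  filt <- db4_filters()
  ref <- max(abs(image), 1e-300)
  out <- numeric(0)
  cur <- image
  for (lev in seq_len(levels)) {
    sb <- dwt2_step(cur, filt)
    for (b in c("LH", "HL", "HH")) {
      s <- subband_stats(sb[[b]], ref)
      names(s) <- sprintf("wav.%s%d.%s", b, lev, names(s))
      out <- c(out, s)
    }
    cur <- sb$LL
  }
  s <- subband_stats(cur, ref)
  names(s) <- sprintf("wav.LL%d.%s", levels, names(s))
  c(out, s)
}

## 2D convolution with edge-replicate padding via FFT, "same"-size response.
## Replicate padding keeps DC-free kernels exactly null on constant images,
## border pixels included.
conv2_same <- function(img, ker) {
  ni <- dim(img); nk <- dim(ker)
  ridx <- c(rep(1L, nk[1] - 1L), seq_len(ni[1]), rep(ni[1], nk[1] - 1L))
  cidx <- c(rep(1L, nk[2] - 1L), seq_len(ni[2]), rep(ni[2], nk[2] - 1L))
  padded <- img[ridx, cidx, drop = FALSE]
  np <- dim(padded)
  nf <- np + nk - 1L
  pad0 <- function(m, d) { out <- matrix(0, d[1], d[2]); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out }
  F <- stats::fft(pad0(padded, nf)) * stats::fft(pad0(ker, nf))
  full <- stats::fft(F, inverse = TRUE) / prod(nf)
  r0 <- (nk[1] - 1L) %/% 2L
  c0 <- (nk[2] - 1L) %/% 2L
  full[(nk[1] - 1L) + r0 + seq_len(ni[1]),
       (nk[2] - 1L) + c0 + seq_len(ni[2]), drop = FALSE]
}

#' Construct the Gabor filter bank
#'
#' Twelve complex Gabor kernels: 3 dyadic scales (wavelengths 4, 8, 16 px,
#' envelope sigma = 0.56 wavelength) times 4 orientations (0, 45, 90, 135
#' degrees). Kernels are made exactly zero-mean (DC-free) so a constant image
#' produces a zero response.
#'
#' @param wavelengths Center wavelengths in pixels.
#' @param orientations Orientations in degrees.
#' @return List of complex kernel matrices named `s<scale>.o<angle>`.
#' @export
gabor_bank <- function(wavelengths = c(4, 8, 16),
                       orientations = c(0, 45, 90, 135)) {
  bank <- list()
  for (si in seq_along(wavelengths)) {
    lambda <- wavelengths[si]
    sigma <- 0.56 * lambda
    h <- ceiling(2.5 * sigma)
    xs <- -h:h
    X <- matrix(xs, 2 * h + 1, 2 * h + 1, byrow = TRUE)
    Y <- matrix(xs, 2 * h + 1, 2 * h + 1)
    for (th in orientations) {
      t <- th * pi / 180
      xr <- X * cos(t) + Y * sin(t)
      yr <- -X * sin(t) + Y * cos(t)
      env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
      ker <- env * exp(1i * 2 * pi * xr / lambda)
      ker <- ker - mean(ker)                      # remove DC exactly
      bank[[sprintf("s%d.o%d", si, th)]] <- ker
    }
  }
  bank
}

#' Gabor filter-bank features
#'
#' Convolves the ROI with the 12-kernel bank of [gabor_bank()] (linear
#' convolution, edge-replicate padding, same-size output) and reports, per
#' filter, the
#' mean, standard deviation, energy and normalized-squared-magnitude entropy
#' of the response magnitude — 48 values.
#'
#' @param image Bounding-box image.
#' @param bank Filter bank; defaults to [gabor_bank()].
#' @return Named numeric vector of length 48 (prefix `gabor.`).
#' @export
gabor_features <- function(image, bank = gabor_bank()) {
  if (length(image) < 4L) stop("degenerate ROI for Gabor filtering", call. = FALSE)
  out <- numeric(0)
  ref <- max(abs(image), 1e-300)
  for (nm in names(bank)) {
    resp <- Mod(conv2_same(image, bank[[nm]]))
    resp[resp < 1e-12 * ref] <- 0         # FFT roundoff on null responses
    energy <- sum(resp^2)
    if (energy == 0) {
      s <- c(mean = 0, sd = 0, energy = 0, entropy = 0)
    } else {
      p <- resp^2 / energy
      s <- c(mean = mean(resp), sd = stats::sd(resp), energy = energy,
             entropy = -sum(ifelse(p > 0, p * log(p), 0)))
    }
    names(s) <- sprintf("gabor.%s.%s", nm, names(s))
    out <- c(out, s)
  }
  out
}

## the 58 uniform 8-bit LBP codes (at most two 0/1 transitions, circular)
uniform_lbp_codes <- function() {
  codes <- 0:255
  trans <- vapply(codes, function(cd) {
    bits <- as.integer(intToBits(cd))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }, 0L)
  codes[trans <= 2L]
}

#' Uniform local binary pattern histogram
#'
#' Classic 8-neighbor LBP on the 3x3 neighborhood (neighbors in order E, NE,
#' N, NW, W, SW, S, SE; bit k has weight 2^k; neighbor >= center sets the
#' bit). One block spans the whole ROI. Only in-mask center pixels whose full
#' neighborhood lies inside the ROI contribute. The histogram is taken over
#' the 58 uniform codes (non-uniform patterns discarded) and normalized to
#' sum to 1 over the counted pixels, or left all-zero if no uniform pattern
#' occurs.
#'
#' @param image Bounding-box image, at least 3x3.
#' @param mask Logical matrix restricting which center pixels count;
#'   defaults to all.
#' @return Named numeric vector of length 58 (prefix `lbp.u<code>`).
#' @export
lbp_features <- function(image, mask = NULL) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) stop("ROI smaller than 3x3: LBP undefined", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  ## neighbor offsets (dr, dc) in bit order E, NE, N, NW, W, SW, S, SE
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  ctr <- image[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  code <- matrix(0L, nr - 2L, nc - 2L)
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    nb <- image[2:(nr - 1) + o[1], 2:(nc - 1) + o[2], drop = FALSE]
    code <- code + as.integer(nb >= ctr) * 2L^(k - 1L)
  }
  counted <- mask[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  u <- uniform_lbp_codes()
  tab <- table(factor(code[counted], levels = u))
  h <- as.numeric(tab)
  nuni <- sum(h)
  if (nuni > 0) h <- h / nuni
  names(h) <- sprintf("lbp.u%d", u)
  h
}
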