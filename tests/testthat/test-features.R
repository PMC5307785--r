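roi_fix <- random_roi(12L, seed = 7)

test_that("descriptor vector has the frozen length, blocks and names", {
  q <- quantize_roi(roi_fix$image, roi_fix$mask)
  v <- extract_all(roi_fix$image, roi_fix$mask)
  expect_length(v, 171L)
  expect_identical(names(v), feature_names())
  expect_true(all(is.finite(v)))
  fam <- c(histogram = 4L, glcm = 22L, glrl = 11L, wavelets = 28L,
           gabor = 48L, lbp = 58L)
  expect_identical(feature_block_sizes(), fam)
  expect_identical(sum(fam), 171L)
  counts <- table(sub("[.].*", "", names(v)))
  expect_equal(unname(counts[c("hist", "glcm", "glrl", "wav", "gabor", "lbp")]),
               unname(fam), ignore_attr = TRUE)
  ## determinism
  expect_identical(v, extract_all(roi_fix$image, roi_fix$mask))
})

test_that("histogram moments match direct sums and degenerate conventions", {
  img <- matrix(c(0.2, 0.4, 0.4, 1.0), 2)
  m <- matrix(TRUE, 2, 2)
  expect_equal(unname(histogram_features(img, m)),
               oracle_moments(c(0.2, 0.4, 0.4, 1.0)), tolerance = 1e-12)
  ## Bernoulli(1/2)
  img2 <- matrix(c(0, 1, 0, 1), 2)
  h <- histogram_features(img2, m)
  expect_equal(unname(h[1:2]), c(0.5, 0.25))
  ## constant ROI
  expect_equal(unname(histogram_features(matrix(0.7, 3, 3), matrix(TRUE, 3, 3))),
               c(0.7, 0, 0, 0))
  expect_error(histogram_features(img, matrix(FALSE, 2, 2)), "empty")
})

test_that("GLCM on a constant ROI is a single cell", {
  q <- quantize_roi(matrix(0.5, 5, 5), matrix(TRUE, 5, 5))
  g <- glcm_features(q)
  expect_equal(unname(g["glcm.asm"]), 1)
  expect_equal(unname(g["glcm.entropy"]), 0)
  expect_equal(unname(g["glcm.contrast"]), 0)
  expect_equal(unname(g["glcm.max_probability"]), 1)
})

test_that("GLCM checkerboard contrast matches explicit pair counting", {
  cb <- matrix(rep(c(0, 1), 8), 4, 4)
  q <- quantize_roi(cb, matrix(TRUE, 4, 4), G = 2L)
  P <- oracle_glcm_avg(q$levels, 2L)
  i <- matrix(1:2, 2, 2); j <- t(i)
  expect_equal(unname(glcm_features(q)["glcm.contrast"]),
               sum((i - j)^2 * P), tolerance = 1e-12)
})

test_that("averaged GLCM is symmetric, normalized, and oracle-identical", {
  for (s in 1:5) {
    roi <- random_roi(10L, seed = s)
    q <- quantize_roi(roi$image, roi$mask, G = 8L)
    P <- oracle_glcm_avg(q$levels, 8L)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
    expect_equal(glcm_features(q),
                 petresponse:::glcm_statistics(P, 8L), tolerance = 1e-9)
  }
})

test_that("GLRL single-run cases follow the definitions", {
  ## single row, one value, direction 0: one run of length 4, RP = 1/4
  q <- quantize_roi(matrix(0.5, 1, 4), matrix(TRUE, 1, 4), G = 4L)
  g0 <- glrl_features(q, directions = 0)
  expect_equal(unname(g0["glrl.rp"]), 1 / 4)
  expect_equal(unname(g0["glrl.lre"]), 16)
  ## 1x4 ROI {1,1,2,2}: two runs of length 2
  img <- matrix(c(0.1, 0.1, 0.9, 0.9), 1)
  q2 <- quantize_roi(img, matrix(TRUE, 1, 4), G = 2L)
  g <- glrl_features(q2, directions = 0)
  expect_equal(unname(g["glrl.sre"]), (1 / 4 + 1 / 4) / 2)   # both runs length 2
  expect_equal(unname(g["glrl.lre"]), 4)
  expect_equal(unname(g["glrl.rp"]), 2 / 4)
})

test_that("GLRL averaged matrix equals the run-enumeration oracle", {
  for (s in 1:5) {
    roi <- random_roi(9L, seed = 100 + s)
    q <- quantize_roi(roi$image, roi$mask, G = 6L)
    Lmax <- max(dim(q$levels))
    R <- oracle_glrl_avg(q$levels, 6L, Lmax)
    got <- glrl_features(q)
    Nr <- sum(R); Np <- sum(q$mask)
    l <- matrix(1:Lmax, 6L, Lmax, byrow = TRUE)
    expect_equal(unname(got["glrl.sre"]), sum(R / l^2) / Nr, tolerance = 1e-9)
    expect_equal(unname(got["glrl.rp"]), Nr / Np, tolerance = 1e-12)
    gmat <- matrix(1:6, 6L, Lmax)
    expect_equal(unname(got["glrl.lrhge"]), sum(R * gmat^2 * l^2) / Nr,
                 tolerance = 1e-9)
  }
})

test_that("wavelet details vanish on constants; subbands match the filter-bank oracle", {
  w <- wavelet_features(matrix(0.3, 8, 8))
  detail <- w[!grepl("LL2", names(w))]
  ## high-pass filter sums are zero only to machine precision
  expect_lt(max(abs(detail[grepl("mean_abs|energy", names(detail))])), 1e-12)
  ## ramp image against the independent implementation
  img <- outer(1:16, 1:16, function(a, b) a / 16 + b / 32)
  sb <- oracle_dwt2_subbands(img)
  got <- wavelet_features(img)
  for (b in names(sb)) {
    expect_equal(unname(got[sprintf("wav.%s.energy", b)]),
                 sum(sb[[b]]^2), tolerance = 1e-9, label = b)
  }
  expect_error(wavelet_features(matrix(1, 3, 3)), "4x4")
})

test_that("Gabor bank has 12 DC-free filters and zero response to constants", {
  bank <- gabor_bank()
  expect_length(bank, 12L)
  for (k in bank) expect_equal(abs(sum(k)), 0, tolerance = 1e-12)
  g <- gabor_features(matrix(0.42, 10, 10))
  expect_equal(unname(g), rep(0, 48), tolerance = 1e-12)
})

test_that("Gabor responses match direct spatial convolution", {
  roi <- random_roi(8L, seed = 3)
  bank <- gabor_bank()
  got <- gabor_features(roi$image)
  for (nm in names(bank)[c(1, 6, 12)]) {      # one filter per scale
    resp <- Mod(oracle_conv2_same(roi$image, bank[[nm]]))
    expect_equal(unname(got[sprintf("gabor.%s.energy", nm)]),
                 sum(resp^2), tolerance = 1e-9, label = nm)
    expect_equal(unname(got[sprintf("gabor.%s.mean", nm)]),
                 mean(resp), tolerance = 1e-9, label = nm)
  }
})

test_that("LBP histogram matches per-pixel enumeration and sums to one", {
  withr::with_seed(55, {
    img <- matrix(runif(64), 8, 8)
    mask <- matrix(TRUE, 8, 8)
    h <- lbp_features(img, mask)
    expect_length(h, 58L)
    expect_equal(sum(h), 1)
    expect_true(all(h >= 0 & h <= 1))
    expect_equal(unname(h), oracle_lbp_hist(img, mask), tolerance = 1e-12)
  })
  ## constant image: every neighbor ties the center, all-ones pattern (255)
  hc <- lbp_features(matrix(1, 5, 5))
  expect_equal(unname(hc["lbp.u255"]), 1)
  expect_equal(sum(hc), 1)
  expect_error(lbp_features(matrix(1, 2, 2)), "3x3")
})

test_that("descriptors are invariant to lesion translation", {
  withr::with_seed(12, {
    patch <- matrix(runif(100, 0.3, 1), 10, 10)
    big1 <- matrix(0.05, 30, 30); big2 <- matrix(0.05, 30, 30)
    big1[3:12, 4:13] <- patch
    big2[15:24, 18:27] <- patch
    m1 <- matrix(FALSE, 30, 30); m1[3:12, 4:13] <- TRUE
    m2 <- matrix(FALSE, 30, 30); m2[15:24, 18:27] <- TRUE
    expect_equal(extract_all(big1, m1), extract_all(big2, m2))
  })
})

test_that("matrix families ignore pixels outside the mask", {
  roi <- random_roi(10L, seed = 31, mask_frac = 0.6)
  q1 <- quantize_roi(roi$image, roi$mask)
  altered <- roi$image
  altered[!roi$mask] <- runif(sum(!roi$mask))
  q2 <- quantize_roi(altered, roi$mask)
  expect_equal(glcm_features(q1), glcm_features(q2))
  expect_equal(glrl_features(q1), glrl_features(q2))
  expect_equal(histogram_features(roi$image, roi$mask),
               histogram_features(altered, roi$mask))
})
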