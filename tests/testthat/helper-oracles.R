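## Independent brute-force oracles. Each deliberately takes a different
## computational route from the package implementation (explicit loops,
## fixpoint iteration, direct definitions) so agreement is evidence, not
## tautology.

## flood fill by fixpoint iteration: repeatedly add any admissible pixel that
## touches the region through a 4-neighbor, until nothing changes
oracle_region_grow <- function(image, seed, threshold_fraction) {
  nr <- nrow(image); nc <- ncol(image)
  thr <- threshold_fraction * image[seed[1], seed[2]]
  ok <- image >= thr
  reg <- matrix(FALSE, nr, nc)
  reg[seed[1], seed[2]] <- TRUE
  repeat {
    grown <- reg
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      if (!reg[r, cl] && ok[r, cl]) {
        if ((r > 1 && reg[r - 1, cl]) || (r < nr && reg[r + 1, cl]) ||
            (cl > 1 && reg[r, cl - 1]) || (cl < nc && reg[r, cl + 1])) {
          grown[r, cl] <- TRUE
        }
      }
    }
    if (identical(grown, reg)) break
    reg <- grown
  }
  reg
}

## direct four-moment computation from definition sums
oracle_moments <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  if (m2 == 0) return(c(m, 0, 0, 0))
  c(m, m2, sum((v - m)^3) / n / m2^1.5, sum((v - m)^4) / n / m2^2)
}

## co-occurrence by explicit pair enumeration over every pixel
oracle_glcm_avg <- function(lev, G, distance = 1L) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  nr <- nrow(lev); nc <- ncol(lev)
  mats <- list()
  for (off in offs) {
    off <- off * distance
    P <- matrix(0, G, G)
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- cl + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          !is.na(lev[r, cl]) && !is.na(lev[r2, c2])) {
        P[lev[r, cl], lev[r2, c2]] <- P[lev[r, cl], lev[r2, c2]] + 1
        P[lev[r2, c2], lev[r, cl]] <- P[lev[r2, c2], lev[r, cl]] + 1
      }
    }
    if (sum(P) > 0) mats[[length(mats) + 1L]] <- P / sum(P)
  }
  Reduce(`+`, mats) / length(mats)
}

## run enumeration with a manual scanner along each line
oracle_glrl_avg <- function(lev, G, Lmax) {
  nr <- nrow(lev); nc <- ncol(lev)
  line_sets <- list(
    lapply(seq_len(nr), function(r) cbind(r, seq_len(nc))),              # 0
    lapply(seq.int(2L, nr + nc), function(s) {                           # 45
      r <- seq_len(nr); cl <- s - r
      keep <- cl >= 1 & cl <= nc
      cbind(rev(r[keep]), rev(cl[keep]))
    }),
    lapply(seq_len(nc), function(cl) cbind(seq_len(nr), cl)),            # 90
    lapply(seq.int(-(nr - 1L), nc - 1L), function(d) {                   # 135
      r <- seq_len(nr); cl <- r + d
      keep <- cl >= 1 & cl <= nc
      cbind(r[keep], cl[keep])
    }))
  mats <- lapply(line_sets, function(lines) {
    R <- matrix(0, G, Lmax)
    for (pts in lines) {
      run_val <- NA; run_len <- 0L
      for (k in seq_len(nrow(pts))) {
        v <- lev[pts[k, 1], pts[k, 2]]
        if (!is.na(v) && !is.na(run_val) && v == run_val) {
          run_len <- run_len + 1L
        } else {
          if (!is.na(run_val)) R[run_val, run_len] <- R[run_val, run_len] + 1
          run_val <- v; run_len <- 1L
        }
      }
      if (!is.na(run_val)) R[run_val, run_len] <- R[run_val, run_len] + 1
    }
    R
  })
  Reduce(`+`, mats) / length(mats)
}

## per-pixel LBP code computation with an explicit neighbor walk
oracle_lbp_hist <- function(image, mask) {
  nr <- nrow(image); nc <- ncol(image)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  uniform <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)]) <= 2
  }
  u <- Filter(uniform, 0:255)
  h <- stats::setNames(numeric(length(u)), as.character(u))
  for (r in 2:(nr - 1)) for (cl in 2:(nc - 1)) {
    if (!mask[r, cl]) next
    code <- 0L
    for (k in 1:8) {
      nb <- image[r + offs[[k]][1], cl + offs[[k]][2]]
      if (nb >= image[r, cl]) code <- code + 2L^(k - 1L)
    }
    if (uniform(code)) h[as.character(code)] <- h[as.character(code)] + 1
  }
  if (sum(h) > 0) h <- h / sum(h)
  unname(h)
}

oracle_dwt2_subbands <- function(img, levels = 2L) {
  filt <- list(lo = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)))
  filt$hi <- rev(filt$lo) * c(1, -1, 1, -1)
  step1d <- function(x, f) {
    n <- length(x); L <- length(f)
    p <- L - 1L
    period <- c(seq_len(n), seq.int(n, 1L))
    xp <- period[((seq.int(-p, n + p - 1L)) %% (2L * n)) + 1L]
    xp <- x[xp]
    ## the package convention: sliding inner products (correlation) with the
    ## analysis filter on the symmetrically extended signal, even phases kept
    full <- numeric(length(xp) - L + 1L)
    for (k in seq_along(full)) full[k] <- sum(f * xp[k + seq_len(L) - 1L])
    full[seq.int(2L, n + L - 1L, by = 2L)]
  }
  step2d <- function(m, fr, fc) {
    rows <- t(sapply(seq_len(nrow(m)), function(r) step1d(m[r, ], fr)))
    if (nrow(m) == 1L) rows <- matrix(rows, nrow = 1L)
    out <- sapply(seq_len(ncol(rows)), function(cl) step1d(rows[, cl], fc))
    matrix(out, ncol = ncol(rows))
  }
  res <- list()
  cur <- img
  for (lv in seq_len(levels)) {
    res[[sprintf("LH%d", lv)]] <- step2d(cur, filt$lo, filt$hi)
    res[[sprintf("HL%d", lv)]] <- step2d(cur, filt$hi, filt$lo)
    res[[sprintf("HH%d", lv)]] <- step2d(cur, filt$hi, filt$hi)
    cur <- step2d(cur, filt$lo, filt$lo)
  }
  res[[sprintf("LL%d", levels)]] <- cur
  res
}

## direct spatial convolution for the Gabor bank ("same" output, replicate
## padding = index clamping):
## out[r,c] = sum_{i,j} ker[i,j] * img[clamp(r + r0 - i + 1), clamp(c + c0 - j + 1)]
oracle_conv2_same <- function(img, ker) {
  ni <- dim(img); nk <- dim(ker)
  r0 <- (nk[1] - 1L) %/% 2L; c0 <- (nk[2] - 1L) %/% 2L
  clampr <- function(i) pmin(pmax(i, 1L), ni[1])
  clampc <- function(j) pmin(pmax(j, 1L), ni[2])
  out <- matrix(0+0i, ni[1], ni[2])
  for (r in seq_len(ni[1])) for (cl in seq_len(ni[2])) {
    acc <- 0+0i
    for (i in seq_len(nk[1])) {
      ri <- clampr(r + r0 - i + 1L)
      cj <- clampc(cl + c0 - seq_len(nk[2]) + 1L)
      acc <- acc + sum(ker[i, ] * img[ri, cj])
    }
    out[r, cl] <- acc
  }
  out
}

## Friedman chi-square via the rank-sum (not mean-rank) formula
oracle_friedman_T1 <- function(rank_table) {
  N <- nrow(rank_table); k <- ncol(rank_table)
  Rj <- colSums(rank_table)
  chisq <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  (N - 1) * chisq / (N * (k - 1) - chisq)
}

## shared fixture: a small random masked ROI
random_roi <- function(n = 12L, seed = 1L, mask_frac = 0.8) {
  withr::with_seed(seed, {
    img <- matrix(stats::runif(n * n), n, n)
    mask <- matrix(stats::runif(n * n) < mask_frac, n, n)
    mask[ceiling(n / 2), ceiling(n / 2)] <- TRUE   # never empty
    list(image = img, mask = mask)
  })
}

## default-world datasets are expensive (126 feature extractions); memoize
## them so the acceptance criteria can share cohorts
.dataset_cache <- new.env(parent = emptyenv())
cached_default_dataset <- function(seed) {
  key <- as.character(seed)
  if (is.null(.dataset_cache[[key]])) {
    .dataset_cache[[key]] <-
      build_dataset(generate_cohort(cohort_config(rng_seed = seed)))
  }
  .dataset_cache[[key]]
}
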