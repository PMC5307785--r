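#' SMOTE class rebalancing
#'
#' Synthetic minority over-sampling: for each of the `n_classes` rarest
#' classes (ties broken by the fixed class enumeration order), `n_per_class`
#' synthetic samples are generated. Each synthetic sample lies on the segment
#' between a randomly chosen minority sample and one of its `k` nearest
#' minority-class neighbors (Euclidean distance), with interpolation factor
#' uniform in \[0, 1\]; labels are inherited. The defaults reproduce the
#' study protocol: 6 synthetic samples for each of the 2 most
#' underrepresented classes. Majority samples are never modified.
#'
#' When a minority class has fewer than `k + 1` samples, `k` is clamped to
#' the class size minus one with a warning. A 1-sample class cannot be
#' interpolated: by default this errors; `degenerate = "duplicate"` instead
#' emits copies of the lone sample (needed inside leave-one-out folds that
#' hold out one of two negative-class samples).
#'
#' @param X Numeric feature matrix (samples in rows).
#' @param y Factor of class labels (levels define the enumeration order).
#' @param n_per_class Synthetic samples per oversampled class (default 6).
#' @param n_classes Number of rarest classes to oversample (default 2).
#' @param k Neighbor count for interpolation (default 5, clamped per class).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param degenerate `"error"` (default) or `"duplicate"` for 1-sample classes.
#' @return List with `X`, `y` (originals first, synthetics appended),
#'   `synthetic` (logical), and `provenance` (data frame with base/neighbor
#'   row indices and interpolation gap for every synthetic sample).
#' @export
smote <- function(X, y, n_per_class = 6L, n_classes = 2L, k = 5L, seed = 1L,
                  degenerate = c("error", "duplicate")) {
  degenerate <- match.arg(degenerate)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (n_per_class < 0L || k < 1L) {
    stop("`n_per_class` must be >= 0 and `k` >= 1", call. = FALSE)
  }
  y <- factor(y, levels = levels(factor(y)))
  counts <- table(y)
  present <- names(counts)[counts > 0]
  ## rarest n_classes classes, ties broken by level enumeration order
  ord <- present[order(counts[present])]
  targets <- utils::head(ord, n_classes)
  if (n_per_class == 0L || length(targets) == 0L) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X)),
                provenance = data.frame(base = integer(), neighbor = integer(),
                                        gap = numeric(), class = character())))
  }
  newX <- list(); newy <- character(); prov <- list()
  withr::with_seed(seed, {
    for (cls in targets) {
      idx <- which(y == cls)
      m <- length(idx)
      if (m == 1L) {
        if (degenerate == "error") {
          stop("class '", cls, "' has a single sample: SMOTE cannot ",
               "interpolate; lower `k`, skip the class, or use ",
               "degenerate = \"duplicate\"", call. = FALSE)
        }
        warning("class '", cls, "' has one sample: duplicating it",
                call. = FALSE)
        for (s in seq_len(n_per_class)) {
          newX[[length(newX) + 1L]] <- X[idx, ]
          newy <- c(newy, cls)
          prov[[length(prov) + 1L]] <- data.frame(base = idx, neighbor = idx,
                                                  gap = 0, class = cls)
        }
        next
      }
      kc <- min(k, m - 1L)
      if (kc < k) {
        warning("class '", cls, "' has ", m, " samples: k clamped to ", kc,
                call. = FALSE)
      }
      D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
      diag(D) <- Inf
      for (s in seq_len(n_per_class)) {
        b <- sample.int(m, 1L)
        nb <- order(D[b, ])[sample.int(kc, 1L)]
        gap <- stats::runif(1)
        newX[[length(newX) + 1L]] <- X[idx[b], ] + gap * (X[idx[nb], ] - X[idx[b], ])
        newy <- c(newy, cls)
        prov[[length(prov) + 1L]] <- data.frame(base = idx[b], neighbor = idx[nb],
                                                gap = gap, class = cls)
      }
    }
  })
  Xs <- rbind(X, do.call(rbind, newX))
  rownames(Xs) <- NULL
  list(X = Xs,
       y = factor(c(as.character(y), newy), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, length(newy))),
       provenance = do.call(rbind, prov))
}

#' Fit a principal component model
#'
#' Principal axes of the (optionally z-scored) centered data, via
#' [stats::prcomp()]. Explained-variance fractions are relative to the total
#' variance over all components. The study protocol reduces to two
#' components.
#'
#' @param X Numeric matrix (>= 2 rows).
#' @param ncomp Number of retained components (default 2).
#' @param scale Z-score features before projection? Default `FALSE`
#'   (center only).
#' @return Object of class `pca_model`: `rotation` (p x ncomp orthonormal),
#'   `center`, `scale`, `explained` (length-ncomp fractions, non-increasing),
#'   `sdev_all`.
#' @export
pca_fit <- function(X, ncomp = 2L, scale = FALSE) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("constant-only table: PCA undefined", call. = FALSE)
  if (scale) {
    ## guard constant columns: unit divisor keeps them at zero after centering
    sc <- ifelse(sds > 0, sds, 1)
    p <- stats::prcomp(X, center = TRUE, scale. = sc)
  } else {
    p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  }
  tot <- sum(p$sdev^2)
  rank <- sum(p$sdev > max(p$sdev) * 1e-12)
  if (ncomp > rank) {
    stop("requested ", ncomp, " components but data rank is ", rank,
         call. = FALSE)
  }
  structure(list(rotation = p$rotation[, seq_len(ncomp), drop = FALSE],
                 center = p$center,
                 scale = if (scale) sc else rep(1, ncol(X)),
                 explained = (p$sdev^2 / tot)[seq_len(ncomp)],
                 sdev_all = p$sdev),
            class = "pca_model")
}

#' Project data onto a fitted principal component model
#' @param model A [pca_fit()] result.
#' @param X Numeric matrix with the same columns as the fitting data.
#' @return Matrix with `ncomp` columns.
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"), ncol(X) == nrow(model$rotation))
  sweep(sweep(X, 2, model$center), 2, model$scale, "/") %*% model$rotation
}
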