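#' Hyperparameter grid of a classifier family
#'
#' The explored architectures: kNN with k in 1..15; MLP1 with one hidden
#' layer of even size in \[6, 28\]; MLP2 with a first hidden layer of even
#' size in \[6, 28\] and a second of half that size; LVQ with even codebook
#' sizes in \[6, 28\]; RBF and PNN with Gaussian spreads 2^e for integer e in
#' \[-1, 15\].
#'
#' @param family One of `"kNN"`, `"MLP1"`, `"MLP2"`, `"LVQ"`, `"RBF"`, `"PNN"`.
#' @return List of classifier specs (each a list with `family` and the
#'   family's hyperparameters).
#' @export
classifier_grid <- function(family) {
  family <- match.arg(family, classifier_families())
  switch(family,
    kNN = lapply(1:15, function(k) list(family = "kNN", k = k)),
    MLP1 = lapply(seq(6L, 28L, 2L), function(h) list(family = "MLP1", hidden = h)),
    MLP2 = lapply(seq(6L, 28L, 2L),
                  function(h) list(family = "MLP2", hidden = c(h, h %/% 2L))),
    LVQ = lapply(seq(6L, 28L, 2L), function(m) list(family = "LVQ", codebook = m)),
    RBF = lapply(2^(-1:15), function(s) list(family = "RBF", spread = s)),
    PNN = lapply(2^(-1:15), function(s) list(family = "PNN", spread = s)))
}

#' The six classifier family names
#' @return Character vector.
#' @export
classifier_families <- function() c("kNN", "MLP1", "MLP2", "LVQ", "RBF", "PNN")

## z-scoring fitted on the training fold; constant features get unit scale
fit_zscore <- function(X) {
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  list(center = ctr, scale = ifelse(sds > 0, sds, 1))
}
apply_zscore <- function(z, X) sweep(sweep(X, 2, z$center), 2, z$scale, "/")

#' Train a classifier
#'
#' A uniform train contract over the six families. Features are z-scored on
#' the training fold (stored in the model) before any distance, kernel or
#' gradient computation, because raw feature scales differ by orders of
#' magnitude. All stochastic initialization flows from `seed`, so identical
#' spec + seed + data give identical models.
#'
#' Family behavior: kNN and PNN store the exemplars; MLPs are fully-connected
#' feed-forward networks (logistic hidden units, softmax output) trained by
#' full-batch gradient descent; LVQ is classical LVQ1 with codebook vectors
#' allocated to classes proportionally to class frequency (at least one per
#' class), initialized at class means plus a small seeded jitter and updated
#' by winner attract/repel with a linearly decaying learning rate; RBF places
#' a Gaussian unit on every training point and solves the output weights by a
#' ridge-stabilized least squares.
#'
#' @param spec A spec from [classifier_grid()].
#' @param X Numeric training matrix.
#' @param y Factor of labels (all predictions use these levels).
#' @param seed Integer seed.
#' @param control Optional list overriding training controls
#'   (`mlp_epochs`, `mlp_lr`, `lvq_epochs`, `lvq_lr`, `rbf_ridge`).
#' @return Object of class `pet_classifier`.
#' @export
train_classifier <- function(spec, X, y, seed = 1L, control = list()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (!is.factor(y)) y <- factor(y)   # factor() on a factor drops empty levels
  if (spec$family %in% c("LVQ", "RBF", "PNN") && any(table(y) == 0)) {
    stop("empty class for prototype-based family ", spec$family, call. = FALSE)
  }
  y <- droplevels(y)
  ctl <- utils::modifyList(list(mlp_epochs = 500L, mlp_lr = 0.3,
                                lvq_epochs = 30L, lvq_lr = 0.3,
                                rbf_ridge = 1e-8, zscore = TRUE), control)
  ## inputs that are already commensurate (e.g. PCA scores) keep their scale
  z <- if (isTRUE(ctl$zscore)) fit_zscore(X) else {
    list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  }
  Xs <- apply_zscore(z, X)
  fit <- switch(spec$family,
    kNN = list(X = Xs, y = y, k = spec$k),
    PNN = list(X = Xs, y = y, spread = spec$spread),
    RBF = train_rbf(Xs, y, spec$spread, ctl$rbf_ridge),
    LVQ = train_lvq(Xs, y, spec$codebook, seed, ctl$lvq_epochs, ctl$lvq_lr),
    MLP1 = train_mlp(Xs, y, spec$hidden, seed, ctl$mlp_epochs, ctl$mlp_lr),
    MLP2 = train_mlp(Xs, y, spec$hidden, seed, ctl$mlp_epochs, ctl$mlp_lr),
    stop("unknown classifier family", call. = FALSE))
  structure(list(spec = spec, zscore = z, fit = fit, classes = levels(y)),
            class = "pet_classifier")
}

train_rbf <- function(X, y, spread, ridge) {
  if (any(table(y) == 0)) stop("empty class for RBF", call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  Phi <- exp(-D2 / (2 * spread^2))
  Yh <- stats::model.matrix(~ y - 1)
  W <- solve(crossprod(Phi) + ridge * diag(nrow(X)), crossprod(Phi, Yh))
  list(centers = X, spread = spread, W = W)
}

train_lvq <- function(X, y, m, seed, epochs, lr0) {
  counts <- table(y)
  if (any(counts == 0)) stop("empty class for LVQ", call. = FALSE)
  ## proportional allocation with at least one prototype per class
  alloc <- pmax(1L, round(m * as.numeric(counts) / sum(counts)))
  while (sum(alloc) > m) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < m) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L
  proto_class <- rep(names(counts), alloc)
  withr::with_seed(seed, {
    proto <- t(vapply(proto_class, function(cls) {
      mu <- colMeans(X[y == cls, , drop = FALSE])
      mu + stats::rnorm(ncol(X), 0, 0.05)
    }, numeric(ncol(X))))
    n <- nrow(X)
    total <- epochs * n
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        step <- step + 1L
        lr <- lr0 * (1 - (step - 1L) / total)
        d2 <- rowSums(sweep(proto, 2, X[i, ])^2)
        w <- which.min(d2)
        sgn <- if (proto_class[w] == as.character(y[i])) 1 else -1
        proto[w, ] <- proto[w, ] + sgn * lr * (X[i, ] - proto[w, ])
      }
    }
  })
  list(prototypes = proto, proto_class = proto_class)
}

train_mlp <- function(X, y, hidden, seed, epochs, lr) {
  C <- nlevels(y)
  sizes <- c(ncol(X), hidden, C)
  Yh <- stats::model.matrix(~ y - 1)
  withr::with_seed(seed, {
    W <- lapply(seq_len(length(sizes) - 1L), function(l) {
      matrix(stats::runif((sizes[l] + 1L) * sizes[l + 1L], -0.5, 0.5),
             sizes[l] + 1L, sizes[l + 1L])
    })
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      ## forward
      acts <- list(cbind(1, X))
      for (l in seq_along(W)) {
        zl <- acts[[l]] %*% W[[l]]
        al <- if (l < length(W)) 1 / (1 + exp(-zl)) else {
          ez <- exp(zl - apply(zl, 1, max))
          ez / rowSums(ez)
        }
        acts[[l + 1L]] <- if (l < length(W)) cbind(1, al) else al
      }
      ## backward (softmax + cross-entropy)
      delta <- (acts[[length(acts)]] - Yh) / n
      for (l in rev(seq_along(W))) {
        grad <- crossprod(acts[[l]], delta)
        if (l > 1L) {
          a <- acts[[l]][, -1, drop = FALSE]
          delta <- (delta %*% t(W[[l]][-1, , drop = FALSE])) * a * (1 - a)
        }
        W[[l]] <- W[[l]] - lr * grad
      }
    }
  })
  list(W = W)
}

#' Predict with a trained classifier
#'
#' One label per row. Tie conventions are frozen: kNN breaks distance ties by
#' the smallest training index and vote ties by class enumeration order; PNN
#' breaks posterior ties by class enumeration order.
#'
#' @param model A [train_classifier()] result.
#' @param X Numeric matrix with the training feature dimension.
#' @return Factor of predicted labels over the training classes.
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "pet_classifier"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$zscore$center)) {
    stop("feature dimension mismatch: model expects ",
         length(model$zscore$center), " columns", call. = FALSE)
  }
  Xs <- apply_zscore(model$zscore, X)
  cls <- model$classes
  spec <- model$spec; fit <- model$fit
  pred <- switch(spec$family,
    kNN = apply(Xs, 1, function(x) {
      d <- sqrt(colSums((t(fit$X) - x)^2))
      nn <- order(d, seq_along(d))[seq_len(min(fit$k, length(d)))]
      votes <- table(factor(fit$y[nn], levels = cls))
      cls[which.max(votes)]
    }),
    PNN = apply(Xs, 1, function(x) {
      d2 <- colSums((t(fit$X) - x)^2)
      kern <- exp(-d2 / (2 * fit$spread^2))
      score <- vapply(cls, function(cl) sum(kern[fit$y == cl]), 0)
      if (all(score == 0)) {          # spread so small every kernel underflows
        as.character(fit$y[which.min(d2)])   # nearest exemplar's class
      } else cls[which.max(score)]
    }),
    RBF = {
      D2 <- outer(rowSums(Xs^2), rowSums(fit$centers^2), "+") -
        2 * Xs %*% t(fit$centers)
      Phi <- exp(-pmax(D2, 0) / (2 * fit$spread^2))
      S <- Phi %*% fit$W
      cls[max.col(S, ties.method = "first")]
    },
    LVQ = apply(Xs, 1, function(x) {
      d2 <- rowSums(sweep(fit$prototypes, 2, x)^2)
      fit$proto_class[which.min(d2)]
    }),
    MLP1 = , MLP2 = {
      a <- cbind(1, Xs)
      for (l in seq_along(fit$W)) {
        zl <- a %*% fit$W[[l]]
        a <- if (l < length(fit$W)) cbind(1, 1 / (1 + exp(-zl))) else zl
      }
      cls[max.col(a, ties.method = "first")]
    })
  factor(pred, levels = cls)
}
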