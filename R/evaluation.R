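#' Rank scores with ties averaged
#'
#' Competition ranking used throughout the comparison machinery: the best
#' (highest) score gets rank 1 and tied scores share the average of the ranks
#' they span.
#'
#' @param scores Numeric vector (higher is better).
#' @return Numeric vector of ranks.
#' @export
rank_with_ties <- function(scores) {
  stopifnot(length(scores) > 0)
  rank(-scores, ties.method = "average")
}

#' Iman-Davenport form of the Friedman statistic
#'
#' With N problems (response classes) and k methods (classifiers), the
#' Friedman chi-square is computed from the mean rank of each method,
#' chi2 = 12N/(k(k+1)) (sum_j Rbar_j^2 - k(k+1)^2/4), and transformed to the
#' F-ratio T1 = (N-1) chi2 / (N(k-1) - chi2), which is compared against the
#' F distribution with (k-1, (k-1)(N-1)) degrees of freedom. A degenerate
#' denominator (chi2 = N(k-1)) is reported as +Inf with a `degenerate`
#' attribute.
#'
#' @param rank_table N x k matrix of ranks (one row per problem; each row
#'   must sum to k(k+1)/2).
#' @return T1 (numeric scalar), with attributes `chisq`, `df` and
#'   `degenerate`.
#' @export
friedman_T1 <- function(rank_table) {
  stopifnot(is.matrix(rank_table))
  N <- nrow(rank_table); k <- ncol(rank_table)
  if (any(abs(rowSums(rank_table) - k * (k + 1) / 2) > 1e-8)) {
    stop("invalid rank table: each row must sum to k(k+1)/2", call. = FALSE)
  }
  rbar <- colMeans(rank_table)
  chisq <- 12 * N / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
  den <- N * (k - 1) - chisq
  degenerate <- den <= .Machine$double.eps^0.5 * N * (k - 1)
  t1 <- if (degenerate) Inf else (N - 1) * chisq / den
  structure(t1, chisq = chisq, df = c(k - 1, (k - 1) * (N - 1)),
            degenerate = degenerate)
}

#' Upper critical value of the F distribution
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return The upper-alpha quantile.
#' @export
f_critical <- function(alpha = 0.05, df1, df2) {
  if (alpha <= 0 || alpha >= 1 || df1 < 1 || df2 < 1) {
    stop("invalid alpha or degrees of freedom", call. = FALSE)
  }
  stats::qf(1 - alpha, df1, df2)
}

#' Bonferroni-Dunn comparison against a baseline classifier
#'
#' Critical difference CD = q_alpha sqrt(k(k+1)/(6N)), with q_alpha the
#' two-sided normal quantile at alpha/(k-1) (Bonferroni correction for k-1
#' comparisons against a control). A classifier significantly outperforms the
#' baseline when the baseline's average rank exceeds its own by more than CD.
#' `cd_override` substitutes an externally supplied critical value while
#' keeping the decision rule.
#'
#' @param avg_ranks Named numeric vector of average ranks per classifier.
#' @param baseline Name of the control classifier (present in `avg_ranks`).
#' @param N Number of problems (classes).
#' @param alpha Significance level.
#' @param cd_override Optional externally supplied CD.
#' @return List with `cd`, `q`, `baseline`, and `significant` (named logical;
#'   the baseline compares to itself as not significant).
#' @export
bonferroni_dunn <- function(avg_ranks, baseline, N, alpha = 0.05,
                            cd_override = NULL) {
  if (!baseline %in% names(avg_ranks)) {
    stop("baseline '", baseline, "' not among the classifiers", call. = FALSE)
  }
  k <- length(avg_ranks)
  q <- stats::qnorm(1 - alpha / (2 * (k - 1)))
  cd <- if (is.null(cd_override)) q * sqrt(k * (k + 1) / (6 * N)) else cd_override
  sig <- (avg_ranks[baseline] - avg_ranks) > cd
  list(cd = cd, q = q, baseline = baseline, significant = sig)
}

#' Full rank-based comparison of an accuracy table
#'
#' Ranks the classifiers within each class (ties averaged), computes average
#' ranks, the Iman-Davenport T1 statistic with its F critical value, and the
#' Bonferroni-Dunn test against the baseline.
#'
#' @param acc_table k x N matrix of per-class accuracies (rows = classifiers,
#'   columns = classes; entries in \[0, 1\]).
#' @param baseline Control classifier (row name), default `"kNN"`.
#' @param alpha Significance level.
#' @param cd_override Optional externally supplied critical difference.
#' @return Object of class `comparison_result`: `rank_table` (N x k),
#'   `avg_rank`, `T1`, `chisq`, `df`, `f_critical`, `cd`, `significant`.
#' @export
compare_classifiers <- function(acc_table, baseline = "kNN", alpha = 0.05,
                                cd_override = NULL) {
  stopifnot(is.matrix(acc_table))
  if (any(acc_table < 0 | acc_table > 1)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  k <- nrow(acc_table); N <- ncol(acc_table)
  rank_table <- t(apply(acc_table, 2, rank_with_ties))  # N x k
  colnames(rank_table) <- rownames(acc_table)
  avg_rank <- colMeans(rank_table)
  t1 <- friedman_T1(rank_table)
  fc <- f_critical(alpha, k - 1, (k - 1) * (N - 1))
  bd <- bonferroni_dunn(avg_rank, baseline, N, alpha, cd_override)
  structure(list(rank_table = rank_table, avg_rank = avg_rank,
                 T1 = as.numeric(t1), chisq = attr(t1, "chisq"),
                 df = attr(t1, "df"), f_critical = fc, alpha = alpha,
                 cd = bd$cd, baseline = baseline,
                 significant = bd$significant,
                 reject_null = as.numeric(t1) > fc),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Friedman / Iman-Davenport comparison\n")
  cat(sprintf("  T1 = %.3f  (chi2 = %.3f, F crit at alpha=%.2f on %d,%d df = %.2f)\n",
              x$T1, x$chisq, x$alpha, x$df[1], x$df[2], x$f_critical))
  cat(sprintf("  null hypothesis %s\n",
              if (x$reject_null) "REJECTED: classifiers differ" else "not rejected"))
  cat("  average ranks:\n")
  print(round(x$avg_rank, 3))
  cat(sprintf("  Bonferroni-Dunn CD vs %s = %.3f; significant: %s\n",
              x$baseline, x$cd,
              paste(names(x$significant)[x$significant], collapse = ", ")))
  invisible(x)
}

#' The study's printed per-class accuracy tables
#'
#' Returns the 6 x 4 per-class accuracy matrix of one of the four
#' experiments (original, smote, pca, smote+pca) as shipped in
#' `extdata/reference_accuracies.csv`, so the comparison statistics can be
#' exercised independently of training.
#'
#' @param experiment One of `"original"`, `"smote"`, `"pca"`, `"smote+pca"`.
#' @return 6 x 4 numeric matrix (classifiers x classes).
#' @export
reference_accuracies <- function(experiment = c("original", "smote", "pca",
                                                "smote+pca")) {
  experiment <- match.arg(experiment)
  path <- system.file("extdata", "reference_accuracies.csv",
                      package = "petresponse", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sub <- df[df$experiment == experiment, ]
  m <- as.matrix(sub[, c("negative", "neutral", "positive_partial",
                         "positive_complete")])
  rownames(m) <- sub$classifier
  m
}

#' Leave-one-out per-class accuracy of one classifier configuration
#'
#' Each sample is held out once; the preprocessing prescribed by `variant`
#' (SMOTE and/or PCA) is fitted on the remaining samples only, the model is
#' trained and the held-out sample predicted. Per-class accuracy is the
#' fraction of correctly predicted held-out samples of that class (per-class
#' recall). `pooled_fit = TRUE` instead fits SMOTE/PCA once on the full
#' table, mirroring a plausible reading of the original protocol.
#'
#' Inside folds, a minority class reduced to a single sample is oversampled
#' by duplication (see [smote()]'s `degenerate` argument).
#'
#' @param spec Classifier spec from [classifier_grid()].
#' @param X Feature matrix; `y` factor of labels.
#' @param variant One of `"original"`, `"smote"`, `"pca"`, `"smote+pca"`.
#' @param seed Master seed for SMOTE and training randomness.
#' @param ncomp PCA components (default 2).
#' @param pca_scale Z-score features before PCA (default `FALSE`).
#' @param smote_per_class,smote_classes SMOTE arithmetic (defaults 6 and 2).
#' @param pooled_fit Fit preprocessing on the full table once.
#' @param control Training controls passed to [train_classifier()].
#' @return Named numeric vector of per-class recalls over `levels(y)`, with
#'   attribute `predictions`.
#' @export
loo_per_class_accuracy <- function(spec, X, y,
                                   variant = c("original", "smote", "pca",
                                               "smote+pca"),
                                   seed = 1L, ncomp = 2L, pca_scale = FALSE,
                                   smote_per_class = 6L, smote_classes = 2L,
                                   pooled_fit = FALSE, control = list()) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2L)
  y <- factor(y)
  if (any(table(y) == 0)) y <- droplevels(y)
  use_smote <- variant %in% c("smote", "smote+pca")
  use_pca <- variant %in% c("pca", "smote+pca")
  ## PCA scores are commensurate: the classifiers keep their natural relative
  ## scale unless the caller explicitly asks for re-standardization
  if (use_pca && is.null(control$zscore)) control$zscore <- FALSE
  n <- nrow(X)
  preds <- character(n)

  if (pooled_fit) {
    Xw <- X; yw <- y
    if (use_smote) {
      sm <- suppressWarnings(smote(Xw, yw, smote_per_class, smote_classes,
                                   seed = seed, degenerate = "duplicate"))
      Xw <- sm$X; yw <- sm$y
    }
    pcam <- if (use_pca) pca_fit(Xw, ncomp, scale = pca_scale) else NULL
  }

  for (i in seq_len(n)) {
    if (pooled_fit) {
      ## whole-table preprocessing; the training rows are all but the held-out
      Xtr <- Xw[-i, , drop = FALSE]; ytr <- yw[-i]
      Xte <- X[i, , drop = FALSE]
      if (use_pca) { Xtr <- pca_transform(pcam, Xtr); Xte <- pca_transform(pcam, Xte) }
    } else {
      Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
      Xte <- X[i, , drop = FALSE]
      if (use_smote) {
        sm <- suppressWarnings(smote(Xtr, ytr, smote_per_class, smote_classes,
                                     seed = seed + i, degenerate = "duplicate"))
        Xtr <- sm$X; ytr <- sm$y
      }
      if (use_pca) {
        pcam <- pca_fit(Xtr, ncomp, scale = pca_scale)
        Xtr <- pca_transform(pcam, Xtr)
        Xte <- pca_transform(pcam, Xte)
      }
    }
    model <- train_classifier(spec, Xtr, ytr, seed = seed + i, control = control)
    preds[i] <- as.character(predict_classifier(model, Xte))
  }
  acc <- vapply(levels(y), function(cl) {
    idx <- which(y == cl)
    if (length(idx) == 0) return(NA_real_)
    mean(preds[idx] == cl)
  }, 0)
  structure(acc, predictions = factor(preds, levels = levels(y)))
}

#' Select the best configuration by average per-class rank
#'
#' Configurations are ranked per class (ties averaged, higher accuracy
#' better); the winner minimizes the mean rank over classes, ties broken by
#' grid order.
#'
#' @param acc_list List (one per configuration) of per-class accuracy
#'   vectors, all over the same classes.
#' @return List with `index` of the winner, `mean_ranks`, and the winner's
#'   `accuracies`.
#' @export
select_best_configuration <- function(acc_list) {
  if (length(acc_list) == 0) stop("no configurations to select from", call. = FALSE)
  A <- do.call(rbind, acc_list)           # configs x classes
  R <- apply(A, 2, rank_with_ties)
  if (is.null(dim(R))) R <- matrix(R, nrow = 1L)
  mr <- rowMeans(R)
  idx <- which.min(mr)                     # first minimum = grid order
  list(index = idx, mean_ranks = mr, accuracies = A[idx, ])
}

#' Run one full experiment: grid search, accuracy table, comparison
#'
#' For each classifier family, every configuration in its grid is evaluated
#' by leave-one-out under the given preprocessing variant; the configuration
#' with the best average per-class rank is selected, and its per-class
#' accuracies form the family's row of the accuracy table. The comparison
#' statistics (Friedman/Iman-Davenport and Bonferroni-Dunn vs the baseline)
#' are then computed on that table.
#'
#' @param X,y Dataset (feature matrix and label factor).
#' @param variant Preprocessing variant (see [loo_per_class_accuracy()]).
#' @param families Subset of [classifier_families()].
#' @param seed Master seed.
#' @param baseline Control classifier for the post-hoc test.
#' @param grids Optional named list overriding the per-family grids (used to
#'   scale experiments down).
#' @param ... Further arguments passed to [loo_per_class_accuracy()].
#' @return List with `accuracy_table`, `comparison`
#'   (a [compare_classifiers()] result when >= 2 families), `chosen` specs
#'   per family, `variant` and `seed`.
#' @export
run_experiment <- function(X, y, variant = "original",
                           families = classifier_families(), seed = 1L,
                           baseline = "kNN", grids = NULL, ...) {
  families <- match.arg(families, classifier_families(), several.ok = TRUE)
  rows <- list(); chosen <- list()
  for (fam in families) {
    grid <- if (!is.null(grids) && !is.null(grids[[fam]])) grids[[fam]] else classifier_grid(fam)
    accs <- lapply(grid, function(spec) {
      as.numeric(loo_per_class_accuracy(spec, X, y, variant, seed = seed, ...))
    })
    best <- select_best_configuration(accs)
    rows[[fam]] <- best$accuracies
    chosen[[fam]] <- grid[[best$index]]
  }
  acc_table <- do.call(rbind, rows)
  rownames(acc_table) <- families
  colnames(acc_table) <- levels(factor(y))
  comparison <- if (length(families) >= 2L && baseline %in% families) {
    compare_classifiers(acc_table, baseline = baseline)
  } else NULL
  list(accuracy_table = acc_table, comparison = comparison, chosen = chosen,
       variant = variant, seed = seed)
}
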