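#' Construct and validate a clinical record
#'
#' The eight per-patient clinical variables carried alongside the imaging
#' features: age (years), tumor stage (ordinal 1-4), pre/post-treatment
#' weight (kg), pre/post lesion SUVmax and pre/post reference-organ SUVmax
#' (dimensionless).
#'
#' @param age,tumor_stage,weight_pre,weight_post,suvmax_lesion_pre,suvmax_lesion_post,suvmax_reference_pre,suvmax_reference_post
#'   Positive numerics; `tumor_stage` must be an integer in 1..4.
#' @return Named numeric vector of length 8 (class `clinical_record`).
#' @export
clinical_record <- function(age, tumor_stage, weight_pre, weight_post,
                            suvmax_lesion_pre, suvmax_lesion_post,
                            suvmax_reference_pre, suvmax_reference_post) {
  v <- c(age = age, tumor_stage = tumor_stage, weight_pre = weight_pre,
         weight_post = weight_post, suvmax_lesion_pre = suvmax_lesion_pre,
         suvmax_lesion_post = suvmax_lesion_post,
         suvmax_reference_pre = suvmax_reference_pre,
         suvmax_reference_post = suvmax_reference_post)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("clinical variables must all be positive and finite", call. = FALSE)
  }
  if (tumor_stage != round(tumor_stage) || tumor_stage < 1 || tumor_stage > 4) {
    stop("`tumor_stage` must be an integer in 1..4", call. = FALSE)
  }
  structure(v, class = "clinical_record")
}

#' Names of the eight clinical variables
#' @return Character vector of length 8.
#' @export
clinical_names <- function() {
  c("age", "tumor_stage", "weight_pre", "weight_post", "suvmax_lesion_pre",
    "suvmax_lesion_post", "suvmax_reference_pre", "suvmax_reference_post")
}

#' Assemble one patient's 350-entry feature vector
#'
#' Concatenates the 8 clinical variables with the 171 pre-treatment and 171
#' post-treatment lesion descriptors (order clinical, pre, post). A complete
#' responder has no segmentable post-treatment lesion; callers handle this
#' upstream by extracting the post descriptors over the pre-treatment lesion
#' footprint applied to the post image, so vectors never contain missing
#' values.
#'
#' @param clinical A [clinical_record()].
#' @param pre,post Descriptor vectors of length 171 (see [extract_all()]).
#' @param label One of [response_classes()].
#' @param id Patient identifier string.
#' @return Object of class `patient_sample`: list with `features` (named
#'   350-vector), `label`, `id`.
#' @export
assemble_sample <- function(clinical, pre, post, label, id = "P000") {
  stopifnot(inherits(clinical, "clinical_record"))
  if (length(pre) != 171L || length(post) != 171L) {
    stop("descriptor vectors must have length 171", call. = FALSE)
  }
  label <- match.arg(label, response_classes())
  feats <- c(unclass(clinical), pre, post)
  names(feats) <- c(clinical_names(), feature_names("pre."), feature_names("post."))
  if (!all(is.finite(feats))) {
    bad <- names(feats)[!is.finite(feats)]
    stop("non-finite feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(features = feats, label = label, id = id),
            class = "patient_sample")
}

#' Build the tabular dataset from a synthetic cohort
#'
#' Runs the pipeline's own segmentation on each patient: the pre-treatment
#' lesion is delineated by 40% region growing from the image maximum. The
#' post-treatment lesion is deemed absent (complete response) when the post
#' image's maximum falls below `absence_ratio` times the pre image's maximum
#' — the patient's own pre-treatment scan is the reference, mirroring the
#' clinical reading that the lesion disappeared into background. An absent
#' lesion gets its post descriptors from the pre-treatment footprint applied
#' to the post image, so feature vectors never contain missing values;
#' otherwise the post image is region-grown like the pre image.
#'
#' @param cohort A [generate_cohort()] result.
#' @param threshold_fraction Region-growing threshold (default 0.40).
#' @param G Gray levels for quantization.
#' @param absence_ratio Post/pre maximum-intensity ratio below which the
#'   post lesion counts as absent (default 0.25).
#' @return `data.frame` with columns `id`, `label`, the 8 clinical variables,
#'   171 `pre.*` and 171 `post.*` features (63 rows for the default cohort).
#' @export
build_dataset <- function(cohort, threshold_fraction = 0.40, G = 16L,
                          absence_ratio = 0.25) {
  samples <- lapply(cohort, function(p) {
    pre_mask <- region_grow(p$pre_image, "auto", threshold_fraction)
    pre_feat <- extract_all(p$pre_image, pre_mask, G)
    post_mask <- if (max(p$post_image) < absence_ratio * max(p$pre_image)) {
      pre_mask
    } else {
      region_grow(p$post_image, "auto", threshold_fraction)
    }
    post_feat <- extract_all(p$post_image, post_mask, G)
    assemble_sample(p$clinical, pre_feat, post_feat, p$label, p$id)
  })
  samples_to_frame(samples)
}

#' Convert a list of patient samples to the canonical data frame
#' @param samples List of [assemble_sample()] results.
#' @return `data.frame` with `id`, `label`, then 350 feature columns.
#' @export
samples_to_frame <- function(samples) {
  feat <- do.call(rbind, lapply(samples, function(s) s$features))
  df <- data.frame(id = vapply(samples, `[[`, "", "id"),
                   label = vapply(samples, `[[`, "", "label"),
                   feat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

dataset_columns <- function() {
  c("id", "label", clinical_names(), feature_names("pre."), feature_names("post."))
}

#' Write the dataset to CSV
#'
#' Numeric columns are serialized with 17 significant digits so that
#' `read_dataset(write_dataset(x))` round-trips doubles exactly.
#'
#' @param dataset Data frame from [build_dataset()] / [samples_to_frame()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (!identical(colnames(dataset), dataset_columns())) {
    stop("dataset columns do not match the frozen schema", call. = FALSE)
  }
  out <- dataset
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset CSV written by [write_dataset()]
#'
#' @param path CSV path.
#' @return Data frame with the frozen column schema; errors identify the
#'   offending column count or name on schema violations.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expect <- dataset_columns()
  if (ncol(df) != length(expect)) {
    stop(sprintf("parse error: expected %d columns, found %d",
                 length(expect), ncol(df)), call. = FALSE)
  }
  bad <- which(colnames(df) != expect)
  if (length(bad) > 0) {
    stop(sprintf("parse error: column %d is '%s', expected '%s'",
                 bad[1], colnames(df)[bad[1]], expect[bad[1]]), call. = FALSE)
  }
  if (nrow(df) > 0 && !all(df$label %in% response_classes())) {
    stop("parse error: unknown response-class label", call. = FALSE)
  }
  df
}

#' Split a dataset frame into a feature matrix and labels
#' @param dataset Data frame with the frozen schema.
#' @return List with `X` (numeric matrix, 350 columns) and `y` (factor over
#'   [response_classes()]).
#' @export
dataset_matrix <- function(dataset) {
  X <- as.matrix(dataset[, -(1:2), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = factor(dataset$label, levels = response_classes()))
}
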