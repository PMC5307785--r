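#' Treatment-response class labels
#'
#' The four ordinal response categories: `negative` (malignancy increased),
#' `neutral` (no response), `positive_partial` (lesion shrank but persists)
#' and `positive_complete` (lesion disappeared).
#'
#' @return Character vector of the four class labels, in fixed enumeration
#'   order (used everywhere ties must be broken by class order).
#' @export
response_classes <- function() {
  c("negative", "neutral", "positive_partial", "positive_complete")
}

#' Configuration for synthetic cohort generation
#'
#' Defaults describe the emulated study population: 63 patients split
#' 2/6/27/28 across the four response classes, one 64x64 attenuation-corrected
#' PET-like image per timepoint. Class effects are encoded as multiplicative
#' post/pre intensity and radius ratios: the lesion brightens and grows under
#' progression, is re-drawn unchanged under no response, shrinks and dims under
#' partial response, and vanishes under complete response.
#'
#' @param class_counts Named integer vector over [response_classes()].
#' @param image_size Pixels per side of the square images.
#' @param lesion_radius_range Pre-treatment lesion radius bounds (pixels).
#' @param lesion_peak_range Pre-treatment lesion peak intensity bounds, in (0, 1].
#' @param texture_smoothness Correlation length (pixels) of the multiplicative
#'   Gaussian random texture field; `Inf` gives a flat (textureless) lesion.
#' @param texture_amplitude Standard deviation of the texture field around 1.
#' @param background_level Background intensity level.
#' @param background_noise_sd Background noise standard deviation; noise is
#'   truncated at three standard deviations so a vanished lesion never leaves a
#'   supra-background pixel in its old footprint.
#' @param intensity_ratios,radius_ratios Named post/pre multiplicative effects
#'   per class.
#' @param suv_scale Multiplier mapping lesion peak intensity to a synthetic
#'   lesion SUVmax clinical variable.
#' @param rng_seed Master seed; identical config + seed gives a byte-identical
#'   cohort.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(class_counts = c(negative = 2L, neutral = 6L,
                                           positive_partial = 27L,
                                           positive_complete = 28L),
                          image_size = 64L,
                          lesion_radius_range = c(10.5, 11.5),
                          lesion_peak_range = c(0.49, 0.51),
                          texture_smoothness = 0.5,
                          texture_amplitude = 0.05,
                          background_level = 0.05,
                          background_noise_sd = 0.005,
                          intensity_ratios = c(negative = 2.0, neutral = 1.0,
                                               positive_partial = 0.3,
                                               positive_complete = 0.0),
                          radius_ratios = c(negative = 1.5, neutral = 1.0,
                                            positive_partial = 0.45,
                                            positive_complete = 0.0),
                          suv_scale = 15,
                          rng_seed = 1L) {
  cls <- response_classes()
  counts <- rep(0L, 4L); names(counts) <- cls
  counts[names(class_counts)] <- as.integer(class_counts)
  if (anyNA(counts) || any(counts < 0L)) {
    stop("config error in `class_counts`: counts must be non-negative integers",
         call. = FALSE)
  }
  if (sum(counts) < 1L) {
    stop("config error in `class_counts`: at least one patient required",
         call. = FALSE)
  }
  if (length(lesion_radius_range) != 2L || diff(lesion_radius_range) < 0 ||
      lesion_radius_range[1] <= 0) {
    stop("config error in `lesion_radius_range`: need a non-empty positive interval",
         call. = FALSE)
  }
  if (length(lesion_peak_range) != 2L || lesion_peak_range[1] <= 0 ||
      lesion_peak_range[2] > 1 || diff(lesion_peak_range) < 0) {
    stop("config error in `lesion_peak_range`: bounds must lie in (0, 1]",
         call. = FALSE)
  }
  max_post_radius <- lesion_radius_range[2] * max(radius_ratios, 1)
  if (2 * max_post_radius + 4 > image_size) {
    stop("config error in `lesion_radius_range`: lesion larger than image",
         call. = FALSE)
  }
  structure(list(class_counts = counts, image_size = as.integer(image_size),
                 lesion_radius_range = lesion_radius_range,
                 lesion_peak_range = lesion_peak_range,
                 texture_smoothness = texture_smoothness,
                 texture_amplitude = texture_amplitude,
                 background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 intensity_ratios = intensity_ratios[cls],
                 radius_ratios = radius_ratios[cls],
                 suv_scale = suv_scale,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

## smooth multiplicative texture field: white noise convolved with a Gaussian
## kernel of width `smoothness`, rescaled to mean 1 / sd `amplitude`
gaussian_texture_field <- function(n, smoothness, amplitude) {
  if (!is.finite(smoothness) || amplitude == 0) return(matrix(1, n, n))
  z <- matrix(stats::rnorm(n * n), n, n)
  h <- ceiling(2 * smoothness)
  g <- stats::dnorm(-h:h, sd = smoothness)
  g <- g / sum(g)
  sm <- apply(z, 2, function(col) {
    p <- c(rev(col[seq_len(min(h, n))]), col, rev(col[seq.int(max(1, n - h + 1), n)]))
    stats::filter(p, g, sides = 2)[h + seq_len(n)]
  })
  sm <- t(apply(sm, 1, function(row) {
    p <- c(rev(row[seq_len(min(h, n))]), row, rev(row[seq.int(max(1, n - h + 1), n)]))
    stats::filter(p, g, sides = 2)[h + seq_len(n)]
  }))
  s <- stats::sd(sm)
  if (s == 0) return(matrix(1, n, n))
  1 + amplitude * (sm - mean(sm)) / s
}

#' Generate one synthetic lesion image with its ground-truth mask
#'
#' The noiseless lesion profile is a radially decreasing Gaussian bump
#' calibrated so that the profile equals 40% of `peak` exactly at `radius`:
#' the ground-truth mask (profile >= 0.4 peak) is then the disc of radius
#' `radius`, matching what the pipeline's own 40% region growing should
#' recover on a clean image. Texture multiplies the profile inside the
#' lesion; truncated Gaussian noise is added everywhere.
#'
#' @param size Image side in pixels.
#' @param center Lesion center `c(row, col)`, 1-based.
#' @param radius Lesion radius in pixels (`0` means no lesion).
#' @param peak Lesion peak intensity in (0, 1].
#' @param smoothness Texture correlation length; `Inf` = flat.
#' @param amplitude Texture standard deviation around 1.
#' @param background Background level added everywhere.
#' @param noise_sd Noise standard deviation (truncated at 3 sd).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param texture_seed Separate seed for the lesion texture field (defaults
#'   to `seed`). Paired pre/post images of one patient share it: the lesion's
#'   texture is a property of the lesion, which persists between scans, while
#'   acquisition noise is redrawn.
#' @return List with `image` (numeric matrix in \[0,1\]) and `mask` (logical
#'   matrix: the noiseless-profile ground truth).
#' @export
generate_lesion_image <- function(size = 64L, center = c(32, 32), radius = 10,
                                  peak = 1.0, smoothness = 4, amplitude = 0.15,
                                  background = 0.05, noise_sd = 0.01,
                                  seed = 1L, texture_seed = seed) {
  size <- as.integer(size)
  if (radius > 0) {
    if (peak <= 0 || peak > 1) stop("`peak` must be in (0, 1]", call. = FALSE)
    if (center[1] - radius < 1 || center[1] + radius > size ||
        center[2] - radius < 1 || center[2] + radius > size) {
      stop("lesion does not fit inside the image", call. = FALSE)
    }
  }
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  if (radius > 0) {
    d2 <- (rr - center[1])^2 + (cc - center[2])^2
    ## exp(-log(2.5) (d/r)^2): equals 0.4*peak exactly at d = radius
    profile <- peak * exp(-log(2.5) * d2 / radius^2)
    mask <- profile >= 0.4 * peak
    tex <- withr::with_seed(texture_seed,
                            gaussian_texture_field(size, smoothness, amplitude))
    lesion <- profile * pmax(tex, 0)
  } else {
    lesion <- matrix(0, size, size)
    mask <- matrix(FALSE, size, size)
  }
  noise <- withr::with_seed(seed,
    matrix(pmin(pmax(stats::rnorm(size * size, 0, noise_sd),
                     -3 * noise_sd), 3 * noise_sd), size, size))
  img <- pmin(pmax(background + lesion + noise, 0), 1)
  list(image = img, mask = mask)
}

#' Generate a synthetic patient cohort
#'
#' Emits `sum(class_counts)` patients, each with a pre-treatment lesion image,
#' a post-treatment image whose lesion intensity and extent follow the
#' patient's response class, eight clinical variables and the pre-treatment
#' ground-truth mask. Deterministic under the config's `rng_seed`.
#'
#' @param config A [cohort_config()].
#' @return List of patients (class `pet_cohort`); each patient is a list with
#'   `id`, `label`, `pre_image`, `post_image`, `clinical`,
#'   `ground_truth_mask_pre`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  counts <- config$class_counts
  n <- sum(counts)
  labels <- rep(names(counts), counts)
  seeds <- withr::with_seed(config$rng_seed,
                            sample.int(.Machine$integer.max, 2L * n))
  patients <- vector("list", n)
  margin <- config$lesion_radius_range[2] * max(config$radius_ratios, 1) + 2
  for (i in seq_len(n)) {
    cls <- labels[i]
    ir <- config$intensity_ratios[[cls]]
    rr <- config$radius_ratios[[cls]]
    pars <- withr::with_seed(seeds[2L * i - 1L], list(
      radius = stats::runif(1, config$lesion_radius_range[1],
                            config$lesion_radius_range[2]),
      peak = stats::runif(1, config$lesion_peak_range[1],
                          config$lesion_peak_range[2]),
      center = round(stats::runif(2, margin + 1, config$image_size - margin)),
      age = stats::runif(1, 18, 85),
      stage = sample(1:4, 1),
      weight_pre = stats::runif(1, 50, 100),
      weight_change = stats::runif(1, 0.95, 1.05),
      suv_ref = stats::runif(2, 1.5, 3.0)
    ))
    pre <- generate_lesion_image(config$image_size, pars$center, pars$radius,
                                 pars$peak, config$texture_smoothness,
                                 config$texture_amplitude,
                                 config$background_level,
                                 config$background_noise_sd,
                                 seed = seeds[2L * i - 1L])
    post_peak <- min(pars$peak * ir, 1)
    post_radius <- pars$radius * rr
    post <- generate_lesion_image(config$image_size, pars$center,
                                  if (ir > 0) post_radius else 0,
                                  if (ir > 0) post_peak else 0.5,
                                  config$texture_smoothness,
                                  config$texture_amplitude,
                                  config$background_level,
                                  config$background_noise_sd,
                                  seed = seeds[2L * i],
                                  texture_seed = seeds[2L * i - 1L])
    clinical <- clinical_record(
      age = pars$age, tumor_stage = pars$stage,
      weight_pre = pars$weight_pre,
      weight_post = pars$weight_pre * pars$weight_change,
      suvmax_lesion_pre = pars$peak * config$suv_scale,
      suvmax_lesion_post = max(post_peak, config$background_level) * config$suv_scale,
      suvmax_reference_pre = pars$suv_ref[1],
      suvmax_reference_post = pars$suv_ref[2])
    patients[[i]] <- structure(list(
      id = sprintf("P%03d", i), label = cls,
      pre_image = pre$image, post_image = post$image,
      clinical = clinical, ground_truth_mask_pre = pre$mask),
      class = "synthetic_patient")
  }
  structure(patients, class = "pet_cohort", config = config)
}

#' @export
print.pet_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat("Synthetic PET/CT response cohort:", length(x), "patients\n")
  print(table(factor(labs, levels = response_classes())))
  invisible(x)
}
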