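#' Estimate the illumination (shading) field from an image ensemble
#'
#' Averages all images of one channel pixelwise, smooths the average with a
#' large Gaussian kernel (sigma = image width / 10) to remove object texture,
#' and rescales the result to mean 1. The resulting multiplicative gain field
#' captures uneven illumination across the field of view and can be divided
#' out of every image of the ensemble.
#'
#' @param images A list of numeric matrices (same shape), typically all actin
#'   channel fields of a sub-experiment.
#' @param sigma Gaussian smoothing sigma in pixels; defaults to width / 10.
#' @return An object of class `illumination_field`: list with `gain` (matrix,
#'   strictly positive, mean 1), `n_images_averaged` and `sigma`.
#' @details A single-image ensemble is allowed (the smoothed, normalised
#'   image itself) but raises a warning, since object structure then leaks
#'   into the estimate.
#' @export
estimate_illumination <- function(images, sigma = NULL) {
  if (is.matrix(images)) images <- list(images)
  if (length(images) == 0) rlang::abort("estimate_illumination() needs at least one image")
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1) rlang::abort("all images must have the same shape")
  if (length(images) == 1) {
    rlang::warn("estimating illumination from a single image; object texture may leak into the gain")
  }
  avg <- Reduce(`+`, lapply(images, as_image_matrix)) / length(images)
  sigma <- sigma %||% (ncol(avg) / 10)
  radius <- 2L * ceiling(3 * sigma) + 1L
  # the Gaussian brush must fit inside the image
  max_radius <- min(dim(avg)) - (1L - min(dim(avg)) %% 2L)
  radius <- min(radius, max_radius)
  sm <- as_image_matrix(EBImage::gblur(avg, sigma = sigma, radius = radius,
                                       boundary = "replicate"))
  m <- mean(sm)
  if (m <= 0) rlang::abort("degenerate ensemble: non-positive mean intensity")
  gain <- sm / m
  gain[gain < 1e-6] <- 1e-6
  structure(
    list(gain = gain, n_images_averaged = length(images), sigma = sigma),
    class = "illumination_field"
  )
}

#' Correct an image for uneven illumination
#'
#' Divides the image elementwise by the estimated gain field, the exact
#' inverse of the multiplicative shading model.
#'
#' @param image Numeric matrix.
#' @param field An [estimate_illumination()] result (or a bare gain matrix).
#' @return The corrected matrix (non-negative wherever the input is).
#' @export
correct_illumination <- function(image, field) {
  gain <- if (inherits(field, "illumination_field")) field$gain else as_image_matrix(field)
  image <- as_image_matrix(image)
  if (!all(dim(image) == dim(gain))) rlang::abort("image and illumination field shapes differ")
  image / gain
}

#' Rescale image intensities to the unit interval
#'
#' Affine min-max rescaling: the darkest pixel maps to 0 and the brightest to
#' 1. A constant image is degenerate and returns all zeros with a warning.
#'
#' @param image Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
rescale_minmax <- function(image) {
  image <- as_image_matrix(image)
  mn <- min(image); mx <- max(image)
  if (mx == mn) {
    rlang::warn("constant image: rescale_minmax() returns all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - mn) / (mx - mn)
}

#' Automatic threshold by Otsu's method in the log domain
#'
#' Computes an intensity threshold by maximising the between-class variance
#' of the image histogram, after min-max scaling the image into `[0, 1]` and
#' log-transforming it (`log(eps + x)`, `eps = 1/65536`). Log-transforming
#' before thresholding makes the split robust to the fraction of the image
#' covered by bright objects, which varies strongly from field to field in a
#' spreading assay. The chosen log-domain boundary is mapped back to the
#' original intensity scale.
#'
#' @param image Numeric matrix with positive dynamic range.
#' @param n_bins Number of histogram bins (default 256).
#' @return A single threshold value, strictly between the image minimum and
#'   maximum.
#' @export
otsu_log_threshold <- function(image, n_bins = 256L) {
  image <- as_image_matrix(image)
  mn <- min(image); mx <- max(image)
  if (mx == mn) rlang::abort("constant image: no threshold exists")
  eps <- 1 / 65536
  y <- log(eps + (image - mn) / (mx - mn))
  lo <- min(y); hi <- max(y)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(y, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2

  w <- counts / sum(counts)
  cw <- cumsum(w)                     # class-0 weight up to boundary k
  cm <- cumsum(w * mids)              # class-0 first moment
  mu <- cm[n_bins]
  k <- seq_len(n_bins - 1L)
  valid <- cw[k] > 0 & cw[k] < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu * cw[k][valid] - cm[k][valid])^2 / (cw[k][valid] * (1 - cw[k][valid]))
  best <- which.max(bcv)
  t_log <- breaks[best + 1L]          # boundary between bins `best` and `best + 1`

  t_scaled <- exp(t_log) - eps
  thr <- mn + t_scaled * (mx - mn)
  # numerical guard: keep strictly inside the dynamic range
  min(max(thr, mn + .Machine$double.eps * abs(mn)), mx - .Machine$double.eps * abs(mx))
}
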