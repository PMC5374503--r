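#' Default Laplacian-of-Gaussian scale set
#'
#' Three scales in mm: fine (0.5), medium (1.5) and coarse (2.0) texture.
#'
#' @return Named numeric vector of sigma values in mm.
#' @export
default_scales <- function() c(fine = 0.5, medium = 1.5, coarse = 2.0)

.validate_scales <- function(scales) {
  scales <- as.numeric(scales)
  if (!length(scales) || any(!is.finite(scales)) || any(scales <= 0))
    stop("scales must be positive sigma values in mm")
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing")
  scales
}

## 1-D kernel construction --------------------------------------------------
## The 3-D LoG kernel is a sum of three separable terms,
##   del^2 G = Gxx*Gy*Gz + Gx*Gyy*Gz + Gx*Gy*Gzz,
## so the filter is applied as three separable passes and summed. Two kernel
## modes are provided:
##  * "corrected" (default): the axis Gaussian is normalized to unit sum and
##    the second-derivative kernel has its mean removed, so a constant volume
##    maps exactly to zero (no DC leakage from truncation/discretization).
##  * "sampled": raw samples of the analytic G and G''; with unit spacing the
##    impulse response is then exactly the sampled analytic 3-D LoG kernel.
##    Used for validation against the closed form.

.gauss_1d <- function(sigma_mm, h_mm, truncate, mode) {
  r <- max(1L, as.integer(ceiling(truncate * sigma_mm / h_mm)))
  x <- (-r:r) * h_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))
  if (mode == "corrected") g / sum(g) else g * h_mm
}

.gauss_d2_1d <- function(sigma_mm, h_mm, truncate, mode) {
  r <- max(1L, as.integer(ceiling(truncate * sigma_mm / h_mm)))
  x <- (-r:r) * h_mm
  g <- exp(-x^2 / (2 * sigma_mm^2)) / (sigma_mm * sqrt(2 * pi))
  g2 <- ((x^2 - sigma_mm^2) / sigma_mm^4) * g * h_mm
  if (mode == "corrected") g2 - mean(g2) else g2
}

## Reflect (mirror with edge repeat) index folding into 1..n.
.reflect_index <- function(j, n) {
  # period of the reflected sequence is 2n
  j <- (j - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

## Dense n x n convolution matrix for one axis with reflect boundary.
.conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    src <- .reflect_index(seq_len(n) + off, n)
    idx <- cbind(seq_len(n), src)
    M[idx] <- M[idx] + kernel[k]
  }
  M
}

## Apply a 1-D kernel along one axis of a 3-D array (reflect boundary).
.conv_axis <- function(a, M, axis) {
  d <- dim(a)
  if (axis == 1L) {
    out <- M %*% matrix(a, nrow = d[1])
    dim(out) <- d
    return(out)
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  out <- M %*% matrix(ap, nrow = dp[1])
  dim(out) <- dp
  aperm(out, order(perm))
}

.smooth_gaussian <- function(volume, spacing, sigma_mm, truncate = 4,
                             mode = "corrected") {
  d <- dim(volume)
  out <- volume
  for (ax in 1:3) {
    g <- .gauss_1d(sigma_mm, spacing[ax], truncate, mode)
    out <- .conv_axis(out, .conv_matrix(d[ax], g), ax)
  }
  out
}

#' Laplacian-of-Gaussian filter of a 3-D volume
#'
#' Applies the LoG operator (Gaussian smoothing at scale `sigma_mm` followed
#' by the Laplacian) to a 3-D grid. The filter is computed as the sum of
#' three separable passes, one per axis, each convolving the
#' second-derivative-of-Gaussian kernel along that axis and the Gaussian
#' kernel along the others; this is algebraically identical to convolution
#' with the sampled analytic 3-D LoG kernel. The sigma given in mm is
#' converted per axis using the voxel spacing, so anisotropic grids are
#' handled correctly. Boundaries use reflect (mirror) padding.
#'
#' @param volume 3-D numeric array.
#' @param spacing Voxel size in mm per axis (length 3, or a scalar recycled).
#' @param sigma_mm Positive filter scale in mm. A sigma smaller than half the
#'   largest voxel size triggers an under-resolved-scale warning.
#' @param truncate Kernel truncation radius in units of sigma (default 4).
#' @param kernel `"corrected"` (default; zero-DC kernels so constants map to
#'   exactly zero) or `"sampled"` (raw analytic samples, used for closed-form
#'   validation).
#' @param scale_normalized If `TRUE`, responses are multiplied by sigma^2
#'   (scale-normalized Laplacian, as used in scale-space blob detection).
#'   Default `FALSE`: the plain LoG response.
#' @return 3-D array of filter responses, same shape as `volume`, with
#'   attributes `sigma_mm` and `scale_normalized`.
#' @export
log_filter <- function(volume, spacing = c(1, 1, 1), sigma_mm,
                       truncate = 4, kernel = c("corrected", "sampled"),
                       scale_normalized = FALSE) {
  kernel <- match.arg(kernel)
  volume <- as.array(volume)
  if (length(dim(volume)) != 3L) stop("volume must be a 3-D array")
  if (anyNA(volume) || any(!is.finite(volume)))
    stop("volume contains non-finite values")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm")
  if (!is.finite(sigma_mm) || sigma_mm <= 0) stop("sigma_mm must be positive")
  if (sigma_mm < max(spacing) / 2)
    warning(sprintf(
      "sigma %.3g mm is under-resolved for voxel spacing %.3g mm",
      sigma_mm, max(spacing)))
  d <- dim(volume)
  g <- lapply(1:3, function(ax) .gauss_1d(sigma_mm, spacing[ax], truncate, kernel))
  g2 <- lapply(1:3, function(ax) .gauss_d2_1d(sigma_mm, spacing[ax], truncate, kernel))
  Mg <- lapply(1:3, function(ax) .conv_matrix(d[ax], g[[ax]]))
  Mg2 <- lapply(1:3, function(ax) .conv_matrix(d[ax], g2[[ax]]))
  # share the partial Gaussian passes between the three derivative terms
  s1 <- .conv_axis(volume, Mg[[1]], 1L)
  s12 <- .conv_axis(s1, Mg[[2]], 2L)
  s13 <- .conv_axis(s1, Mg[[3]], 3L)
  s23 <- .conv_axis(.conv_axis(volume, Mg[[2]], 2L), Mg[[3]], 3L)
  out <- .conv_axis(s23, Mg2[[1]], 1L) +
    .conv_axis(s13, Mg2[[2]], 2L) +
    .conv_axis(s12, Mg2[[3]], 3L)
  if (scale_normalized) out <- out * sigma_mm^2
  attr(out, "sigma_mm") <- sigma_mm
  attr(out, "scale_normalized") <- scale_normalized
  out
}

#' Summarize a set of filter responses by the three quantifier functions
#'
#' Computes the average (A), the population standard deviation (SD, the
#' second central moment with a 1/n denominator) and the intensity-histogram
#' entropy (E) of the filter responses gathered from one region. Entropy
#' uses a uniform discretization of the region's own min-max range into
#' `n_bins` equal-width intervals (half-open, with the maximum assigned to
#' the last bin) and is reported in bits: E = -sum_k p_k log2 p_k with
#' p_k the fraction of responses in interval k. All responses equal gives
#' E = 0 (a single occupied bin).
#'
#' @param responses Numeric vector of filter responses at the voxels of one
#'   region; `NA` values are dropped.
#' @param n_bins Number of histogram intervals (default 256).
#' @return Named numeric vector `c(A, SD, E)`; all `NA` (with a warning) if
#'   no responses remain, so one empty region does not abort a cohort run.
#' @export
quantify_responses <- function(responses, n_bins = 256) {
  if (!is.numeric(n_bins) || n_bins < 2) stop("n_bins must be >= 2")
  n_bins <- as.integer(n_bins)
  x <- responses[!is.na(responses)]
  if (!length(x)) {
    warning("empty response set: quantifiers are missing")
    return(c(A = NA_real_, SD = NA_real_, E = NA_real_))
  }
  a <- mean(x)
  s <- sqrt(mean((x - a)^2))
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    e <- 0
  } else {
    k <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    p <- tabulate(k, nbins = n_bins) / length(x)
    p <- p[p > 0]
    e <- -sum(p * log2(p))
  }
  c(A = a, SD = s, E = e)
}

#' Extract multi-scale regional texture features for one subject
#'
#' Filters the whole intensity volume once per scale and summarizes the
#' responses within each mapped region by the three quantifier functions,
#' yielding 9 features per region with the default three scales. Regions in
#' the map that are absent from the label grid yield missing values and a
#' warning; if none of the mapped labels is present the label file is likely
#' wrong and an error is raised.
#'
#' @param volume A [labeled_volume()].
#' @param region_map Region map data frame (default [default_region_map()]).
#' @param scales Strictly increasing sigma values in mm (default
#'   [default_scales()]).
#' @param n_bins Entropy histogram intervals (default 256).
#' @param ... Further arguments passed to [log_filter()].
#' @return One-row data frame: `subject_id` plus one column per
#'   (region, scale, quantifier), named `region__sigma__quantifier`.
#' @export
extract_features <- function(volume, region_map = default_region_map(),
                             scales = default_scales(), n_bins = 256, ...) {
  stopifnot(inherits(volume, "labeled_volume"))
  region_map <- validate_region_map(region_map)
  scales <- .validate_scales(scales)
  lab <- as.vector(volume$labels)
  present <- region_map$label_id %in% lab
  if (!any(present))
    stop("no region-map label occurs in the label grid; wrong label volume?")
  if (any(!present))
    warning(sprintf("%d region(s) absent from label grid: %s",
                    sum(!present),
                    paste(region_map$region_name[!present], collapse = ", ")))
  # voxel index lists per mapped region, computed once
  idx <- lapply(region_map$label_id, function(id) which(lab == id))
  vals <- numeric(0)
  nms <- character(0)
  for (s in scales) {
    resp <- as.vector(log_filter(volume$intensity, volume$spacing, s, ...))
    for (r in seq_len(nrow(region_map))) {
      q <- if (length(idx[[r]])) {
        quantify_responses(resp[idx[[r]]], n_bins = n_bins)
      } else {
        c(A = NA_real_, SD = NA_real_, E = NA_real_)
      }
      vals <- c(vals, q)
      nms <- c(nms, feature_name(region_map$region_name[r], s, names(q)))
    }
  }
  out <- as.data.frame(as.list(vals))
  names(out) <- nms
  cbind(data.frame(subject_id = volume$subject_id, stringsAsFactors = FALSE),
        out)
}

#' Extract features for a cohort of volumes
#'
#' @param volumes Either a list of [labeled_volume()] objects or a function
#'   `function(i)` returning the i-th volume (a streaming source, so large
#'   cohorts need not be held in memory), in which case `n` must be given.
#' @param n Number of subjects when `volumes` is a function.
#' @param ... Arguments passed to [extract_features()].
#' @return Feature table data frame, one row per subject.
#' @export
extract_cohort_features <- function(volumes, n = NULL, ...) {
  get_vol <- if (is.function(volumes)) {
    if (is.null(n)) stop("n is required when volumes is a function")
    volumes
  } else {
    n <- length(volumes)
    function(i) volumes[[i]]
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) rows[[i]] <- extract_features(get_vol(i), ...)
  ft <- do.call(rbind, rows)
  if (anyDuplicated(ft$subject_id)) stop("duplicate subject_id in cohort")
  rownames(ft) <- NULL
  ft
}

#' Dense scale sweep of regional texture features
#'
#' Repeats the feature extraction over a dense grid of sigma values, for
#' studying how regional significance varies with the filter scale.
#'
#' @inheritParams extract_cohort_features
#' @param sigma_grid Strictly increasing sigma values in mm.
#' @param long If `TRUE` (default) return a long-format data frame with
#'   columns `subject_id`, `region`, `sigma_mm`, `quantifier`, `value`;
#'   otherwise the wide feature table.
#' @return Long or wide scale-sweep table.
#' @export
scale_sweep <- function(volumes, sigma_grid, n = NULL, long = TRUE, ...) {
  sigma_grid <- .validate_scales(sigma_grid)
  wide <- extract_cohort_features(volumes, n = n, scales = sigma_grid, ...)
  if (!long) return(wide)
  info <- parse_feature_names(names(wide)[-1])
  out <- data.frame(
    subject_id = rep(wide$subject_id, times = nrow(info)),
    region = rep(info$region, each = nrow(wide)),
    sigma_mm = rep(info$sigma_mm, each = nrow(wide)),
    quantifier = rep(info$quantifier, each = nrow(wide)),
    value = as.vector(as.matrix(wide[, -1])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
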