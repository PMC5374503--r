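#' Phantom region specification
#'
#' Declarative description of one synthetic region: a sphere or an
#' axis-aligned box placed on the voxel grid. Regions must be pairwise
#' disjoint and lie fully inside the grid.
#'
#' @param label_id Positive integer label.
#' @param region_name Region name (unique within a phantom).
#' @param shape `"sphere"` or `"box"`.
#' @param center Voxel coordinates of the center (length 3, 1-based).
#' @param size Sphere radius, or box half-widths (length 1 or 3), in voxels.
#' @return A `phantom_region` list.
#' @export
phantom_region <- function(label_id, region_name, shape = c("sphere", "box"),
                           center, size) {
  shape <- match.arg(shape)
  if (label_id <= 0 || label_id != round(label_id))
    stop("label_id must be a positive integer")
  center <- as.numeric(center)
  if (length(center) != 3L) stop("center must have length 3")
  size <- as.numeric(size)
  if (shape == "box" && length(size) == 1L) size <- rep(size, 3)
  if (any(size <= 0)) stop("size must be positive")
  structure(list(label_id = as.integer(label_id),
                 region_name = as.character(region_name),
                 shape = shape, center = center, size = size),
            class = "phantom_region")
}

#' Regional texture parameters for the Gaussian-random-field phantom
#'
#' A region's synthetic intensity field is mu + tau * Z_ell, where Z_ell is
#' a unit-marginal-variance Gaussian random field with correlation length
#' `ell`. The correlation length is defined as the lag at which the field's
#' autocorrelation falls to 1/e; it is realized by smoothing white noise
#' with a Gaussian kernel of standard deviation ell/2 (the autocorrelation
#' of such a field is exp(-r^2 / ell^2)) and re-standardizing to unit
#' marginal variance, so amplitude and correlation length are decoupled.
#' `ell = 0` gives voxel-wise white noise. An optional second, independent
#' noise component (`tau2`, `ell2`) allows broadband fields carrying
#' structure at two scales (e.g. fine acquisition noise plus mesoscale
#' tissue heterogeneity).
#'
#' @param mu Mean intensity.
#' @param tau Noise amplitude (marginal standard deviation), >= 0.
#' @param ell Correlation length in mm (1/e autocorrelation lag), >= 0.
#' @param tau2,ell2 Optional second component (defaults 0: off).
#' @return A `texture_params` list.
#' @export
texture_params <- function(mu = 0, tau = 0, ell = 0, tau2 = 0, ell2 = 0) {
  vals <- c(mu = mu, tau = tau, ell = ell, tau2 = tau2, ell2 = ell2)
  if (any(!is.finite(vals))) stop("texture parameters must be finite")
  if (tau < 0 || ell < 0 || tau2 < 0 || ell2 < 0)
    stop("tau, ell, tau2, ell2 must be >= 0")
  structure(as.list(vals), class = "texture_params")
}

#' Build a label volume from phantom region specs
#'
#' @param grid_dim Grid dimensions (length 3).
#' @param regions List of [phantom_region()] specs.
#' @return 3-D integer label array; background is 0. Overlapping regions or
#'   regions exceeding the grid raise an error.
#' @export
build_label_volume <- function(grid_dim, regions) {
  grid_dim <- as.integer(grid_dim)
  if (length(grid_dim) != 3L || any(grid_dim < 1))
    stop("grid_dim must be 3 positive integers")
  lab <- array(0L, dim = grid_dim)
  if (!length(regions)) return(lab)
  ids <- vapply(regions, function(r) r$label_id, 1L)
  nms <- vapply(regions, function(r) r$region_name, "")
  if (anyDuplicated(ids) || anyDuplicated(nms))
    stop("phantom regions must have unique label ids and names")
  co <- list(seq_len(grid_dim[1]), seq_len(grid_dim[2]), seq_len(grid_dim[3]))
  for (r in regions) {
    if (r$shape == "sphere") {
      lo <- floor(r$center - r$size); hi <- ceiling(r$center + r$size)
    } else {
      lo <- floor(r$center - r$size); hi <- ceiling(r$center + r$size)
    }
    if (any(lo < 1) || any(hi > grid_dim))
      stop(sprintf("region '%s' exceeds the grid", r$region_name))
    dx2 <- lapply(1:3, function(a) (co[[a]] - r$center[a])^2)
    inside <- if (r$shape == "sphere") {
      outer(outer(dx2[[1]], dx2[[2]], `+`), dx2[[3]], `+`) <= r$size^2
    } else {
      wx <- abs(co[[1]] - r$center[1]) <= r$size[1]
      wy <- abs(co[[2]] - r$center[2]) <= r$size[2]
      wz <- abs(co[[3]] - r$center[3]) <= r$size[3]
      outer(outer(wx, wy, `&`), wz, `&`)
    }
    if (any(lab[inside] != 0L))
      stop(sprintf("region '%s' overlaps another region", r$region_name))
    lab[inside] <- r$label_id
  }
  lab
}

#' Region map corresponding to a list of phantom regions
#'
#' @param regions List of [phantom_region()] specs.
#' @return Data frame usable as `region_map` in [extract_features()].
#' @export
phantom_region_map <- function(regions) {
  validate_region_map(data.frame(
    label_id = vapply(regions, function(r) r$label_id, 1L),
    region_name = vapply(regions, function(r) r$region_name, ""),
    hemisphere = "midline"
  ))
}

## One standardized Gaussian random field: white noise smoothed at sigma_s =
## ell / 2 (mm) and re-standardized to zero mean, unit variance over the grid.
.standardized_field <- function(white, ell, spacing) {
  z <- white
  if (ell > 0) z <- .smooth_gaussian(z, spacing, ell / 2)
  (z - mean(z)) / sd(as.vector(z))
}

#' Simulate a phantom intensity volume
#'
#' Fills each labeled region with mu + tau * Z_ell (plus the optional second
#' component tau2 * Z2_ell2) according to its [texture_params()]; background
#' voxels are 0. All regions share the same underlying noise field(s) per
#' correlation length, which is harmless since regions are disjoint.
#' Deterministic given `seed`.
#'
#' @param labels 3-D integer label array.
#' @param params Named list of [texture_params()], keyed by label id (as
#'   character) or by region name when `region_map` is given. Every label
#'   present in `labels` (other than 0) must have parameters.
#' @param spacing Voxel size in mm per axis (default 1 mm isotropic).
#' @param seed Integer seed.
#' @param region_map Optional region map to translate region-name keys.
#' @return 3-D numeric intensity array.
#' @export
simulate_intensity <- function(labels, params, spacing = c(1, 1, 1),
                               seed = 1, region_map = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (!is.null(region_map)) {
    region_map <- validate_region_map(region_map)
    ix <- match(names(params), region_map$region_name)
    if (anyNA(ix)) stop("params keys not found in region_map")
    names(params) <- as.character(region_map$label_id[ix])
  }
  miss <- setdiff(as.character(present), names(params))
  if (length(miss))
    stop("missing texture params for label(s): ", paste(miss, collapse = ", "))
  set.seed(seed)
  white1 <- array(rnorm(prod(dim(labels))), dim = dim(labels))
  use2 <- any(vapply(params[as.character(present)],
                     function(p) p$tau2 > 0, TRUE))
  white2 <- if (use2) array(rnorm(prod(dim(labels))), dim = dim(labels))
  fields1 <- list(); fields2 <- list()
  out <- array(0, dim = dim(labels))
  for (id in present) {
    p <- params[[as.character(id)]]
    idx <- which(labels == id)
    v <- rep(p$mu, length(idx))
    if (p$tau > 0) {
      key <- sprintf("%.6f", p$ell)
      if (is.null(fields1[[key]]))
        fields1[[key]] <- .standardized_field(white1, p$ell, spacing)
      v <- v + p$tau * fields1[[key]][idx]
    }
    if (p$tau2 > 0) {
      key <- sprintf("%.6f", p$ell2)
      if (is.null(fields2[[key]]))
        fields2[[key]] <- .standardized_field(white2, p$ell2, spacing)
      v <- v + p$tau2 * fields2[[key]][idx]
    }
    out[idx] <- v
  }
  out
}

#' Effect specification for the phantom cohort
#'
#' Describes how one texture parameter of one region depends on a subject
#' attribute. Categorical drivers (`group`, `sex`) carry one value per
#' level; the continuous `age` driver applies a linear map
#' value = baseline + slope * (age - ref_age).
#'
#' @param region Target region name.
#' @param driver `"group"`, `"sex"` or `"age"`.
#' @param parameter `"mu"`, `"tau"`, `"ell"`, `"tau2"` or `"ell2"`.
#' @param values Named numeric vector (categorical drivers): replacement
#'   parameter value per level; levels not named keep the baseline.
#' @param slope,ref_age Linear map for the `age` driver.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(region, driver = c("group", "sex", "age"),
                        parameter = c("mu", "tau", "ell", "tau2", "ell2"),
                        values = NULL, slope = NULL, ref_age = NULL) {
  driver <- match.arg(driver)
  parameter <- match.arg(parameter)
  if (driver == "age") {
    if (is.null(slope) || is.null(ref_age) || !is.finite(slope))
      stop("age effects need finite 'slope' and 'ref_age'")
  } else {
    if (is.null(values) || is.null(names(values)) || !all(nzchar(names(values))))
      stop("categorical effects need a named 'values' vector")
  }
  structure(list(region = as.character(region), driver = driver,
                 parameter = parameter, values = values, slope = slope,
                 ref_age = ref_age),
            class = "effect_spec")
}

#' Cohort specification for the phantom generator
#'
#' @param grid_dim Grid dimensions (default 64^3, a desk-scale stand-in for
#'   a 256^3, 1 mm^3 acquisition).
#' @param spacing Voxel size in mm (default 1 mm isotropic).
#' @param n_per_group Named integer vector: subjects per group level
#'   (default `c(A = 50, B = 50)`).
#' @param sex_ratio Probability that a subject is male (default 0.5).
#' @param age_range Uniform age range in years (default `c(8, 40)`).
#' @param seed Master seed; subject attributes and per-subject noise seeds
#'   are all derived from it.
#' @param site Site label recorded in the metadata (default "phantom").
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(grid_dim = c(64, 64, 64), spacing = c(1, 1, 1),
                        n_per_group = c(A = 50, B = 50), sex_ratio = 0.5,
                        age_range = c(8, 40), seed = 1, site = "phantom") {
  if (is.null(names(n_per_group)) || any(n_per_group < 1))
    stop("n_per_group must be a named vector with >= 1 subject per group")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  if (length(age_range) != 2L || diff(age_range) < 0 || any(age_range < 0))
    stop("age_range must be a non-decreasing pair of non-negative ages")
  structure(list(grid_dim = as.integer(grid_dim),
                 spacing = as.numeric(spacing),
                 n_per_group = n_per_group, sex_ratio = sex_ratio,
                 age_range = age_range, seed = as.integer(seed),
                 site = as.character(site)),
            class = "cohort_spec")
}

#' Draw the subject metadata for a phantom cohort
#'
#' Deterministic given the spec's master seed. Draw order (frozen): subject
#' sexes, then ages, then per-subject noise seeds, all from one stream
#' seeded with `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Metadata data frame with columns `subject_id`, `group`, `sex`,
#'   `age`, `site`, `noise_seed`.
#' @export
phantom_metadata <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- sum(spec$n_per_group)
  set.seed(spec$seed)
  sex <- ifelse(runif(n) < spec$sex_ratio, "M", "F")
  age <- runif(n, spec$age_range[1], spec$age_range[2])
  noise_seed <- sample.int(.Machine$integer.max, n)
  md <- data.frame(
    subject_id = sprintf("phantom%04d", seq_len(n)),
    group = rep(names(spec$n_per_group), times = spec$n_per_group),
    sex = sex, age = age, site = spec$site, noise_seed = noise_seed,
    stringsAsFactors = FALSE
  )
  validate_cohort_metadata(md)
}

## Resolve one subject's per-region texture parameters from the baseline and
## the effect specs. Two effects on the same (region, parameter) conflict.
.subject_params <- function(baseline, effects, subject) {
  if (length(effects)) {
    keys <- vapply(effects, function(e) paste(e$region, e$parameter), "")
    if (anyDuplicated(keys))
      stop("contradictory effects on one (region, parameter)")
  }
  params <- baseline
  for (e in effects) {
    if (!e$region %in% names(params))
      stop(sprintf("effect targets unknown region '%s'", e$region))
    p <- params[[e$region]]
    if (e$driver == "age") {
      p[[e$parameter]] <- p[[e$parameter]] + e$slope * (subject$age - e$ref_age)
    } else {
      lev <- as.character(subject[[e$driver]])
      if (lev %in% names(e$values)) p[[e$parameter]] <- unname(e$values[lev])
    }
    if (p[[e$parameter]] < 0 && e$parameter != "mu")
      stop("effect drives a non-negative parameter below zero")
    params[[e$region]] <- p
  }
  params
}

#' Simulate one phantom subject
#'
#' @param labels Shared 3-D label array.
#' @param region_map Region map matching `labels`.
#' @param baseline Named list of [texture_params()], keyed by region name.
#' @param effects List of [effect_spec()] (may be empty).
#' @param subject One metadata row (with `subject_id`, `group`, `sex`,
#'   `age`, `noise_seed`).
#' @param spacing Voxel spacing in mm.
#' @return A [labeled_volume()].
#' @export
simulate_subject <- function(labels, region_map, baseline, effects, subject,
                             spacing = c(1, 1, 1)) {
  params <- .subject_params(baseline, effects, subject)
  img <- simulate_intensity(labels, params, spacing = spacing,
                            seed = subject$noise_seed,
                            region_map = region_map)
  labeled_volume(img, labels, spacing = spacing,
                 subject_id = subject$subject_id)
}

#' Simulate a phantom cohort
#'
#' Generates the shared label grid, the subject metadata, and either a list
#' of volumes (`materialize = TRUE`) or a streaming volume source (a
#' function of the subject index), which keeps memory flat for large
#' cohorts. Any relabeling of an effect-free cohort is distributionally
#' identical (exchangeability), which is what makes null phantoms usable
#' for type-I-error calibration.
#'
#' @param spec A [cohort_spec()].
#' @param regions List of [phantom_region()] specs.
#' @param baseline Named list of [texture_params()] keyed by region name;
#'   a single `texture_params` is recycled to all regions.
#' @param effects List of [effect_spec()] (default none: a null cohort).
#' @param materialize If `TRUE` return all volumes as a list; otherwise
#'   return a `volume_source` function.
#' @return List with `metadata`, `labels`, `region_map`, and either
#'   `volumes` or `volume_source`.
#' @export
simulate_cohort <- function(spec, regions, baseline, effects = list(),
                            materialize = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- build_label_volume(spec$grid_dim, regions)
  map <- phantom_region_map(regions)
  if (inherits(baseline, "texture_params")) {
    baseline <- stats::setNames(
      rep(list(baseline), nrow(map)), map$region_name)
  }
  miss <- setdiff(map$region_name, names(baseline))
  if (length(miss))
    stop("baseline params missing for region(s): ",
         paste(miss, collapse = ", "))
  md <- phantom_metadata(spec)
  src <- function(i) {
    simulate_subject(labels, map, baseline, effects, md[i, , drop = FALSE],
                     spacing = spec$spacing)
  }
  out <- list(metadata = md, labels = labels, region_map = map)
  if (materialize) {
    out$volumes <- lapply(seq_len(nrow(md)), src)
  } else {
    out$volume_source <- src
  }
  out
}
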