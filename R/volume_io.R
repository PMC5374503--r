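#' Labeled volume: a co-registered intensity grid and integer label grid
#'
#' Container for one subject's skull-stripped intensity volume together with
#' its region parcellation. The two grids must have identical dimensions and
#' are assumed co-registered voxel-for-voxel, so all downstream computation
#' works in voxel indices; no affine/world-space geometry is used. Label 0 is
#' reserved for background (non-brain or unlabeled tissue).
#'
#' @param intensity 3-D numeric array of image intensities (arbitrary units).
#' @param labels 3-D array of non-negative integer region labels, same shape
#'   as `intensity`. May be stored as doubles (a common NIfTI dialect) but
#'   every value must be an exactly representable non-negative integer.
#' @param spacing Numeric vector of length 3, voxel size in mm per axis; all
#'   components must be positive.
#' @param subject_id Character scalar identifying the subject.
#'
#' @return An object of class `labeled_volume`: a list with elements
#'   `intensity` (double array), `labels` (integer array), `spacing`,
#'   and `subject_id`.
#' @export
labeled_volume <- function(intensity, labels, spacing = c(1, 1, 1),
                           subject_id = "subject") {
  intensity <- as.array(intensity)
  labels <- as.array(labels)
  if (length(dim(intensity)) != 3L || length(dim(labels)) != 3L)
    stop("intensity and labels must be 3-D arrays")
  if (!identical(dim(intensity), dim(labels)))
    stop(sprintf("shape mismatch: intensity %s vs labels %s",
                 paste(dim(intensity), collapse = "x"),
                 paste(dim(labels), collapse = "x")))
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel sizes in mm")
  lv <- as.vector(labels)
  if (anyNA(lv) || any(lv < 0) || any(lv != round(lv)))
    stop("labels must be non-negative integers (label 0 = background)")
  storage.mode(intensity) <- "double"
  lab <- array(as.integer(round(lv)), dim = dim(labels))
  structure(
    list(intensity = intensity, labels = lab, spacing = spacing,
         subject_id = as.character(subject_id)[1]),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> subject '%s', grid %s, spacing %s mm, %d regions\n",
              x$subject_id, paste(dim(x$intensity), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Read a labeled volume from a pair of NIfTI files
#'
#' Reads an intensity volume and its co-registered label volume (for example
#' FreeSurfer's `brain` and `aseg` outputs converted to NIfTI) and validates
#' them as a [labeled_volume()]. Voxel spacing is taken from the intensity
#' image header.
#'
#' @param intensity_path Path to the intensity NIfTI file (.nii or .nii.gz).
#' @param labels_path Path to the label NIfTI file, same grid.
#' @param subject_id Subject identifier; defaults to the intensity file name
#'   without extensions.
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(intensity_path, labels_path,
                                subject_id = NULL) {
  img <- RNifti::readNifti(intensity_path)
  lab <- RNifti::readNifti(labels_path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(intensity_path))
  spacing <- RNifti::pixdim(img)[1:3]
  labeled_volume(intensity = array(as.numeric(img), dim = dim(img)),
                 labels = array(as.numeric(lab), dim = dim(lab)),
                 spacing = spacing, subject_id = subject_id)
}

#' Write a labeled volume to a pair of NIfTI files
#'
#' @param volume A [labeled_volume()].
#' @param intensity_path,labels_path Output NIfTI paths (.nii or .nii.gz).
#' @return Invisibly, the two paths.
#' @export
write_labeled_volume <- function(volume, intensity_path, labels_path) {
  stopifnot(inherits(volume, "labeled_volume"))
  img <- RNifti::asNifti(volume$intensity)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, intensity_path)
  lab <- RNifti::asNifti(array(as.double(volume$labels),
                               dim = dim(volume$labels)))
  RNifti::pixdim(lab) <- volume$spacing
  RNifti::writeNifti(lab, labels_path)
  invisible(c(intensity_path, labels_path))
}

#' Default sub-cortical region map (31 regions)
#'
#' The default parcellation covers 31 prominent sub-cortical structures with
#' their standard FreeSurfer `aseg` label ids: ten bilateral pairs
#' (cerebellum white matter, thalamus proper, caudate, putamen, pallidum,
#' hippocampus, amygdala, accumbens area, choroid plexus, vessel), the
#' lateral ventricles, and midline structures (brain stem, CSF, 3rd and 4th
#' ventricles, and the five corpus callosum sub-regions). The exact region
#' list is configurable: any data frame with unique `label_id` and
#' `region_name` columns is accepted by the extraction functions.
#'
#' @return A data frame with columns `label_id`, `region_name`,
#'   `hemisphere` (`left`, `right`, or `midline`); 31 rows.
#' @export
default_region_map <- function() {
  pairs <- data.frame(
    name = c("Cerebellum-White-Matter", "Thalamus-Proper", "Caudate",
             "Putamen", "Pallidum", "Hippocampus", "Amygdala",
             "Accumbens-area", "choroid-plexus", "vessel",
             "Lateral-Ventricle"),
    left = c(7L, 10L, 11L, 12L, 13L, 17L, 18L, 26L, 31L, 30L, 4L),
    right = c(46L, 49L, 50L, 51L, 52L, 53L, 54L, 58L, 63L, 62L, 43L)
  )
  bilateral <- data.frame(
    label_id = c(pairs$left, pairs$right),
    region_name = c(paste0("Left-", pairs$name), paste0("Right-", pairs$name)),
    hemisphere = rep(c("left", "right"), each = nrow(pairs))
  )
  midline <- data.frame(
    label_id = c(16L, 24L, 14L, 15L, 251L, 252L, 253L, 254L, 255L),
    region_name = c("Brain-Stem", "CSF", "3rd-Ventricle", "4th-Ventricle",
                    "CC_Posterior", "CC_Mid_Posterior", "CC_Central",
                    "CC_Mid_Anterior", "CC_Anterior"),
    hemisphere = "midline"
  )
  map <- rbind(bilateral, midline)
  validate_region_map(map)
}

#' Validate a region map
#'
#' @param map Data frame with columns `label_id` (unique positive integers)
#'   and `region_name` (unique strings); an optional `hemisphere` column is
#'   carried through.
#' @return The validated map, with `label_id` coerced to integer.
#' @export
validate_region_map <- function(map) {
  if (!is.data.frame(map) || !all(c("label_id", "region_name") %in% names(map)))
    stop("region map needs columns 'label_id' and 'region_name'")
  if (any(map$label_id <= 0) || any(map$label_id != round(map$label_id)))
    stop("label_id must be positive integers (0 is reserved for background)")
  if (anyDuplicated(map$label_id)) stop("duplicate label_id in region map")
  if (anyDuplicated(map$region_name)) stop("duplicate region_name in region map")
  map$label_id <- as.integer(map$label_id)
  map$region_name <- as.character(map$region_name)
  rownames(map) <- NULL
  map
}

#' Read a cohort metadata table
#'
#' @param path CSV file with one row per subject and at least the columns
#'   `subject_id`, `group`, `sex`, `age`, `site`.
#' @return Validated data frame.
#' @export
read_cohort_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_metadata(md)
}

#' Validate cohort metadata
#'
#' @param metadata Data frame with columns `subject_id`, `group`, `sex`,
#'   `age`, `site`. Subject ids must be unique and ages non-negative.
#' @return The validated data frame.
#' @export
validate_cohort_metadata <- function(metadata) {
  need <- c("subject_id", "group", "sex", "age", "site")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$subject_id))
    stop("duplicate subject_id in metadata")
  if (any(!is.finite(metadata$age)) || any(metadata$age < 0))
    stop("age must be non-negative and finite")
  metadata$subject_id <- as.character(metadata$subject_id)
  rownames(metadata) <- NULL
  metadata
}

#' Remove quality-assessment failures from a cohort
#'
#' Drops the listed subjects from the metadata table, mirroring a QA-based
#' exclusion list (e.g. volumes with visible segmentation errors). Listed ids
#' that are not present in the cohort produce a warning, not an error.
#'
#' @param metadata Cohort metadata data frame (see
#'   [validate_cohort_metadata()]).
#' @param excluded_ids Character vector of subject ids to remove.
#' @return The metadata with excluded subjects removed.
#' @export
apply_exclusions <- function(metadata, excluded_ids) {
  excluded_ids <- as.character(excluded_ids)
  absent <- setdiff(excluded_ids, metadata$subject_id)
  if (length(absent))
    warning(sprintf("%d excluded id(s) not present in cohort: %s",
                    length(absent), paste(absent, collapse = ", ")))
  keep <- !(metadata$subject_id %in% excluded_ids)
  message(sprintf("apply_exclusions: removed %d of %d subjects",
                  sum(!keep), nrow(metadata)))
  out <- metadata[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an exclusion list (one subject id per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Text file path.
#' @return Character vector of subject ids.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

## Feature-table serialization ----------------------------------------------
## Columns are named region__sigma__quantifier with sigma printed in mm at
## three decimals (e.g. "Left-Hippocampus__0.500__E"), giving stable,
## parseable identifiers for the full 279-feature layout.

#' Build a feature column name
#' @param region Region name(s).
#' @param sigma_mm Filter scale(s) in mm.
#' @param quantifier Quantifier code(s): "A", "SD" or "E".
#' @return Character vector of column names.
#' @export
feature_name <- function(region, sigma_mm, quantifier) {
  paste(region, sprintf("%.3f", sigma_mm), quantifier, sep = "__")
}

#' Parse feature column names
#'
#' @param x Character vector of `region__sigma__quantifier` names.
#' @return Data frame with columns `feature`, `region`, `sigma_mm`,
#'   `quantifier`.
#' @export
parse_feature_names <- function(x) {
  parts <- strsplit(x, "__", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("unparseable feature name(s): ", paste(x[bad], collapse = ", "))
  sig <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2])), 1.0)
  qua <- vapply(parts, `[`, "", 3)
  if (anyNA(sig) || !all(qua %in% c("A", "SD", "E")))
    stop("feature names must follow region__sigma__quantifier with ",
         "quantifier in {A, SD, E}")
  data.frame(feature = x,
             region = vapply(parts, `[`, "", 1),
             sigma_mm = sig,
             quantifier = qua,
             stringsAsFactors = FALSE)
}

#' Write a feature table to CSV
#'
#' One row per subject, first column `subject_id`, remaining columns named
#' `region__sigma__quantifier`. Values are written with full double
#' precision (15 significant digits) so a write/read round trip preserves
#' features to at least 1e-12 relative; missing features become empty cells.
#'
#' @param features Feature table data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), names(features)[1] == "subject_id")
  parse_feature_names(names(features)[-1])  # validate naming scheme
  write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_feature_table()].
#' @return Feature table data frame; empty cells become `NA`.
#' @export
read_feature_table <- function(path) {
  ft <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 na.strings = "")
  if (names(ft)[1] != "subject_id")
    stop("feature table must start with a subject_id column")
  if (anyDuplicated(ft$subject_id))
    stop("duplicate subject_id rows in feature table")
  parse_feature_names(names(ft)[-1])
  ft$subject_id <- as.character(ft$subject_id)
  for (j in seq_along(ft)[-1]) ft[[j]] <- as.numeric(ft[[j]])
  ft
}
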