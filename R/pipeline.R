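#' Export a heatmap matrix of -log10 raw p-values
#'
#' Writes the per-region significance heatmap in the layout used for the
#' figures: regions as rows, (scale x quantifier) combinations as columns,
#' cell values -log10 of the raw p-value, plus a parallel 0/1 mask marking
#' the features that stay significant after Holm-Bonferroni correction.
#'
#' @param results Result table from [run_group_analysis()] or
#'   [run_correlation_analysis()].
#' @param values_path CSV path for the -log10 p matrix.
#' @param mask_path Optional CSV path for the significance mask.
#' @return Invisibly, the heatmap matrix (data frame).
#' @export
write_heatmap_csv <- function(results, values_path, mask_path = NULL) {
  need <- c("region", "sigma_mm", "quantifier", "p_raw", "significant")
  stopifnot(all(need %in% names(results)))
  regions <- unique(results$region)
  cols <- unique(results[, c("sigma_mm", "quantifier")])
  cols <- cols[order(cols$sigma_mm, match(cols$quantifier, c("A", "SD", "E"))), ]
  col_names <- sprintf("%.3fmm_%s", cols$sigma_mm, cols$quantifier)
  val <- mask <- matrix(NA_real_, length(regions), nrow(cols),
                        dimnames = list(regions, col_names))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    cn <- sprintf("%.3fmm_%s", r$sigma_mm, r$quantifier)
    val[r$region, cn] <- -log10(r$p_raw)
    mask[r$region, cn] <- as.numeric(r$significant)
  }
  vdf <- data.frame(region = rownames(val), val, check.names = FALSE)
  write.csv(vdf, values_path, row.names = FALSE)
  if (!is.null(mask_path)) {
    mdf <- data.frame(region = rownames(mask), mask, check.names = FALSE)
    write.csv(mdf, mask_path, row.names = FALSE)
  }
  invisible(vdf)
}

.write_manifest <- function(path, manifest) {
  # flat key: value text manifest; deterministic ordering
  keys <- sort(names(manifest))
  lines <- vapply(keys, function(k) {
    sprintf("%s: %s", k, paste(format(manifest[[k]], digits = 15),
                               collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline: volumes (or phantom) to corrected result tables
#'
#' Orchestrates exclusion, feature extraction, the selected statistical
#' analysis, Holm-Bonferroni correction, and CSV export. The feature table
#' is extracted once and written next to the results, so repeated calls for
#' the other analysis modes can pass it back in via `features` instead of
#' re-filtering the volumes. Rerunning with the same inputs and seed
#' reproduces all outputs exactly; a plain-text manifest records the
#' configuration and seeds.
#'
#' @param inputs Either the output of [simulate_cohort()] or a list with
#'   elements `metadata` plus one of `volumes` (list of [labeled_volume()])
#'   or `volume_source` (function of the subject index), and optionally
#'   `region_map`.
#' @param mode `"group"` (two-group comparison on `group`), `"sex"`
#'   (two-group comparison on `sex`) or `"age"` (correlation analysis).
#' @param output_dir Directory for the output CSVs; created if missing.
#'   `NULL` (default) skips all file output.
#' @param features Optional pre-computed feature table (skips extraction).
#' @param region_map Region map; defaults to the one in `inputs`, else
#'   [default_region_map()].
#' @param scales Filter scales in mm (default [default_scales()]).
#' @param n_bins Entropy histogram intervals (default 256).
#' @param exclusions Character vector of subject ids to exclude (QA
#'   failures), or a path to an exclusion list file.
#' @param control_group For `sex` and `age` modes, restrict the cohort to
#'   this diagnosis group before testing (the usual design: sex and age
#'   effects are assessed in controls). Default `NULL`: no restriction.
#' @param n_permutations,seed,tie_rule,alpha Passed to the analysis
#'   functions.
#' @param bootstrap,n_bootstrap,size_per_group Balanced-bootstrap Fisher
#'   settings for the group modes.
#' @return List with `features`, `results`, `metadata` (post-exclusion,
#'   post-restriction), `mode`, and `manifest`.
#' @export
run_full <- function(inputs, mode = c("group", "sex", "age"),
                     output_dir = NULL, features = NULL, region_map = NULL,
                     scales = default_scales(), n_bins = 256,
                     exclusions = character(0), control_group = NULL,
                     n_permutations = 100000, seed = 1,
                     tie_rule = c("ge", "gt"), alpha = 0.05,
                     bootstrap = FALSE, n_bootstrap = 100,
                     size_per_group = 100) {
  mode <- match.arg(mode)
  tie_rule <- match.arg(tie_rule)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  md <- validate_cohort_metadata(inputs$metadata)
  if (length(exclusions) == 1 && file.exists(exclusions))
    exclusions <- read_exclusion_list(exclusions)
  if (length(exclusions)) md <- apply_exclusions(md, exclusions)
  if (is.null(region_map))
    region_map <- if (!is.null(inputs$region_map)) inputs$region_map
      else default_region_map()
  if (is.null(features)) {
    keep_id <- md$subject_id
    if (!is.null(inputs$volumes)) {
      all_id <- vapply(inputs$volumes, function(v) v$subject_id, "")
      vols <- inputs$volumes[all_id %in% keep_id]
      features <- extract_cohort_features(vols, region_map = region_map,
                                          scales = scales, n_bins = n_bins)
    } else if (!is.null(inputs$volume_source)) {
      all_md <- validate_cohort_metadata(inputs$metadata)
      sel <- which(all_md$subject_id %in% keep_id)
      features <- extract_cohort_features(
        function(i) inputs$volume_source(sel[i]), n = length(sel),
        region_map = region_map, scales = scales, n_bins = n_bins)
    } else {
      stop("inputs must provide volumes, a volume_source, or features")
    }
  } else {
    features <- features[features$subject_id %in% md$subject_id, ,
                         drop = FALSE]
  }
  md_an <- md
  if (mode %in% c("sex", "age") && !is.null(control_group)) {
    md_an <- md[md$group == control_group, , drop = FALSE]
  }
  feat_an <- features[features$subject_id %in% md_an$subject_id, ,
                      drop = FALSE]
  results <- switch(mode,
    group = run_group_analysis(feat_an, md_an, grouping = "group",
                               n_permutations = n_permutations, seed = seed,
                               tie_rule = tie_rule, alpha = alpha,
                               bootstrap = bootstrap,
                               n_bootstrap = n_bootstrap,
                               size_per_group = size_per_group),
    sex = run_group_analysis(feat_an, md_an, grouping = "sex",
                             n_permutations = n_permutations, seed = seed,
                             tie_rule = tie_rule, alpha = alpha,
                             bootstrap = bootstrap,
                             n_bootstrap = n_bootstrap,
                             size_per_group = size_per_group),
    age = run_correlation_analysis(feat_an, md_an, covariate = "age",
                                   n_permutations = n_permutations,
                                   seed = seed, alpha = alpha,
                                   tie_rule = tie_rule)
  )
  manifest <- list(
    mode = mode, seed = seed, n_permutations = n_permutations,
    alpha = alpha, tie_rule = tie_rule, scales = scales, n_bins = n_bins,
    n_subjects = nrow(md_an), n_features = nrow(results),
    n_excluded = length(exclusions),
    package_version = as.character(utils::packageVersion("logradiomics"))
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(features, file.path(output_dir, "features.csv"))
    write.csv(results, file.path(output_dir,
                                 sprintf("results_%s.csv", mode)),
              row.names = FALSE)
    write_heatmap_csv(results,
                      file.path(output_dir,
                                sprintf("heatmap_%s_neglog10p.csv", mode)),
                      file.path(output_dir,
                                sprintf("heatmap_%s_sigmask.csv", mode)))
    .write_manifest(file.path(output_dir, sprintf("manifest_%s.txt", mode)),
                    manifest)
  }
  list(features = features, results = results, metadata = md_an,
       mode = mode, manifest = manifest)
}

#' Group-significance curves across a dense scale sweep
#'
#' Extracts features over `sigma_grid`, runs the two-group permutation
#' analysis over all (region, sigma, quantifier) features at once (one Holm
#' family), and returns the result table ordered by region, quantifier and
#' sigma, from which -log10(p) versus sigma curves can be read directly.
#'
#' @param inputs As in [run_full()].
#' @param sigma_grid Strictly increasing sigma values in mm.
#' @param grouping Metadata column with the two-level labels.
#' @param ... Passed to [run_group_analysis()].
#' @return Result table with one row per (region, sigma, quantifier).
#' @export
sweep_group_significance <- function(inputs, sigma_grid, grouping = "group",
                                     ...) {
  md <- validate_cohort_metadata(inputs$metadata)
  region_map <- if (!is.null(inputs$region_map)) inputs$region_map
    else default_region_map()
  vols <- if (!is.null(inputs$volumes)) inputs$volumes
    else inputs$volume_source
  n <- if (is.function(vols)) nrow(md) else NULL
  wide <- scale_sweep(vols, sigma_grid, n = n, long = FALSE,
                      region_map = region_map)
  res <- run_group_analysis(wide, md, grouping = grouping, ...)
  res[order(res$region, res$quantifier, res$sigma_mm), ]
}
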