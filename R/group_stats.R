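#' Absolute difference of group medians (ABM)
#'
#' The test statistic for the two-group permutation analysis: the absolute
#' difference between the two group medians, with the median of an even-sized
#' group taken as the mean of the two central order statistics. Missing
#' values are dropped before the medians are computed.
#'
#' @param values_a,values_b Numeric vectors of feature values for the two
#'   groups.
#' @return Non-negative scalar.
#' @export
abm_statistic <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b))
    stop("both groups must be non-empty after missing-value removal")
  abs(median(a) - median(b))
}

.two_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop(sprintf("exactly two group labels required, got %d", length(lev)))
  if (!all(table(groups) >= 1L)) stop("one group is empty")
  # canonical subject order (group, then value) so Monte-Carlo results do
  # not depend on the row order of the input table
  ord <- order(groups, values)
  list(values = values[ord], in_a = groups[ord] == lev[1], levels = lev)
}

#' Monte-Carlo permutation test on the absolute difference of medians
#'
#' Draws `n_permutations` uniform random relabelings of the subjects
#' (preserving the two group sizes) and compares the permuted ABM statistic
#' against the observed one. Under the default `tie_rule = "ge"` counting is
#' tie-inclusive with the +1 validity correction,
#' p = (#\{ABM_perm >= ABM_obs\} + 1) / (N + 1), which cannot be zero;
#' `tie_rule = "gt"` uses strict counting without the correction
#' (p = #\{ABM_perm > ABM_obs\} / N), the literal "percentage of permutations
#' greater than the observed" rule, for replication.
#'
#' @param values Numeric feature values, one per subject.
#' @param groups Two-level group labels, same length; pairs with missing
#'   values or labels are dropped.
#' @param n_permutations Number of random permutations (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @param tie_rule `"ge"` (default) or `"gt"`, see Details.
#' @return List with elements `p` (the permutation p-value), `abm_obs`
#'   (observed statistic), `n_exceed`, `n_permutations`, `tie_rule`.
#' @export
permutation_test <- function(values, groups, n_permutations = 100000,
                             seed = NULL, tie_rule = c("ge", "gt")) {
  tie_rule <- match.arg(tie_rule)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  g <- .two_groups(values, groups)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_perm_abm(g$values, g$in_a, as.integer(n_permutations),
                      tie_ge = tie_rule == "ge",
                      add_one = tie_rule == "ge")
  list(p = res$p, abm_obs = res$abm_obs, n_exceed = res$n_exceed,
       n_permutations = as.integer(n_permutations), tie_rule = tie_rule)
}

#' Exact permutation test by exhaustive enumeration
#'
#' Enumerates every assignment of subjects to the two groups that preserves
#' the group sizes and reports the tie-inclusive exact p-value, the fraction
#' of assignments whose ABM is at least the observed one (the identity
#' assignment is included, so p >= 1/choose(n, n_a)). Used as the oracle for
#' [permutation_test()]; limited to small cohorts.
#'
#' @inheritParams permutation_test
#' @param max_n Enumeration bound on the total number of subjects
#'   (default 12).
#' @return List with `p`, `abm_obs` and `n_assignments`.
#' @export
exhaustive_permutation_test <- function(values, groups, max_n = 12) {
  g <- .two_groups(values, groups)
  n <- length(g$values)
  if (n > max_n)
    stop(sprintf("n = %d exceeds the enumeration bound of %d", n, max_n))
  n_a <- sum(g$in_a)
  obs <- abm_statistic(g$values[g$in_a], g$values[!g$in_a])
  sets <- utils::combn(n, n_a)
  abms <- apply(sets, 2, function(ix) {
    abm_statistic(g$values[ix], g$values[-ix])
  })
  list(p = mean(abms >= obs), abm_obs = obs, n_assignments = ncol(sets))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()]: exact enumeration when both
#' groups are small and tie-free, otherwise the tie-corrected normal
#' approximation. Degenerate inputs for which the approximation is undefined
#' (e.g. all values tied) are reported as p = 1.
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  p <- suppressWarnings(
    tryCatch(wilcox.test(a, b, exact = NULL, correct = TRUE)$p.value,
             error = function(e) NaN))
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

#' Combine p-values with Fisher's method
#'
#' X = -2 sum(log p_i) referred to a chi-square distribution with 2k degrees
#' of freedom. Zero p-values are clamped to the smallest positive double
#' with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return List with `chi2` (the statistic), `df`, and `p` (the combined
#'   p-value).
#' @export
fisher_combine <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("zero p-value(s) clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  k <- length(p)
  list(chi2 = x, df = 2 * k, p = pchisq(x, df = 2 * k, lower.tail = FALSE))
}

#' Balanced-bootstrap Wilcoxon analysis aggregated by Fisher's method
#'
#' Draws `n_samples` balanced resamples (a fixed number of subjects from
#' each group, neutralizing group-size imbalance), applies the Wilcoxon
#' rank-sum test to each resample, and combines the resulting p-values with
#' Fisher's method. Because the resamples overlap, the combined p-values are
#' overly optimistic and are meaningful only for ranking features relative
#' to one another, not as calibrated significance levels.
#'
#' @param values Numeric feature values, one per subject.
#' @param groups Two-level group labels.
#' @param n_samples Number of bootstrap resamples (default 100).
#' @param size_per_group Subjects drawn from each group per resample
#'   (default 100).
#' @param replace Sample with replacement (default `TRUE`, the bootstrap
#'   reading); `FALSE` gives without-replacement subsampling and then
#'   requires `size_per_group` at most the smaller group size.
#' @param seed Optional integer seed.
#' @return List with `chi2`, `df`, `p_fisher` and the vector `p_samples`.
#' @export
balanced_bootstrap_fisher <- function(values, groups, n_samples = 100,
                                      size_per_group = 100, replace = TRUE,
                                      seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  g <- .two_groups(values, groups)
  a <- g$values[g$in_a]   # already in canonical (sorted) order
  b <- g$values[!g$in_a]
  if (!replace && size_per_group > min(length(a), length(b)))
    stop("size_per_group exceeds a group size with replace = FALSE")
  if (!is.null(seed)) set.seed(seed)
  ps <- vapply(seq_len(n_samples), function(i) {
    ra <- sample(a, size_per_group, replace = replace)
    rb <- sample(b, size_per_group, replace = replace)
    rank_sum_test(ra, rb)
  }, 1.0)
  fc <- fisher_combine(ps)
  list(chi2 = fc$chi2, df = fc$df, p_fisher = fc$p, p_samples = ps)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusted p-values p~_(i) = min(1, max_{j <= i} (m - j + 1) p_(j)) in
#' ascending order of raw p, mapped back to the input order. Missing entries
#' are excluded from the family size m and returned as `NA`.
#'
#' @param p Numeric vector of raw p-values in [0, 1] (NA allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @export
holm_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out[ok] <- p.adjust(p[ok], method = "holm")
  out
}

.feature_seeds <- function(feature_names, seed) {
  # one substream per feature, keyed by sorted feature name so results do
  # not depend on column order
  ord <- order(feature_names)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(feature_names))
  seeds[order(ord)]
}

#' Two-group analysis of a feature table
#'
#' Runs the ABM permutation test for every feature column, applies the
#' Holm-Bonferroni correction simultaneously over all analyzed features, and
#' (optionally) adds the balanced-bootstrap Fisher aggregate. With the
#' default 31-region, 3-scale, 3-quantifier layout this is a family of 279
#' hypothesis tests. Missing feature values are dropped per feature;
#' features observed on fewer than `low_n` subjects in either group are
#' flagged `low_n` but still reported.
#'
#' @param features Feature table: `subject_id` column plus numeric feature
#'   columns named `region__sigma__quantifier`.
#' @param metadata Cohort metadata containing `subject_id` and the grouping
#'   column.
#' @param grouping Name of the metadata column holding the two-level group
#'   labels (e.g. `"group"` or `"sex"`).
#' @param n_permutations Permutations per feature (default 100000).
#' @param seed Master seed; per-feature substreams are derived from it so
#'   each feature's p-value is reproducible and independent of column order.
#' @param tie_rule Counting rule for [permutation_test()].
#' @param alpha Family-wise significance level (default 0.05).
#' @param bootstrap If `TRUE`, add Fisher aggregates from
#'   [balanced_bootstrap_fisher()].
#' @param n_bootstrap,size_per_group,bootstrap_replace Bootstrap settings.
#' @param low_n Minimum per-group subject count below which a feature is
#'   flagged (default 10).
#' @return Data frame with one row per feature: `feature`, `region`,
#'   `sigma_mm`, `quantifier`, `n_a`, `n_b`, `abm`, `p_raw`, `p_holm`,
#'   `significant`, `low_n`, and when `bootstrap` is on, `fisher_chi2` and
#'   `p_fisher`.
#' @export
run_group_analysis <- function(features, metadata, grouping = "group",
                               n_permutations = 100000, seed = 1,
                               tie_rule = c("ge", "gt"), alpha = 0.05,
                               bootstrap = FALSE, n_bootstrap = 100,
                               size_per_group = 100,
                               bootstrap_replace = TRUE, low_n = 10) {
  tie_rule <- match.arg(tie_rule)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(is.data.frame(features), names(features)[1] == "subject_id")
  if (!grouping %in% names(metadata))
    stop(sprintf("metadata has no '%s' column", grouping))
  m <- match(features$subject_id, metadata$subject_id)
  if (anyNA(m)) stop("feature table contains subjects absent from metadata")
  grp <- as.character(metadata[[grouping]][m])
  lev <- sort(unique(grp[!is.na(grp)]))
  if (length(lev) != 2L)
    stop(sprintf("grouping variable '%s' must be binary on this cohort",
                 grouping))
  if (min(table(grp)) < 2) stop("fewer than 2 subjects in one group")
  feat_names <- names(features)[-1]
  info <- parse_feature_names(feat_names)
  seeds <- .feature_seeds(feat_names, seed)
  res <- lapply(seq_along(feat_names), function(j) {
    v <- features[[feat_names[j]]]
    ok <- !is.na(v) & !is.na(grp)
    n_a <- sum(grp[ok] == lev[1]); n_b <- sum(grp[ok] == lev[2])
    if (n_a < 1 || n_b < 1)
      return(data.frame(n_a = n_a, n_b = n_b, abm = NA_real_,
                        p_raw = NA_real_))
    pt <- permutation_test(v[ok], grp[ok], n_permutations = n_permutations,
                           seed = seeds[j], tie_rule = tie_rule)
    data.frame(n_a = n_a, n_b = n_b, abm = pt$abm_obs, p_raw = pt$p)
  })
  res <- do.call(rbind, res)
  out <- cbind(info, res)
  out$p_holm <- holm_correct(out$p_raw)
  out$significant <- !is.na(out$p_holm) & out$p_holm < alpha
  out$low_n <- pmin(out$n_a, out$n_b) < low_n
  if (bootstrap) {
    bs <- lapply(seq_along(feat_names), function(j) {
      v <- features[[feat_names[j]]]
      ok <- !is.na(v) & !is.na(grp)
      set.seed(seeds[j])
      b <- balanced_bootstrap_fisher(v[ok], grp[ok], n_samples = n_bootstrap,
                                     size_per_group = size_per_group,
                                     replace = bootstrap_replace)
      data.frame(fisher_chi2 = b$chi2, p_fisher = b$p_fisher)
    })
    out <- cbind(out, do.call(rbind, bs))
  }
  rownames(out) <- NULL
  out
}
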