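#' Spearman rank correlation coefficient
#'
#' Pearson correlation of tie-averaged ranks. Returned as `NA` with a
#' warning when either variable is constant (the coefficient is undefined).
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @return Correlation in [-1, 1], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant variable: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y), method = "pearson")
}

#' Permutation p-value for a Spearman correlation
#'
#' Randomly permutes `y`, recomputes the rank correlation, and counts
#' permutations whose absolute correlation reaches the observed absolute
#' correlation (a two-sided test). The counting conventions mirror
#' [permutation_test()]: tie-inclusive with the +1 validity correction by
#' default, or the literal strict rule via `tie_rule = "gt"`.
#'
#' @inheritParams spearman_rho
#' @param n_permutations Number of permutations (default 100000).
#' @param seed Optional integer seed.
#' @param tie_rule `"ge"` (default) or `"gt"`.
#' @return List with `p`, `rho_obs`, `n_exceed`, `n_permutations`.
#' @export
correlation_permutation_p <- function(x, y, n_permutations = 100000,
                                      seed = NULL,
                                      tie_rule = c("ge", "gt")) {
  tie_rule <- match.arg(tie_rule)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant variable: permutation p undefined")
    return(list(p = NA_real_, rho_obs = NA_real_, n_exceed = NA_real_,
                n_permutations = as.integer(n_permutations)))
  }
  ord <- order(x, y)  # canonical pair order: row-order-invariant MC stream
  x <- x[ord]; y <- y[ord]
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_perm_srcc(rank(x), rank(y), as.integer(n_permutations),
                       tie_ge = tie_rule == "ge",
                       add_one = tie_rule == "ge")
  list(p = res$p, rho_obs = res$rho_obs, n_exceed = res$n_exceed,
       n_permutations = as.integer(n_permutations))
}

#' Bootstrap lower confidence bound on the absolute Spearman correlation
#'
#' Resamples the subjects with replacement, computes the absolute rank
#' correlation for each resample, and returns the empirical 5th percentile
#' of the sampled values (inverted-CDF convention: the order statistic at
#' ceil(0.05 B), i.e. the 5th smallest of 100) -- the highest value smaller
#' than 95% of the sampled correlations. Degenerate resamples in which
#' either variable is constant are skipped with a warning, up to a 20% skip
#' budget.
#'
#' @inheritParams spearman_rho
#' @param n_samples Number of bootstrap resamples (default 100).
#' @param sample_size Subjects per resample (default 100).
#' @param seed Optional integer seed.
#' @param percentile Lower-tail probability of the bound (default 0.05,
#'   a 95% lower confidence bound).
#' @return List with `ci_lower_abs`, the vector `abs_rho_samples`, and
#'   `n_skipped`.
#' @export
bootstrap_srcc_lower_bound <- function(x, y, n_samples = 100,
                                       sample_size = 100, seed = NULL,
                                       percentile = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (sample_size < 3) stop("sample_size must be >= 3")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(0)
  n_skip <- 0
  max_skip <- ceiling(0.2 * n_samples)
  while (length(vals) < n_samples) {
    ix <- sample.int(length(x), sample_size, replace = TRUE)
    if (length(unique(x[ix])) < 2 || length(unique(y[ix])) < 2) {
      n_skip <- n_skip + 1
      if (n_skip > max_skip)
        stop("too many degenerate bootstrap resamples (constant values)")
      next
    }
    vals <- c(vals, abs(cor(rank(x[ix]), rank(y[ix]))))
  }
  if (n_skip > 0)
    warning(sprintf("%d degenerate resample(s) skipped", n_skip))
  k <- max(1L, as.integer(ceiling(percentile * n_samples)))
  list(ci_lower_abs = sort(vals)[k], abs_rho_samples = vals,
       n_skipped = n_skip)
}

#' Correlation analysis of a feature table against a continuous covariate
#'
#' For every feature: the Spearman rank correlation with the covariate, a
#' two-sided permutation p-value, the Holm-Bonferroni correction applied
#' simultaneously over all analyzed features, a bootstrap 95% lower bound on
#' the absolute correlation, and a `flagged_moderate` indicator for
#' moderate-to-high correlations (|rho| > `rho_flag`, default 0.4). The flag
#' is a reporting filter, not a test: features below it still receive
#' p-values.
#'
#' @param features Feature table (`subject_id` plus feature columns).
#' @param metadata Cohort metadata containing `subject_id` and the covariate
#'   (the cohort is expected to be pre-filtered, e.g. to controls only).
#' @param covariate Name of the numeric metadata column (default `"age"`).
#' @param n_permutations Permutations per feature (default 100000).
#' @param seed Master seed; per-feature substreams as in
#'   [run_group_analysis()].
#' @param alpha Family-wise significance level (default 0.05).
#' @param rho_flag Absolute-correlation threshold for `flagged_moderate`.
#' @param n_bootstrap,bootstrap_size Bootstrap settings for the lower bound
#'   (defaults 100 resamples of 100 subjects; `bootstrap_size` is capped at
#'   the cohort size).
#' @param tie_rule Counting rule for the permutation p-values.
#' @return Data frame with one row per feature: `feature`, `region`,
#'   `sigma_mm`, `quantifier`, `n`, `rho`, `p_raw`, `p_holm`, `significant`,
#'   `ci_lower_abs`, `flagged_moderate`.
#' @export
run_correlation_analysis <- function(features, metadata, covariate = "age",
                                     n_permutations = 100000, seed = 1,
                                     alpha = 0.05, rho_flag = 0.4,
                                     n_bootstrap = 100, bootstrap_size = 100,
                                     tie_rule = c("ge", "gt")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(is.data.frame(features), names(features)[1] == "subject_id")
  if (!covariate %in% names(metadata))
    stop(sprintf("metadata has no '%s' column", covariate))
  m <- match(features$subject_id, metadata$subject_id)
  if (anyNA(m)) stop("feature table contains subjects absent from metadata")
  z <- metadata[[covariate]][m]
  if (!is.numeric(z)) stop("covariate must be numeric")
  feat_names <- names(features)[-1]
  info <- parse_feature_names(feat_names)
  seeds <- .feature_seeds(feat_names, seed)
  res <- lapply(seq_along(feat_names), function(j) {
    v <- features[[feat_names[j]]]
    ok <- !is.na(v) & !is.na(z)
    n <- sum(ok)
    if (n < 3 || length(unique(v[ok])) < 2 || length(unique(z[ok])) < 2)
      return(data.frame(n = n, rho = NA_real_, p_raw = NA_real_,
                        ci_lower_abs = NA_real_))
    rho <- spearman_rho(v[ok], z[ok])
    pp <- correlation_permutation_p(v[ok], z[ok],
                                    n_permutations = n_permutations,
                                    seed = seeds[j], tie_rule = tie_rule)
    bb <- bootstrap_srcc_lower_bound(v[ok], z[ok], n_samples = n_bootstrap,
                                     sample_size = min(bootstrap_size, n),
                                     seed = seeds[j])
    data.frame(n = n, rho = rho, p_raw = pp$p,
               ci_lower_abs = bb$ci_lower_abs)
  })
  res <- do.call(rbind, res)
  out <- cbind(info, res)
  out$p_holm <- holm_correct(out$p_raw)
  out$significant <- !is.na(out$p_holm) & out$p_holm < alpha
  out$flagged_moderate <- !is.na(out$rho) & abs(out$rho) > rho_flag
  out <- out[, c("feature", "region", "sigma_mm", "quantifier", "n", "rho",
                 "p_raw", "p_holm", "significant", "ci_lower_abs",
                 "flagged_moderate")]
  rownames(out) <- NULL
  out
}
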