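# Shared fixture builders; everything is generated in code at test time.

# Two disjoint spheres in a small grid, for io/extraction tests.
tiny_two_region_phantom <- function(grid = c(24, 24, 24)) {
  list(phantom_region(1L, "alpha", "sphere", c(7, 12, 12), 4),
       phantom_region(2L, "beta", "sphere", c(17, 12, 12), 4))
}

# A label volume containing every default-map label: 31 small boxes laid on
# a lattice, so the full 279-feature layout can be exercised cheaply.
full_map_label_volume <- function() {
  map <- default_region_map()
  centers <- as.matrix(expand.grid(x = c(6, 17, 28, 39),
                                   y = c(6, 17, 28, 39),
                                   z = c(10, 30)))
  regions <- lapply(seq_len(nrow(map)), function(i) {
    phantom_region(map$label_id[i], map$region_name[i], "box",
                   centers[i, ], 3)
  })
  list(labels = build_label_volume(c(45, 45, 40), regions), map = map)
}

# Synthetic feature table in the default 279-column layout (no imaging):
# i.i.d. standard normal features, used by the statistics tests.
synthetic_feature_table <- function(n_subjects, seed,
                                    map = default_region_map(),
                                    scales = default_scales()) {
  set.seed(seed)
  cols <- as.vector(outer(
    as.vector(outer(map$region_name, sprintf("%.3f", scales),
                    paste, sep = "__")),
    c("A", "SD", "E"), paste, sep = "__"))
  ft <- as.data.frame(matrix(rnorm(n_subjects * length(cols)),
                             nrow = n_subjects))
  names(ft) <- cols
  cbind(data.frame(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                   stringsAsFactors = FALSE), ft)
}

simple_metadata <- function(n, groups = c("A", "B"), seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", seq_len(n)),
             group = rep(groups, length.out = n),
             sex = sample(c("M", "F"), n, replace = TRUE),
             age = runif(n, 8, 40),
             site = "test", stringsAsFactors = FALSE)
}

# Analytic 3-D LoG kernel, evaluated directly (independent of the package's
# separable construction).
analytic_log_kernel <- function(radius, sigma) {
  x <- -radius:radius
  g <- function(t) exp(-t^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  k <- array(0, c(length(x), length(x), length(x)))
  for (i in seq_along(x)) for (j in seq_along(x)) for (l in seq_along(x)) {
    r2 <- x[i]^2 + x[j]^2 + x[l]^2
    k[i, j, l] <- (r2 - 3 * sigma^2) / sigma^4 * g(x[i]) * g(x[j]) * g(x[l])
  }
  k
}
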