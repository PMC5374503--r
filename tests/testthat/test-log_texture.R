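test_that("the LoG response of a constant volume is zero", {
  v <- array(7.3, c(16, 16, 16))
  for (s in default_scales()) {
    r <- suppressWarnings(log_filter(v, spacing = 1, sigma_mm = s))
    expect_lt(max(abs(r)), 1e-10)
  }
})

test_that("the impulse response matches the sampled analytic LoG kernel", {
  # 'sampled' kernels with wide truncation: the separable implementation must
  # reproduce direct evaluation of del^2 G at each voxel offset
  n <- 49; c0 <- 25; sigma <- 2
  v <- array(0, c(n, n, n)); v[c0, c0, c0] <- 1
  r <- log_filter(v, spacing = 1, sigma_mm = sigma, truncate = 8,
                  kernel = "sampled")
  rad <- 16
  K <- analytic_log_kernel(rad, sigma)
  got <- r[(c0 - rad):(c0 + rad), (c0 - rad):(c0 + rad),
           (c0 - rad):(c0 + rad)]
  expect_lt(max(abs(got - K)) / max(abs(K)), 1e-6)
})

test_that("separable filtering equals dense convolution with the same kernel", {
  # independent oracle: direct dense convolution (triple loop over offsets)
  # against the separable implementation, away from the boundary
  set.seed(7)
  n <- 16; sigma <- 1.2; trunc <- 3
  v <- array(rnorm(n^3), c(n, n, n))
  r <- log_filter(v, spacing = 1, sigma_mm = sigma, truncate = trunc,
                  kernel = "sampled")
  rad <- as.integer(ceiling(trunc * sigma))
  K <- analytic_log_kernel(rad, sigma)
  off <- -rad:rad
  interior <- (rad + 1):(n - rad)
  dense <- array(0, c(n, n, n))
  for (a in seq_along(off)) for (b in seq_along(off)) for (d in seq_along(off)) {
    dense[interior, interior, interior] <-
      dense[interior, interior, interior] +
      K[a, b, d] * v[interior - off[a], interior - off[b], interior - off[d]]
  }
  got <- r[interior, interior, interior]
  want <- dense[interior, interior, interior]
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
})

test_that("LoG filtering is linear and translation-covariant in the interior", {
  set.seed(21)
  n <- 20
  a <- array(rnorm(n^3), c(n, n, n))
  b <- array(rnorm(n^3), c(n, n, n))
  r_sum <- log_filter(a + 2 * b, 1, 1.5)
  r_lin <- log_filter(a, 1, 1.5) + 2 * log_filter(b, 1, 1.5)
  expect_equal(as.vector(r_sum), as.vector(r_lin), tolerance = 1e-12)

  sh <- array(0, c(n, n, n)); sh[2:n, , ] <- a[1:(n - 1), , ]
  r1 <- log_filter(a, 1, 1.5)
  r2 <- log_filter(sh, 1, 1.5)
  core <- 8:(n - 7)
  expect_equal(r2[core + 1, core, core], r1[core, core, core],
               tolerance = 1e-10)
})

test_that("a Gaussian blob selects its own scale under normalization", {
  # scale-normalized response at the blob center peaks near sqrt(2/3)*s
  n <- 41; c0 <- 21; s <- 2
  x <- (1:n) - c0
  blob <- exp(-outer(outer(x^2, x^2, "+"), x^2, "+") / (2 * s^2))
  sig <- seq(0.6, 3.6, by = 0.2)
  resp <- vapply(sig, function(sg) {
    abs(suppressWarnings(
      log_filter(blob, 1, sg, scale_normalized = TRUE))[c0, c0, c0])
  }, 1.0)
  peak <- sig[which.max(resp)]
  expect_gt(peak, 0.6 * s)
  expect_lt(peak, 1.1 * s)
})

test_that("under-resolved scales and bad inputs are flagged", {
  v <- array(rnorm(5^3), c(5, 5, 5))
  expect_warning(log_filter(v, spacing = 2, sigma_mm = 0.6),
                 "under-resolved")
  expect_error(log_filter(v, 1, -1), "positive")
  v[1] <- Inf
  expect_error(log_filter(v, 1, 1), "non-finite")
})

test_that("quantifier functions reproduce the worked examples", {
  expect_equal(quantify_responses(c(1, 2, 3, 4)),
               c(A = 2.5, SD = sqrt(1.25), E = 2.0))
  expect_equal(quantify_responses(c(0, 0, 1, 1)),
               c(A = 0.5, SD = 0.5, E = 1.0))
  expect_equal(quantify_responses(rep(3.7, 50)), c(A = 3.7, SD = 0, E = 0))
  expect_warning(q <- quantify_responses(numeric(0)), "empty")
  expect_true(all(is.na(q)))
})

test_that("quantifier invariances hold on random data", {
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(sample(50:500, 1), sd = runif(1, 0.1, 10))
    q <- quantify_responses(x)
    expect_gte(q[["E"]], 0); expect_lte(q[["E"]], 8)  # log2(256) bits
    expect_gte(q[["SD"]], 0)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    qa <- quantify_responses(a * x + b)
    expect_equal(qa[["A"]], a * q[["A"]] + b, tolerance = 1e-10)
    expect_equal(qa[["SD"]], a * q[["SD"]], tolerance = 1e-10)
    expect_equal(qa[["E"]], q[["E"]], tolerance = 1e-10)  # affine-invariant
    qn <- quantify_responses(-x)
    expect_equal(qn[["SD"]], q[["SD"]], tolerance = 1e-10)
  }
  # E = log2(m) for m equally occupied bins
  for (m in c(2, 4, 8, 16)) {
    x <- rep(seq_len(m), each = 10)
    expect_equal(quantify_responses(x)[["E"]], log2(m), tolerance = 1e-10)
  }
})

test_that("feature extraction yields 9 features per region, NA for absent ones", {
  regions <- tiny_two_region_phantom()
  lab <- build_label_volume(c(24, 24, 24), regions)
  map <- phantom_region_map(regions)
  # locally constant signal: all quantifiers zero in both regions
  v <- labeled_volume(array(0, dim(lab)), lab, c(1, 1, 1), "flat")
  ft <- suppressWarnings(extract_features(v, map))
  expect_equal(ncol(ft), 1 + 2 * 3 * 3)
  expect_true(all(abs(unlist(ft[1, -1])) < 1e-10))

  # delete region 2 from the labels: its 9 features go missing
  lab2 <- lab; lab2[lab2 == 2L] <- 0L
  v2 <- labeled_volume(array(rnorm(length(lab)), dim(lab)), lab2,
                       c(1, 1, 1), "partial")
  expect_warning(ft2 <- extract_features(v2, map), "absent")
  vals <- unlist(ft2[1, -1])
  expect_equal(sum(is.na(vals)), 9)
  expect_equal(sum(!is.na(vals)), 9)

  # no mapped label present at all: hard error
  v3 <- labeled_volume(array(rnorm(27), c(3, 3, 3)), array(0L, c(3, 3, 3)))
  expect_error(extract_features(v3, map), "wrong label")
})

test_that("scale_sweep with one sigma equals extract_features at that sigma", {
  regions <- tiny_two_region_phantom()
  lab <- build_label_volume(c(24, 24, 24), regions)
  img <- simulate_intensity(lab, list(`1` = texture_params(tau = 1),
                                      `2` = texture_params(tau = 2, ell = 2)),
                            seed = 5)
  v <- labeled_volume(img, lab, c(1, 1, 1), "s1")
  map <- phantom_region_map(regions)
  wide <- scale_sweep(list(v), sigma_grid = 1.5, long = FALSE,
                      region_map = map)
  direct <- extract_features(v, map, scales = 1.5)
  expect_equal(wide, direct)

  long <- scale_sweep(list(v), sigma_grid = c(1, 2), region_map = map)
  expect_identical(names(long),
                   c("subject_id", "region", "sigma_mm", "quantifier",
                     "value"))
  expect_equal(nrow(long), 2 * 2 * 3)  # 2 regions x 2 sigmas x 3 quantifiers
  got <- long$value[long$region == "beta" & long$sigma_mm == 2 &
                      long$quantifier == "SD"]
  expect_equal(got, direct2 <- extract_features(v, map, scales = 2)[[
    "beta__2.000__SD"]])
})
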