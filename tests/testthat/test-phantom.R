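test_that("label volumes match direct voxel enumeration", {
  regions <- list(phantom_region(1, "a", "sphere", c(16, 16, 16), 5),
                  phantom_region(2, "b", "sphere", c(40, 40, 40), 5),
                  phantom_region(3, "c", "box", c(16, 40, 16), c(2, 3, 4)))
  lab <- build_label_volume(c(64, 64, 64), regions)
  # oracle: enumerate voxel centers directly
  gr <- expand.grid(x = 1:64, y = 1:64, z = 1:64)
  in_sph <- function(c0, r) {
    (gr$x - c0[1])^2 + (gr$y - c0[2])^2 + (gr$z - c0[3])^2 <= r^2
  }
  expect_equal(sum(lab == 1), sum(in_sph(c(16, 16, 16), 5)))
  expect_equal(sum(lab == 2), sum(in_sph(c(40, 40, 40), 5)))
  expect_equal(sum(lab == 3),
               sum(abs(gr$x - 16) <= 2 & abs(gr$y - 40) <= 3 &
                     abs(gr$z - 16) <= 4))

  expect_equal(build_label_volume(c(8, 8, 8), list()),
               array(0L, c(8, 8, 8)))
  expect_error(build_label_volume(c(64, 64, 64), list(
    phantom_region(1, "a", "sphere", c(16, 16, 16), 5),
    phantom_region(2, "b", "sphere", c(18, 16, 16), 5))), "overlap")
  expect_error(build_label_volume(c(20, 20, 20), list(
    phantom_region(1, "a", "sphere", c(18, 10, 10), 5))), "exceeds")
})

test_that("simulated intensity honours means, amplitude and determinism", {
  regions <- list(phantom_region(1, "a", "sphere", c(12, 12, 12), 7),
                  phantom_region(2, "b", "box", c(30, 30, 30), 6))
  lab <- build_label_volume(c(40, 40, 40), regions)

  # tau = 0: exact piecewise-constant volume
  img0 <- simulate_intensity(lab, list(`1` = texture_params(mu = 4),
                                       `2` = texture_params(mu = -2)),
                             seed = 1)
  expect_true(all(img0[lab == 1] == 4))
  expect_true(all(img0[lab == 2] == -2))
  expect_true(all(img0[lab == 0] == 0))

  # same seed twice: bit-identical
  pars <- list(`1` = texture_params(mu = 0, tau = 1, ell = 2),
               `2` = texture_params(mu = 5, tau = 0.3))
  expect_identical(simulate_intensity(lab, pars, seed = 9),
                   simulate_intensity(lab, pars, seed = 9))

  expect_error(simulate_intensity(lab, list(`1` = texture_params())),
               "missing texture params")
})

test_that("re-standardization gives unit within-region variance", {
  region <- list(phantom_region(1, "core", "sphere", c(32, 32, 32), 14))
  lab <- build_label_volume(c(64, 64, 64), region)
  expect_gt(sum(lab == 1), 1e4)
  sds <- vapply(1:20, function(s) {
    img <- simulate_intensity(lab, list(`1` = texture_params(tau = 1)),
                              seed = s)
    sd(img[lab == 1])
  }, 1.0)
  expect_true(all(sds > 0.97 & sds < 1.03))
})

test_that("phantom metadata is deterministic with the declared structure", {
  spec <- cohort_spec(n_per_group = c(ASD = 7, TDC = 9), age_range = c(8, 40),
                      seed = 123)
  md1 <- phantom_metadata(spec)
  md2 <- phantom_metadata(spec)
  expect_identical(md1, md2)
  expect_equal(as.vector(table(md1$group)[c("ASD", "TDC")]), c(7, 9))
  expect_true(all(md1$age >= 8 & md1$age <= 40))
  expect_false(anyDuplicated(md1$subject_id) > 0)
  expect_false(anyDuplicated(md1$noise_seed) > 0)
})

test_that("effects modify the targeted parameter per subject attributes", {
  regions <- list(phantom_region(1, "roi", "sphere", c(12, 12, 12), 6))
  spec <- cohort_spec(grid_dim = c(24, 24, 24),
                      n_per_group = c(A = 3, B = 3), seed = 4)
  base <- list(roi = texture_params(mu = 1, tau = 0))
  # group effect on mu, age effect stacked on top would conflict -> error
  eff_conflict <- list(
    effect_spec("roi", "group", "mu", values = c(B = 5)),
    effect_spec("roi", "age", "mu", slope = 0.1, ref_age = 8))
  expect_error(simulate_cohort(spec, regions, base, eff_conflict,
                               materialize = TRUE),
               "contradictory")

  eff <- list(effect_spec("roi", "group", "mu", values = c(B = 5)))
  co <- simulate_cohort(spec, regions, base, eff, materialize = TRUE)
  mus <- vapply(co$volumes, function(v) mean(v$intensity[co$labels == 1]),
                1.0)
  expect_equal(mus[co$metadata$group == "A"], rep(1, 3))
  expect_equal(mus[co$metadata$group == "B"], rep(5, 3))

  # linear age map: mu = baseline + slope * (age - ref)
  eff_age <- list(effect_spec("roi", "age", "mu", slope = 0.5, ref_age = 8))
  co2 <- simulate_cohort(spec, regions, base, eff_age, materialize = TRUE)
  mus2 <- vapply(co2$volumes, function(v) mean(v$intensity[co2$labels == 1]),
                 1.0)
  expect_equal(mus2, 1 + 0.5 * (co2$metadata$age - 8), tolerance = 1e-12)

  expect_error(simulate_cohort(spec, regions, base,
                               list(effect_spec("nope", "group", "mu",
                                                values = c(B = 2))),
               materialize = TRUE), "unknown region")
})

test_that("raising tau raises the expected SD feature at every scale", {
  region <- list(phantom_region(1, "core", "sphere", c(16, 16, 16), 9))
  lab <- build_label_volume(c(32, 32, 32), region)
  map <- phantom_region_map(region)
  mean_sd <- function(tau) {
    v <- vapply(1:6, function(s) {
      img <- simulate_intensity(lab, list(`1` = texture_params(tau = tau)),
                                seed = 40 + s)
      ft <- extract_features(labeled_volume(img, lab), map)
      unlist(ft[1, grepl("__SD$", names(ft))])
    }, numeric(3))
    rowMeans(v)
  }
  s1 <- mean_sd(1); s2 <- mean_sd(1.5); s3 <- mean_sd(2.25)
  expect_true(all(s2 > s1))
  expect_true(all(s3 > s2))
})
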