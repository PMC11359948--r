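test_that("vessel masks hit the density target deterministically", {
  m1 <- synth_vessel_mask(3, 304, 0.2)
  expect_gte(mean(m1), 0.16)
  expect_lte(mean(m1), 0.24)
  expect_identical(m1, synth_vessel_mask(3, 304, 0.2))
  expect_error(synth_vessel_mask(1, 100, 0.9), "density")
})

test_that("non-branching vessel masks have branch-free skeletons", {
  m <- synth_vessel_mask(8, 150, 0.15, branching = 0)
  sk <- binary_skeleton(m)
  bp <- retquant:::branch_points(sk)
  expect_identical(sum(bp), 0L)
  expect_gt(mean(m), 0.15 * 0.8)
})

test_that("FAZ masks realise the requested shape", {
  m <- synth_faz_mask(4, 200, radius = 40, eccentricity = 0, noise = 0)
  f <- faz_feature_set(m)
  expect_lt(abs(f[["FAZ_CI"]] - 1), 0.15)
  expect_lt(f[["FAZ_eccentricity"]], 0.1)
  m2 <- synth_faz_mask(4, 200, radius = 40, eccentricity = 0.6, noise = 0)
  f2 <- faz_feature_set(m2)
  expect_lt(abs(f2[["FAZ_eccentricity"]] - 0.6), 0.1)
  expect_identical(m2, synth_faz_mask(4, 200, radius = 40,
                                      eccentricity = 0.6, noise = 0))
  expect_error(synth_faz_mask(1, 100, radius = 5), "radius")
})

test_that("boundary noise raises the anisotropy index on average", {
  anis <- function(noise) {
    vapply(1:20, function(s)
      faz_feature_set(synth_faz_mask(1000 + s, 160, radius = 35,
                                     noise = noise))[["FAZ_anisotropy"]],
      numeric(1))
  }
  expect_gt(mean(anis(0.3)), mean(anis(0)))
})

test_that("cohort records satisfy the record invariants end to end", {
  ch <- tiny_cohort()
  expect_length(ch$records, 6)
  expect_identical(ch$labels$label, rep(c("control", "DR"), each = 3))
  for (rec in ch$records) {
    expect_s3_class(rec, "eye_record")
    expect_length(rec$projections, 6)
    d <- dim(rec$projections[[1]])
    for (p in rec$projections) {
      expect_identical(dim(p), d)
      expect_true(all(p >= 0 & p <= 255))
    }
    for (m in rec$masks) expect_identical(dim(m), d)
    # the FAZ is capillary-free by construction
    expect_identical(sum(rec$masks$capillary & rec$masks$FAZ), 0L)
  }
  # regeneration with the same spec is bit-identical
  spec <- cohort_spec(n_per_group = c(control = 3, DR = 3),
                      image_size = 96,
                      faz_radius = c(control = 16, DR = 14), seed = 42)
  again <- synth_cohort(spec)
  expect_identical(again$records[[4]], ch$records[[4]])
})

test_that("a null image cohort keeps the false-selection rate low", {
  spec <- cohort_spec(n_per_group = c(control = 8, DR = 8),
                      image_size = 96,
                      vessel_density = 0.2, faz_radius = 16,
                      faz_eccentricity = 0.4, faz_noise = 0.08,
                      texture_smoothness = 1.8, texture_offset = 0,
                      seed = 77)
  tab <- build_feature_table(synth_cohort(spec)$records)
  sel <- select_features(tab, mode = "two_group", alpha = 0.05)
  # identical generator parameters in both groups: near-alpha selection
  expect_lt(mean(sel$selected), 0.15)
})

test_that("signal tables inject shifts only where designated", {
  sig <- c("FAZ_area", "capillary_VAD_mean", "OCT_FULL_LBP3")
  tab <- synth_signal_table(c(control = 40, AMD = 40), sig, 2.5, seed = 6)
  x <- as.matrix(tab[, feature_names()])
  shift <- colMeans(x[tab$label == "AMD", ]) -
    colMeans(x[tab$label == "control", ])
  expect_true(all(shift[sig] > 1.5))
  expect_lt(max(abs(shift[setdiff(feature_names(), sig)])), 1.5)
  expect_error(synth_signal_table(c(control = 5, DR = 5), "nope", seed = 1),
               "unknown signal feature")
})
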