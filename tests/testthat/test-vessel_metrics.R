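test_that("artery/vein merging is a pixelwise union", {
  a <- rect_mask(30, 5:10, 5:10)
  v <- rect_mask(30, 20:25, 20:25)
  empty <- matrix(FALSE, 30, 30)
  expect_identical(merge_large_vessel(a, empty), a)
  expect_identical(sum(merge_large_vessel(a, v)), sum(a) + sum(v))
  ov <- rect_mask(30, 8:12, 8:12)
  expect_lte(sum(merge_large_vessel(a, ov)), sum(a) + sum(ov))
  expect_error(merge_large_vessel(a, matrix(FALSE, 10, 10)),
               "geometry mismatch")
})

test_that("skeletonization thins bars and crossings as expected", {
  expect_identical(sum(binary_skeleton(matrix(FALSE, 20, 20))), 0L)
  # 5-wide bar of length 50: end effects bounded by the bar width
  bar <- rect_mask(100, 30:34, 20:69)
  sk <- binary_skeleton(bar)
  expect_true(all(bar[sk]))  # skeleton is a subset of the mask
  expect_gte(sum(sk), 46)
  expect_lte(sum(sk), 52)
  # a "+" crossing has exactly one branch pixel (>= 3 skeleton neighbours)
  plus <- rect_mask(100, 48:52, 20:80) | rect_mask(100, 20:80, 48:52)
  skp <- binary_skeleton(plus)
  nb <- sapply(which(skp), function(i) {
    r <- (i - 1) %% 100 + 1; c <- (i - 1) %/% 100 + 1
    sum(skp[max(1, r - 1):min(100, r + 1),
            max(1, c - 1):min(100, c + 1)]) - 1
  })
  expect_identical(sum(nb >= 3), 1L)
})

test_that("windowed index maps honour the defined-zero conventions", {
  # all background: every index defined 0
  m <- matrix(FALSE, 40, 40)
  maps <- local_index_maps(m, 20)
  for (k in c("VAD", "VSD", "VPI", "VDI", "VCI", "VCP", "SP"))
    expect_true(all(maps[[k]] == 0), info = k)
  # fully vessel tile: VAD = 1, no internal boundary
  full <- matrix(TRUE, 20, 20)
  maps <- local_index_maps(full, 20)
  expect_equal(as.vector(maps$VAD), 1)
  expect_equal(as.vector(maps$VPI), 0)
  # straight 1-pixel line of 20 pixels: VSD = 0.05, zero curvature
  line <- matrix(FALSE, 20, 20); line[10, ] <- TRUE
  maps <- local_index_maps(line, 20)
  expect_equal(as.vector(maps$VSD), 20 / 400)
  expect_equal(as.vector(maps$SP), 0)
  expect_error(local_index_maps(matrix(TRUE, 10, 10), 20),
               "window larger than image")
})

test_that("mean VAD over full tiles conserves the vessel fraction", {
  m <- withr::with_seed(9, matrix(runif(80 * 80) < 0.3, 80))
  maps <- local_index_maps(m, 20)
  expect_equal(mean(maps$VAD), mean(m), tolerance = 1e-12)
})

test_that("VDI and VCI are stable under window-size doubling on uniform texture", {
  m <- withr::with_seed(3, matrix(runif(80 * 80) < 0.3, 80))
  a <- local_index_maps(m, 20)
  b <- local_index_maps(m, 40)
  expect_lt(abs(mean(a$VDI) - mean(b$VDI)) / mean(a$VDI), 0.1)
  expect_lt(abs(mean(a$VCI) - mean(b$VCI)) / mean(a$VCI), 0.1)
})

test_that("box-counting dimension hits the point/line/plane limits", {
  pt <- matrix(FALSE, 256, 256); pt[77, 191] <- TRUE
  expect_lt(abs(box_counting_fd(pt) - 0), 0.05)
  ln <- matrix(FALSE, 256, 256); ln[128, ] <- TRUE
  expect_lt(abs(box_counting_fd(ln) - 1), 0.1)
  pl <- matrix(TRUE, 256, 256)
  expect_lt(abs(box_counting_fd(pl) - 2), 0.05)
  expect_error(box_counting_fd(matrix(FALSE, 64, 64)), "empty structure")
})

test_that("distribution summaries use sample std and non-excess kurtosis", {
  s <- distribution_summary(matrix(5, 4, 4))
  expect_equal(unname(s[c("std", "skew", "kur")]), c(0, 0, 0))
  s2 <- distribution_summary(c(0, 0, 0, 1))
  expect_equal(unname(s2[c("max", "mean", "median")]), c(1, 0.25, 0))
  expect_equal(unname(s2["std"]), 0.5)  # n-1 denominator
  z <- withr::with_seed(15, rnorm(1e5))
  expect_lt(abs(distribution_summary(z)[["kur"]] - 3), 0.1)
  expect_error(distribution_summary(3), "insufficient windows")
})

test_that("a vessel structure yields exactly 43 deterministic features", {
  m <- synth_vessel_mask(5, 120, 0.25)
  f1 <- vessel_feature_set(m, "capillary")
  f2 <- vessel_feature_set(m, "capillary")
  expect_length(f1, 43)
  expect_identical(f1, f2)
  expect_identical(names(f1)[1], "capillary_VAD_max")
  expect_identical(names(f1)[43], "capillary_FD")
  fd <- f1[["capillary_FD"]]
  expect_gte(fd, 0); expect_lte(fd, 2)
  lv <- vessel_feature_set(m, "large_vessel")
  expect_length(c(f1, lv), 86)
})
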