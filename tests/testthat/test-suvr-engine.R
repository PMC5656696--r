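# brute-force oracle: explicit voxel loop, no vectorized statistics
loop_region_stats <- function(values, sel) {
  kept <- c()
  miss <- 0L
  for (i in seq_along(values)) {
    if (sel[i]) {
      if (is.na(values[i])) miss <- miss + 1L else kept <- c(kept, values[i])
    }
  }
  mu <- sum(kept) / length(kept)
  list(mean = mu,
       sd = if (length(kept) > 1) sqrt(sum((kept - mu)^2) / (length(kept) - 1)) else 0,
       n = length(kept), missing = miss)
}

cube_mask <- function(dims, idx, name = "VOI") {
  w <- array(0, dims)
  w[idx] <- 1
  voi_mask(w, name = name)
}

test_that("region_mean matches hand arithmetic on small masks", {
  dims <- c(4, 4, 4)
  vol <- volume_grid(array(2.5, dims))
  m <- cube_mask(dims, 1:10)
  rs <- region_mean(vol, m)
  expect_equal(rs$mean, 2.5)
  expect_equal(rs$sd, 0)
  expect_identical(rs$voxel_count, 10L)

  vals <- array(0, dims)
  vals[1:4] <- c(1, 2, 3, 6)
  rs2 <- region_mean(volume_grid(vals), cube_mask(dims, 1:4))
  expect_equal(rs2$mean, 3.0)

  vals3 <- array(0, dims)
  vals3[1:3] <- c(1, 2, NaN)
  rs3 <- region_mean(volume_grid(vals3), cube_mask(dims, 1:3))
  expect_equal(rs3$mean, 1.5)
  expect_identical(rs3$missing_excluded, 1L)
  expect_identical(rs3$voxel_count, 2L)
})

test_that("region_mean equals the brute-force voxel loop on random volumes", {
  set.seed(33)
  for (i in 1:10) {
    dims <- sample(3:8, 3, replace = TRUE)
    vals <- array(stats::rnorm(prod(dims), 2, 0.5), dims)
    vals[sample(prod(dims), 3)] <- NaN
    sel <- array(stats::runif(prod(dims)) < 0.4, dims)
    vol <- volume_grid(vals)
    if (!any(sel & !is.na(vol$values))) next
    m <- voi_mask(sel * 1)
    rs <- region_mean(vol, m)
    oracle <- loop_region_stats(vol$values, sel)
    expect_equal(rs$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(rs$sd, oracle$sd, tolerance = 1e-12)
    expect_identical(rs$voxel_count, oracle$n)
    expect_identical(rs$missing_excluded, oracle$missing)
  }
})

test_that("compute_suvr is the ratio of region means", {
  dims <- c(6, 6, 6)
  uni <- volume_grid(array(3.7, dims))
  ctx <- cube_mask(dims, 1:20, "cortex")
  ref <- cube_mask(dims, 101:140, "cerebellum")
  expect_equal(compute_suvr(uni, ctx, ref)$suvr, 1.0)

  ph <- generate_phantom(noise_sd = 0, cortex_uptake = 2.0,
                         cerebellum_uptake = 1.25)
  rec <- compute_suvr(ph$volume, ph$cortex, ph$cerebellum,
                      subject_id = "P01", tracer = "FBB")
  expect_equal(rec$suvr, 1.6)
  expect_identical(rec$subject_id, "P01")

  # the threshold-magnitude case: cortex mean 1.478 over unit reference
  vals <- array(1.0, dims)
  vals[1:20] <- 1.478
  rec2 <- compute_suvr(volume_grid(vals), ctx, ref)
  expect_equal(rec2$suvr, 1.478)
})

test_that("SUVR is invariant under global intensity scaling", {
  ph <- generate_phantom(noise_sd = 0.1, seed = 5)
  base <- compute_suvr(ph$volume, ph$cortex, ph$cerebellum)$suvr
  for (c in c(0.25, 3, 1e4)) {
    scaled <- volume_grid(ph$volume$values * c, ph$volume$affine)
    expect_equal(compute_suvr(scaled, ph$cortex, ph$cerebellum)$suvr, base,
                 tolerance = 1e-12)
  }
})

test_that("growing the cortex mask into background pulls SUVR toward background", {
  ph <- generate_phantom(dims = c(12, 12, 12), noise_sd = 0,
                         cortex_uptake = 2, cerebellum_uptake = 1.25,
                         background_uptake = 1)
  base <- compute_suvr(ph$volume, ph$cortex, ph$cerebellum)$suvr
  # dilate the cortex mask by adding background voxels above the shell
  w <- ph$cortex$weights
  bg <- which(ph$volume$values == 1 & w == 0)
  w[bg[1:50]] <- 1
  grown <- voi_mask(w, ph$cortex$affine, name = "grown")
  grown_suvr <- compute_suvr(ph$volume, grown, ph$cerebellum)$suvr
  bg_ratio <- 1 / 1.25
  expect_lt(grown_suvr, base)
  expect_gt(grown_suvr, bg_ratio)
})

test_that("degenerate inputs are rejected", {
  dims <- c(5, 5, 5)
  vol <- volume_grid(array(1, dims))
  other <- voi_mask(array(1, c(5, 5, 4)))
  expect_error(region_mean(vol, other), "grid mismatch")

  vals <- array(1, dims)
  vals[1:4] <- NaN
  expect_error(region_mean(volume_grid(vals), cube_mask(dims, 1:4)),
               "missing")

  neg <- array(-1, dims)
  neg[1:4] <- 1
  expect_error(
    compute_suvr(volume_grid(neg), cube_mask(dims, 1:4),
                 cube_mask(dims, 5:8)),
    "invalid reference region")
})
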