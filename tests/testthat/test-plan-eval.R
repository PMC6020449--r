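# RTDOSE round trips, contour rasterization, DVHs and dose metrics

test_that("RTDOSE scaling follows the 32-bit contract and round-trips", {
  d <- c(4, 4, 3)
  set.seed(8)
  dose <- array(stats::runif(prod(d), 0, 4), dim = d)
  dose[1] <- 4.0   # pin the maximum
  g <- dose_grid(dose, array(0, d), spacing_mm = c(2, 2, 5),
                 origin_mm = c(-3, -3, 0), unit = "Gy")
  f <- withr::local_tempfile(fileext = ".dcm")
  export_rtdose(g, f, mu_scale = 1)
  ds <- rtmc:::dcm_read(f)
  expect_equal(rtmc:::dcm_get(ds, "DoseGridScaling"), 4.0 / (2^32 - 1),
               tolerance = 1e-9)
  back <- read_rtdose(f)
  expect_lt(max(abs(back$dose - g$dose)), 4.0 / (2^32 - 1) + 1e-15)
  expect_equal(back$spacing_mm, g$spacing_mm)
  expect_equal(back$origin_mm, g$origin_mm)
  expect_true(isTRUE(attr(back, "sigma_missing")))
})

test_that("degenerate grids and invalid dose are handled at export", {
  d <- c(2, 2, 2)
  zero <- dose_grid(array(0, d), array(0, d), c(1, 1, 1), unit = "Gy")
  f <- withr::local_tempfile(fileext = ".dcm")
  export_rtdose(zero, f)
  back <- read_rtdose(f)
  expect_true(all(back$dose == 0))
  bad <- dose_grid(array(1, d), array(0, d), c(1, 1, 1))
  bad$dose[1] <- NaN
  expect_error(export_rtdose(bad, withr::local_tempfile()),
               class = "rtmc_export_error")
})

test_that("both GridFrameOffsetVector dialects parse; bad inputs error", {
  d <- c(2, 2, 4)
  g <- dose_grid(array(1, d), array(0, d), c(1, 1, 2.5), unit = "Gy")
  f <- withr::local_tempfile(fileext = ".dcm")
  export_rtdose(g, f)                       # per-frame offsets (0, 2.5, 5, 7.5)
  expect_equal(read_rtdose(f)$spacing_mm[3], 2.5)
  # uniform-offset shorthand: rewrite the tag with two values
  ds <- rtmc:::dcm_read(f)
  ds <- rtmc:::dcm_set(ds, "GridFrameOffsetVector", c(0, 2.5))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  rtmc:::dcm_write(ds, f2)
  expect_equal(read_rtdose(f2)$spacing_mm[3], 2.5)
  # missing GFOV
  key <- rtmc:::dcm_tag_key("GridFrameOffsetVector")
  ds[[key]] <- NULL
  f3 <- withr::local_tempfile(fileext = ".dcm")
  rtmc:::dcm_write(ds, f3)
  expect_error(read_rtdose(f3), class = "rtmc_format_error")
  # non-RTDOSE input
  ct <- rtmc:::dcm_dataset(SOPClassUID = rtmc:::SOP_CT,
                           SOPInstanceUID = rtmc:::dcm_uid(3, 1),
                           Modality = "CT")
  f4 <- withr::local_tempfile(fileext = ".dcm")
  rtmc:::dcm_write(ct, f4)
  expect_error(read_rtdose(f4), class = "rtmc_format_error")
})

# a grid whose voxel centers sit at odd millimetres (origin 1, spacing 2)
odd_grid <- function(n = 12, nz = 1) {
  dose_grid(array(1, c(n, n, nz)), array(0, c(n, n, nz)),
            spacing_mm = c(2, 2, 2), origin_mm = c(1, 1, 0), unit = "Gy")
}

square <- function(x0, x1, z = 0) {
  cbind(c(x0, x1, x1, x0), c(x0, x0, x1, x1), z)
}

test_that("voxel-center rasterization counts match the parity oracle", {
  g <- odd_grid()
  # 10x10 mm square on a 2 mm grid: 5x5 centers inside
  m <- rasterize_structure(list(square(0, 10)), g)
  expect_identical(sum(m), 25L)
  # point far outside
  expect_false(m[12, 12, 1])
  # 20 mm square with a 10 mm hole: 100 - 25 = 75 ring voxels
  ring <- rasterize_structure(list(square(0, 20), square(4, 14)), g)
  expect_identical(sum(ring), 75L)
  # nested contour subtracts (hole voxels are off)
  expect_false(ring[4, 4, 1])   # center (7,7) inside the hole
  expect_true(ring[1, 1, 1])    # center (1,1) in the ring
})

test_that("contours land on the nearest slice and empty overlap warns", {
  g <- dose_grid(array(1, c(4, 4, 3)), array(0, c(4, 4, 3)),
                 spacing_mm = c(2, 2, 5), origin_mm = c(1, 1, 0), unit = "Gy")
  m <- rasterize_structure(list(square(0, 8, z = 4.2)), g)
  expect_identical(sum(m[, , 2]), 16L)   # z = 4.2 -> slice at z = 5
  expect_identical(sum(m[, , c(1, 3)]), 0L)
  expect_warning(m2 <- rasterize_structure(list(square(0, 8, z = 99)), g),
                 "overlap")
  expect_true(isTRUE(attr(m2, "empty_overlap")))
  expect_error(rasterize_structure(list(), g), class = "rtmc_evaluation_error")
  expect_error(rasterize_structure(list(square(0, 8)[1:2, ]), g), "3 vertices")
})

test_that("cumulative DVHs follow their defining step functions", {
  g <- odd_grid(4)
  g$dose[] <- 2.0
  mask <- array(TRUE, dim = g$dims)
  curve <- cumulative_dvh(g, mask, bin_width_gy = 0.1)
  expect_equal(curve$volume_pct[curve$dose_gy <= 2.0], rep(100, 21))
  expect_equal(curve$volume_pct[curve$dose_gy > 2.0], 0)
  met <- dose_metrics(curve, v_at_gy = 0)
  expect_equal(met$D95_gy, 2.0)
  expect_equal(met$Dmax_gy, 2.0)
  expect_equal(met$Dmean_gy, 2.0, tolerance = 0.05 + 1e-12)
  expect_equal(met$V0_pct, 100)
  # two equal-volume voxels at 1 and 3 Gy
  g2 <- dose_grid(array(c(1, 3), c(2, 1, 1)), array(0, c(2, 1, 1)),
                  c(1, 1, 1), unit = "Gy")
  curve2 <- cumulative_dvh(g2, array(TRUE, c(2, 1, 1)), 0.1)
  expect_equal(curve2$volume_pct[which.min(abs(curve2$dose_gy - 2.0))], 50)
  met2 <- dose_metrics(curve2, v_at_gy = c(2, 99))
  expect_equal(met2$D95_gy, 1.0)
  expect_equal(met2$V2_pct, 50)
  expect_equal(met2$V99_pct, 0)     # clamped beyond the curve
  expect_true(isTRUE(attr(met2, "clamped")))
  expect_error(cumulative_dvh(g, array(FALSE, g$dims), 0.1),
               class = "rtmc_evaluation_error")
})

test_that("DVH-derived mean dose matches the voxel mean within half a bin", {
  set.seed(14)
  d <- c(6, 6, 4)
  g <- dose_grid(array(stats::rgamma(prod(d), 4, 2), d), array(0, d),
                 c(2, 2, 2), unit = "Gy")
  mask <- array(stats::runif(prod(d)) > 0.3, d)
  bw <- 0.05
  curve <- cumulative_dvh(g, mask, bw)
  met <- dose_metrics(curve)
  expect_lt(abs(met$Dmean_gy - mean(g$dose[mask])), bw / 2)
  # curve invariants
  expect_true(all(diff(curve$volume_pct) <= 1e-12))
  expect_equal(curve$volume_pct[1], 100)
  expect_equal(curve$volume_pct[nrow(curve)], 0)
})

test_that("DVH plots build as ggplot objects", {
  g <- odd_grid(4)
  curve <- cumulative_dvh(g, array(TRUE, g$dims), 0.1)
  p <- ggplot2::autoplot(curve)
  expect_s3_class(p, "ggplot")
  ps <- plot_dose_slice(g, what = "dose")
  expect_s3_class(ps, "ggplot")
})
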