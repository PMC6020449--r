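# statistical merging of binary dose files, column tallies and phase spaces

test_that("binary dose merging applies history-weighted error propagation", {
  layout <- dose_layout(16, 2, "double")
  hdr <- as.raw(1:16)
  base <- withr::local_tempdir()
  f1 <- tiny_dose_file(file.path(base, "a.bin"), c(1.0, 5), c(0.20, 0.1),
                       layout, hdr)
  f2 <- tiny_dose_file(file.path(base, "b.bin"), c(3.0, 5), c(0.20, 0.1),
                       layout, hdr)
  m <- merge_binary_dose(c(f1, f2), layout, c(1000, 1000))
  expect_equal(m$dose[1], 2.0)
  expect_equal(m$sigma[1], sqrt(0.5^2 * 0.04 + 0.5^2 * 0.04), tolerance = 1e-12)
  expect_identical(m$header, hdr)
  expect_equal(m$histories, 2000)

  f3 <- tiny_dose_file(file.path(base, "c.bin"), c(2.0, 0), c(0.1, 0), layout, hdr)
  f4 <- tiny_dose_file(file.path(base, "d.bin"), c(6.0, 0), c(0.3, 0), layout, hdr)
  m2 <- merge_binary_dose(c(f3, f4), layout, c(3000, 1000))
  expect_equal(m2$dose[1], 3.0)
  expect_equal(m2$sigma[1], sqrt(0.75^2 * 0.01 + 0.25^2 * 0.09), tolerance = 1e-12)

  # single file: identity
  one <- merge_binary_dose(f1, layout, 500)
  x <- read_binary_dose(f1, layout)
  expect_identical(one$dose, x$dose)
  expect_identical(one$sigma, x$sigma)

  # size mismatch
  bad <- file.path(base, "bad.bin")
  writeBin(raw(10), bad)
  expect_error(merge_binary_dose(c(f1, bad), layout, c(1, 1)),
               class = "rtmc_format_error")
})

test_that("merging is permutation-invariant and associative", {
  layout <- dose_layout(0, 5, "double")
  base <- withr::local_tempdir()
  set.seed(9)
  fs <- vapply(1:3, function(i) {
    tiny_dose_file(file.path(base, paste0(i, ".bin")),
                   stats::runif(5, 1, 2), stats::runif(5, 0.01, 0.1),
                   layout, raw(0))
  }, character(1))
  h <- c(1000, 3000, 2000)
  m123 <- merge_binary_dose(fs, layout, h)
  m321 <- merge_binary_dose(rev(fs), layout, rev(h))
  expect_equal(m123$dose, m321$dose, tolerance = 1e-14)
  expect_equal(m123$sigma, m321$sigma, tolerance = 1e-12)
  # associativity: merge {1,2} then {12,3}
  m12 <- merge_binary_dose(fs[1:2], layout, h[1:2],
                           out = file.path(base, "m12.bin"))
  mab <- merge_binary_dose(c(file.path(base, "m12.bin"), fs[3]), layout,
                           c(sum(h[1:2]), h[3]))
  expect_equal(mab$dose, m123$dose, tolerance = 1e-14)
  expect_equal(mab$sigma, m123$sigma, tolerance = 1e-12)
})

test_that("column tallies merge with the same formulas and verify keys", {
  base <- withr::local_tempdir()
  write_tab <- function(f, val, unc) {
    utils::write.table(data.frame(x = 1:3, y = c(0, 0, 1), v = val, u = unc),
                       f, row.names = FALSE, col.names = FALSE)
    f
  }
  f1 <- write_tab(file.path(base, "t1.txt"), c(1, 2, 3), c(0.2, 0.2, 0.2))
  f2 <- write_tab(file.path(base, "t2.txt"), c(3, 2, 1), c(0.2, 0.2, 0.2))
  m <- merge_column_tallies(c(f1, f2), c(1000, 1000), 3, 4)
  expect_equal(m[[3]], c(2, 2, 2))
  expect_equal(m[[4]], rep(sqrt(2 * 0.25 * 0.04), 3), tolerance = 1e-12)
  expect_equal(m[[1]], 1:3)
  one <- merge_column_tallies(f1, 100, 3, 4)
  expect_equal(one[[3]], c(1, 2, 3))
  f3 <- file.path(base, "t3.txt")
  utils::write.table(data.frame(x = c(1, 9, 3), y = c(0, 0, 1),
                                v = 1:3, u = rep(0.1, 3)),
                     f3, row.names = FALSE, col.names = FALSE)
  expect_error(merge_column_tallies(c(f1, f3), c(1, 1), 3, 4),
               "row 2", class = "rtmc_alignment_error")
})

test_that("phase spaces concatenate with additive headers", {
  rec <- function(n, e) tibble::tibble(
    type = rep(1L, n), energy_mev = rep(e, n), x_mm = seq_len(n),
    y_mm = 0, z_mm = 0, u = 0, v = 0, w = 1, weight = 1)
  base <- withr::local_tempdir()
  f1 <- file.path(base, "a.phsp"); f2 <- file.path(base, "b.phsp")
  write_phsp(phase_space(rec(10, 1.0), 1000), f1)
  write_phsp(phase_space(rec(30, 2.0), 3000), f2)
  m <- merge_phsp(c(f1, f2), out = file.path(base, "m.phsp"))
  expect_equal(m$n_original_histories, 4000)
  expect_identical(m$n_particles, 40L)
  back <- read_phsp(file.path(base, "m.phsp"))
  expect_equal(back$records$energy_mev, c(rep(1, 10), rep(2, 30)))
  # single-file merge: byte-identical records, same header
  one <- merge_phsp(f1)
  expect_equal(one$records, read_phsp(f1)$records)
  expect_equal(one$n_original_histories, 1000)
  # record-layout mismatch (7-field records) is a format error
  f3 <- file.path(base, "c.phsp")
  con <- file(f3, "wb")
  writeBin(charToRaw(paste0(
    "$PHSP_DIALECT 1\n$N_ORIGINAL_HISTORIES 10\n$N_PARTICLES 0\n",
    "$RECORD_LAYOUT type energy_mev x_mm y_mm z_mm u v w\n$END_HEADER\n")), con)
  close(con)
  expect_error(merge_phsp(c(f1, f3)), class = "rtmc_format_error")
  # direction cosines must be unit norm
  badrec <- rec(1, 1); badrec$w <- 2
  expect_error(phase_space(badrec, 1), "unit-norm")
})

test_that("region uncertainty averages k*sigma/dose above half maximum", {
  g <- dose_grid(array(1, c(2, 2, 1)), array(0.02, c(2, 2, 1)), c(1, 1, 1))
  expect_equal(region_uncertainty(g, k = 2), 4.0)
  expect_equal(region_uncertainty(g, k = 0), 0)
  g2 <- dose_grid(array(c(10, 1, 10, 10), c(2, 2, 1)),
                  array(c(0.1, 0.5, 0.1, 0.1), c(2, 2, 1)), c(1, 1, 1))
  mask <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(region_uncertainty(g2, mask, k = 2), 2.0)
  expect_error(region_uncertainty(g, array(FALSE, c(2, 2, 1))),
               class = "rtmc_evaluation_error")
  zero <- dose_grid(array(0, c(1, 1, 1)), array(0, c(1, 1, 1)), c(1, 1, 1))
  expect_error(region_uncertainty(zero), class = "rtmc_evaluation_error")
})
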