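# CT loading, resampling, HU conversion, phantom file round trips

test_that("fixture CT series loads with the constructed geometry and HU", {
  base <- withr::local_tempdir()
  spec <- fixture_spec("MARC_HN", seed = 2)
  make_ct(spec, file.path(base, "ct"))
  vol <- load_ct_series(file.path(base, "ct"))
  expect_identical(vol$dims, c(32L, 32L, 16L))
  expect_equal(vol$spacing_mm, c(4, 4, 5))
  # center of the water cylinder is exactly HU 0; far corner is air
  expect_equal(vol$hu[16, 16, 8], 0)
  expect_equal(vol$hu[1, 1, 1], -1000)
})

test_that("degenerate and inconsistent series are handled", {
  base <- withr::local_tempdir()
  spec <- fixture_spec("MARC_HN", dims = c(8, 8, 3), seed = 2)
  make_ct(spec, file.path(base, "ct"))
  # single-slice directory is legal
  one <- file.path(base, "one")
  dir.create(one)
  file.copy(file.path(base, "ct", "ct_0001.dcm"), one)
  v1 <- load_ct_series(one)
  expect_identical(v1$dims[3], 1L)
  # non-uniform slice gap: drop the middle slice of three
  gap <- file.path(base, "gap")
  dir.create(gap)
  file.copy(file.path(base, "ct", c("ct_0001.dcm", "ct_0003.dcm")), gap)
  spec2 <- fixture_spec("MARC_HN", dims = c(8, 8, 1), seed = 99)
  make_ct(spec2, file.path(base, "ct1"))
  file.copy(file.path(base, "ct1", "ct_0001.dcm"), file.path(gap, "ct_extra.dcm"))
  expect_error(load_ct_series(gap), class = "rtmc_series_error")  # mixed series
  unlink(file.path(gap, "ct_extra.dcm"))
  gap3 <- file.path(base, "gap3")
  dir.create(gap3)
  file.copy(file.path(base, "ct", c("ct_0001.dcm", "ct_0002.dcm")), gap3)
  # fabricate a third slice at a non-uniform z by shifting slice 3's position
  spec3 <- fixture_spec("MARC_HN", dims = c(8, 8, 6), seed = 2)
  make_ct(spec3, file.path(base, "ct6"))
  file.copy(file.path(base, "ct6", "ct_0006.dcm"), file.path(gap3, "ct_0006.dcm"))
  expect_error(load_ct_series(gap3), class = "rtmc_geometry_error")
})

test_that("volume-weighted downsampling averages HU and preserves constants", {
  v <- image_volume(array(c(0, 100, 200, 300), dim = c(2, 2, 1)),
                    spacing_mm = c(1, 1, 1))
  r <- resample_volume(v, c(2, 2, 1))
  expect_identical(r$dims, c(1L, 1L, 1L))
  expect_equal(as.numeric(r$hu), 150)
  # constant field is invariant under any resampling
  cv <- image_volume(array(0, dim = c(6, 6, 4)), spacing_mm = c(2, 2, 3))
  expect_true(all(resample_volume(cv, c(3, 5, 4))$hu == 0))
  expect_true(all(resample_volume(cv, c(1, 1, 1))$hu == 0))
  # identity resampling is bit-identical
  v2 <- image_volume(array(rnorm(64), dim = c(4, 4, 4)), spacing_mm = c(2, 2, 2))
  expect_identical(resample_volume(v2, c(2, 2, 2)), v2)
  expect_error(resample_volume(v2, c(100, 2, 2)), class = "rtmc_geometry_error")
})

test_that("downsample-then-convert conserves mass on smooth fixtures", {
  set.seed(31)
  hu <- array(200 * outer(outer(sin(seq(0, pi, length.out = 16)),
                                cos(seq(0, pi, length.out = 16))),
                          rep(1, 8)),
              dim = c(16, 16, 8))
  v <- image_volume(hu, spacing_mm = c(2, 2, 4))
  tab <- default_hu_table()
  m0 <- phantom_mass_g(apply_conversion(v, tab))
  m1 <- phantom_mass_g(apply_conversion(resample_volume(v, c(4, 4, 8)), tab))
  expect_lt(abs(m1 - m0) / m0, 0.005)
})

test_that("HU conversion interpolates, clamps, and reports uncovered HU", {
  tab <- hu_table(
    material_bins = data.frame(hu_low = -1000, hu_high = 1000,
                               material_name = "W", material_index = 1),
    density_breakpoints = data.frame(hu = c(-1000, 0, 1000),
                                     density_g_cm3 = c(0.001, 1.0, 1.6)))
  mk <- function(h) image_volume(array(h, dim = c(1, 1, 1)), c(1, 1, 1))
  expect_equal(as.numeric(apply_conversion(mk(0), tab)$density), 1.0)
  expect_equal(as.numeric(apply_conversion(mk(-500), tab)$density), 0.5005)
  expect_equal(as.numeric(apply_conversion(mk(1000), tab)$density), 1.6)
  expect_error(apply_conversion(mk(2000), tab), "2000",
               class = "rtmc_conversion_error")
  # monotone table gives voxelwise monotone density
  hu_seq <- seq(-1000, 1000, by = 37)
  v <- image_volume(array(hu_seq, dim = c(length(hu_seq), 1, 1)), c(1, 1, 1))
  expect_true(all(diff(as.numeric(apply_conversion(v, tab)$density)) >= 0))
})

test_that("conversion tables load from YAML and match the built-in default", {
  f <- system.file("extdata", "hu_table_default.yaml", package = "rtmc")
  tab <- read_hu_table(f)
  def <- default_hu_table()
  expect_equal(tab$material_bins$material_name, def$material_bins$material_name)
  expect_equal(tab$density_breakpoints$density_g_cm3,
               def$density_breakpoints$density_g_cm3)
})

test_that("egsphant files round-trip and enforce the code-space limit", {
  ph <- voxel_phantom(array(1L, c(2, 2, 1)), array(1.0, c(2, 2, 1)),
                      spacing_mm = c(10, 10, 10),
                      material_names = c("1" = "WATER"))
  f <- withr::local_tempfile(fileext = ".egsphant")
  write_egsphant(ph, f)
  lines <- readLines(f)
  expect_identical(lines[1], "1")
  expect_identical(lines[2], "WATER")
  expect_identical(lines[8], "11")   # first material-map row
  r <- read_egsphant(f)
  expect_identical(r$material, ph$material)
  expect_lt(max(abs(r$density - ph$density)), 1e-6)
  # a fixture phantom: write -> read -> write is byte-identical
  spec <- fixture_spec("MARC_HN", dims = c(8, 8, 4), seed = 12)
  base <- withr::local_tempdir()
  make_ct(spec, file.path(base, "ct"))
  ph2 <- apply_conversion(load_ct_series(file.path(base, "ct")))
  # egsphant media are renumbered 1..N; renumber first for a clean round trip
  mat <- array(match(ph2$material, sort(unique(as.integer(ph2$material)))),
               dim = ph2$dims)
  nm <- ph2$material_names[as.character(sort(unique(as.integer(ph2$material))))]
  ph2 <- voxel_phantom(mat, ph2$density, ph2$spacing_mm, ph2$origin_mm,
                       setNames(unname(nm), seq_along(nm)))
  f1 <- file.path(base, "a.egsphant"); f2 <- file.path(base, "b.egsphant")
  write_egsphant(ph2, f1)
  write_egsphant(read_egsphant(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # header lists both materials in index order
  ph3 <- voxel_phantom(array(c(1L, 2L), c(2, 1, 1)), array(1, c(2, 1, 1)),
                       c(1, 1, 1), material_names = c("1" = "A", "2" = "B"))
  f3 <- withr::local_tempfile()
  write_egsphant(ph3, f3)
  expect_identical(readLines(f3)[2:3], c("A", "B"))
  # code space exhaustion
  nbig <- length(rtmc:::.egs_codes) + 1L
  big <- voxel_phantom(array(seq_len(nbig), c(nbig, 1, 1)),
                       array(1, c(nbig, 1, 1)), c(1, 1, 1))
  expect_error(write_egsphant(big, withr::local_tempfile()),
               class = "rtmc_capacity_error")
})

test_that("PenVox files round-trip exactly and refuse bad density", {
  ph <- voxel_phantom(array(1L, c(1, 1, 1)), array(1.0, c(1, 1, 1)),
                      spacing_mm = c(10, 10, 10),
                      material_names = c("1" = "WATER"))
  f <- withr::local_tempfile(fileext = ".penvox")
  write_penvox(ph, f)
  body <- readLines(f)
  expect_identical(length(body), 5L)           # 4 header lines + 1 record
  expect_match(body[5], "^1 1\\.0")
  base <- withr::local_tempdir()
  spec <- fixture_spec("STATIC_SBRT_LUNG", dims = c(8, 8, 4), seed = 13)
  make_ct(spec, file.path(base, "ct"))
  ph2 <- apply_conversion(load_ct_series(file.path(base, "ct")))
  f2 <- file.path(base, "p.penvox")
  write_penvox(ph2, f2)
  r <- read_penvox(f2)
  expect_identical(r$material, ph2$material)
  expect_lt(max(abs(r$density - ph2$density) / pmax(ph2$density, 1e-12)), 1e-6)
  expect_identical(unname(r$material_names), unname(
    ph2$material_names[names(r$material_names)]))
  # negative density is refused at construction
  expect_error(voxel_phantom(array(1L, c(1, 1, 1)), array(-1, c(1, 1, 1)),
                             c(1, 1, 1)))
})
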