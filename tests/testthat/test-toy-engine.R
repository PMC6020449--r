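# toy dose engine: geometry, attenuation physics, determinism, estimators

run_one_field <- function(nhist, seed, tag, gantry = 0, half = 50,
                          ledger = FALSE) {
  res <- run_split_field(nhist, 1, seed, ledger = ledger, work_tag = tag)
  res$grid
}

test_that("central-axis dose decreases with depth beyond the entry voxel", {
  g <- run_one_field(30000, 21, "depth")
  prof <- g$dose[8, , 8]   # beam enters at low y (gantry 0)
  expect_true(all(diff(prof[2:16]) < 0))
  expect_gt(prof[2], prof[16] * 1.5)
})

test_that("voxels outside the aperture projection receive exactly zero", {
  ts <- toy_setup()
  beams <- open_field_beam(half = 15)   # 30 x 30 mm field in a 160 mm phantom
  items <- distribute_work(beams, 1, "EQUAL", 5000, master_seed = 3)
  wd <- file.path(withr::local_tempdir(), "shadow")
  items <- bind_work_items(ts$model, beams, items, wd, ts$phantom_path)
  r <- toy_mc_run(items$bound_dir[1])
  # corner columns are far outside the diverging field
  expect_identical(max(r$grid$dose[1:3, , 1:3]), 0)
  expect_identical(max(r$grid$dose[14:16, , 14:16]), 0)
  expect_gt(max(r$grid$dose[8, , 8]), 0)
})

test_that("identical seeds and inputs give bit-identical outputs", {
  a <- run_split_field(4000, 2, 77, work_tag = "det1")
  b <- run_split_field(4000, 2, 77, work_tag = "det2")
  for (i in 1:2) {
    fa <- file.path(a$items$bound_dir[i], "dose.bin")
    fb <- file.path(b$items$bound_dir[i], "dose.bin")
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
  }
})

test_that("degenerate inputs are rejected or flagged", {
  ts <- toy_setup()
  beams <- open_field_beam()
  items <- distribute_work(beams, 1, "EQUAL", 100, master_seed = 1)
  wd <- file.path(withr::local_tempdir(), "deg")
  items <- bind_work_items(ts$model, beams, items, wd, ts$phantom_path)
  # zero histories
  eng <- readLines(file.path(items$bound_dir[1], "engine.in"))
  eng[1] <- "NHIST      0"
  writeLines(eng, file.path(items$bound_dir[1], "engine.in"))
  expect_error(toy_mc_run(items$bound_dir[1]), class = "rtmc_format_error")
  # closed aperture: zero dose with a warning
  eng[1] <- "NHIST      100"
  writeLines(eng, file.path(items$bound_dir[1], "engine.in"))
  bm <- readLines(file.path(items$bound_dir[1], "beam.in"))
  bm[6] <- paste("MLCA", paste(rep("0.0", 20), collapse = " "))
  bm[7] <- paste("MLCB", paste(rep("0.0", 20), collapse = " "))
  writeLines(bm, file.path(items$bound_dir[1], "beam.in"))
  expect_warning(r <- toy_mc_run(items$bound_dir[1]), "closed")
  expect_identical(max(r$grid$dose), 0)
})

test_that("closed-form depth dose behaves at its limits", {
  cfg <- list(mu_attenuation_cm2_g = 0.05, density_g_cm3 = 1.0)
  d <- c(0, 2, 4, 8)
  a <- analytic_depth_dose(d, cfg)
  expect_identical(which.max(a), 1L)                       # maximal at surface
  expect_equal(a[2] / a[3], exp(0.05 * 1.0 * 2))           # ratio closed form
  flat <- analytic_depth_dose(d, list(mu_attenuation_cm2_g = 0, density_g_cm3 = 1))
  expect_true(all(flat == 1))                              # mu = 0 limit
  het <- water_phantom()
  het$density[1] <- 2
  expect_error(analytic_depth_dose(1, cfg, phantom = het), "heterogeneous")
})

test_that("engine converges to the analytic depth dose within 3 sigma", {
  g <- run_one_field(1e5, 31, "conv")
  prof <- g$dose[8, , 8]
  sprof <- g$sigma[8, , 8]
  depth_cm <- seq_len(16) - 0.5
  # source at 1000 mm from iso, iso at phantom center (depth 8 cm)
  an <- analytic_depth_dose(depth_cm,
                            list(mu_attenuation_cm2_g = 0.05,
                                 density_g_cm3 = 1.0, ssd_cm = 100 - 8))
  i0 <- 3
  ratio_mc <- prof / prof[i0]
  ratio_an <- an / an[i0]
  s_ratio <- sqrt((sprof / prof[i0])^2 + (prof * sprof[i0] / prof[i0]^2)^2)
  z <- (ratio_mc - ratio_an) / s_ratio
  expect_true(all(abs(z[-i0]) < 3))
})

test_that("quadrupling histories roughly halves the relative uncertainty", {
  g1 <- run_one_field(4000, 41, "u1")
  g4 <- run_one_field(16000, 42, "u4")
  r <- region_uncertainty(g4, k = 2) / region_uncertainty(g1, k = 2)
  expect_gt(r, 0.5 * 0.85)
  expect_lt(r, 0.5 * 1.15)
})

test_that("deposited energy never exceeds the source energy", {
  g <- run_one_field(5000, 51, "energy")
  # water at 1 g/cm3, 1 cm3 voxels: mass = 1 g per voxel
  deposited_per_history <- sum(g$dose) * 1.0
  expect_lte(deposited_per_history, 1.0)   # energy_per_history = 1
  expect_gt(deposited_per_history, 0.2)
})

test_that("exit phase space records leave the far side of the phantom", {
  base <- withr::local_tempdir()
  pp <- file.path(base, "w.penvox")
  write_penvox(water_phantom(), pp)
  mf <- create_toy_model(file.path(base, "model"), emit_phsp = TRUE)
  model <- load_model(mf)
  beams <- open_field_beam()
  items <- distribute_work(beams, 1, "EQUAL", 2000, master_seed = 13)
  items <- bind_work_items(model, beams, items, file.path(base, "w"), pp)
  r <- toy_mc_run(items$bound_dir[1])
  expect_false(is.null(r$phsp_file))
  ph <- read_phsp(r$phsp_file)
  expect_equal(ph$n_original_histories, 2000)
  expect_gt(ph$n_particles, 0)
  # beam travels +y from gantry 0: survivors exit at the far y face
  expect_true(all(ph$records$y_mm >= 80 - 1e-6))
  nrm <- with(ph$records, sqrt(u^2 + v^2 + w^2))
  expect_true(all(abs(nrm - 1) < 1e-5))
})
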