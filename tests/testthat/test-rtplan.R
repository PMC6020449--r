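# RT plan parsing, technique classification, and discretization

# hand-built two-segment step-and-shoot beam with known weights
two_segment_plan_file <- function(path, dweights = c(0.25, 0.75), meterset = 200) {
  lb <- seq(-100, 100, by = 10)
  banks <- rtmc:::.aperture_banks(-30, 30, -30, 30, lb)
  bld <- rtmc:::.bld_items(c(-40, 40, -40, 40), banks)
  cum <- cumsum(c(0, dweights))
  cps <- list()
  for (s in seq_along(dweights)) {
    first <- rtmc:::dcm_dataset(
      ControlPointIndex = as.integer(2 * s - 2),
      CumulativeMetersetWeight = cum[s],
      BeamLimitingDevicePositionSequence = bld)
    if (s == 1) {
      first <- rtmc:::dcm_set(first, "GantryAngle", 90)
      first <- rtmc:::dcm_set(first, "IsocenterPosition", c(0, 0, 0))
    }
    cps[[2 * s - 1]] <- first
    cps[[2 * s]] <- rtmc:::dcm_dataset(
      ControlPointIndex = as.integer(2 * s - 1),
      CumulativeMetersetWeight = cum[s + 1])
  }
  ds <- rtmc:::dcm_dataset(
    SOPClassUID = rtmc:::SOP_RTPLAN, SOPInstanceUID = rtmc:::dcm_uid(77, 1),
    Modality = "RTPLAN", PatientID = "T1",
    FractionGroupSequence = list(rtmc:::dcm_dataset(
      NumberOfFractionsPlanned = 1L,
      ReferencedBeamSequence = list(rtmc:::dcm_dataset(
        ReferencedBeamNumber = 1L, BeamMeterset = meterset)))),
    BeamSequence = list(rtmc:::dcm_dataset(
      BeamNumber = 1L, BeamName = "b1",
      NumberOfControlPoints = length(cps), ControlPointSequence = cps)))
  rtmc:::dcm_write(ds, path)
  path
}

test_that("segment MU is delta weight times beam meterset", {
  f <- withr::local_tempfile(fileext = ".dcm")
  two_segment_plan_file(f, dweights = c(0.25, 0.75), meterset = 200)
  plan <- parse_rtplan(f)
  expect_identical(plan$technique, "STEP_AND_SHOOT")
  expect_equal(plan$segments$mu, c(50, 150))
  expect_equal(plan$total_mu, 200)
})

test_that("fixture plans parse with the documented segment counts", {
  base <- withr::local_tempdir()
  sns <- fixture_spec("STEP_AND_SHOOT_PROSTATE", seed = 3)
  make_plan(sns, file.path(base, "sns.dcm"))
  p <- parse_rtplan(file.path(base, "sns.dcm"))
  expect_identical(p$technique, "STEP_AND_SHOOT")
  expect_identical(nrow(p$segments), 25L)
  expect_length(unique(p$segments$gantry_start_deg), 7)

  st <- fixture_spec("STATIC_SBRT_LUNG", seed = 3)
  make_plan(st, file.path(base, "st.dcm"))
  ps <- parse_rtplan(file.path(base, "st.dcm"))
  expect_identical(ps$technique, "STATIC")
  expect_identical(nrow(ps$segments), 9L)

  ma <- fixture_spec("MARC_HN", seed = 3)
  make_plan(ma, file.path(base, "ma.dcm"))
  pm <- parse_rtplan(file.path(base, "ma.dcm"))
  expect_identical(pm$technique, "MARC")
  expect_identical(nrow(pm$segments), 45L)
})

test_that("static single-segment plan carries its meterset as total MU", {
  f <- withr::local_tempfile(fileext = ".dcm")
  two_segment_plan_file(f, dweights = 1, meterset = 100)
  plan <- parse_rtplan(f)
  expect_identical(plan$technique, "STATIC")
  expect_equal(plan$total_mu, 100)
  beams <- discretize_plan(plan)
  expect_identical(nrow(beams), 1L)
  expect_equal(beams$mu, 100)
})

test_that("mArc arclets become static beams at their central angles", {
  base <- withr::local_tempdir()
  spec <- fixture_spec("MARC_HN", n_arclets = 3, seed = 5)
  make_plan(spec, file.path(base, "m3.dcm"))
  plan <- parse_rtplan(file.path(base, "m3.dcm"))
  beams <- discretize_plan(plan)
  expect_identical(nrow(beams), 3L)
  expect_equal(beams$gantry_deg, c(0, 8, 16))
  # the full-circle 45-arclet fixture conserves MU to the last bit
  spec45 <- fixture_spec("MARC_HN", seed = 6)
  make_plan(spec45, file.path(base, "m45.dcm"))
  p45 <- parse_rtplan(file.path(base, "m45.dcm"))
  b45 <- discretize_plan(p45)
  expect_identical(nrow(b45), 45L)
  expect_identical(sum(b45$mu), p45$total_mu)
})

test_that("circular midpoints wrap correctly across zero", {
  expect_equal(rtmc:::arc_central_angle(358, 2), 0)
  expect_equal(rtmc:::arc_central_angle(90, 94), 92)
  expect_equal(rtmc:::arc_central_angle(350, 10), 0)
})

test_that("discretization is idempotent on a rebuilt plan", {
  base <- withr::local_tempdir()
  spec <- fixture_spec("STEP_AND_SHOOT_PROSTATE", seed = 9)
  make_plan(spec, file.path(base, "p.dcm"))
  beams <- discretize_plan(parse_rtplan(file.path(base, "p.dcm")))
  again <- discretize_plan(plan_from_beams(beams))
  expect_equal(again$gantry_deg, beams$gantry_deg)
  expect_equal(again$mu, beams$mu)
  expect_equal(again$mlc_a_mm, beams$mlc_a_mm)
  expect_equal(again$jaw_x1_mm, beams$jaw_x1_mm)
})

test_that("malformed plans raise typed errors", {
  f <- withr::local_tempfile(fileext = ".dcm")
  # wrong modality
  ds <- rtmc:::dcm_dataset(SOPClassUID = rtmc:::SOP_CT,
                           SOPInstanceUID = rtmc:::dcm_uid(1, 1),
                           Modality = "CT")
  rtmc:::dcm_write(ds, f)
  expect_error(parse_rtplan(f), class = "rtmc_format_error")
  # missing MLC in first control point
  ds2 <- rtmc:::dcm_dataset(
    SOPClassUID = rtmc:::SOP_RTPLAN, SOPInstanceUID = rtmc:::dcm_uid(1, 2),
    Modality = "RTPLAN",
    BeamSequence = list(rtmc:::dcm_dataset(
      BeamNumber = 1L, NumberOfControlPoints = 2L,
      ControlPointSequence = list(
        rtmc:::dcm_dataset(ControlPointIndex = 0L, CumulativeMetersetWeight = 0,
                           GantryAngle = 0),
        rtmc:::dcm_dataset(ControlPointIndex = 1L, CumulativeMetersetWeight = 1)))))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  rtmc:::dcm_write(ds2, f2)
  expect_error(parse_rtplan(f2), "011A|011C|jaw", class = "rtmc_plan_content_error")
})

test_that("aperture motion during beam-on is an unsupported technique", {
  lb <- seq(-100, 100, by = 10)
  mk_bld <- function(x) rtmc:::.bld_items(c(-40, 40, -40, 40),
                                          rtmc:::.aperture_banks(-x, x, -30, 30, lb))
  cps <- list(
    local({
      cp <- rtmc:::dcm_dataset(ControlPointIndex = 0L, CumulativeMetersetWeight = 0,
                               GantryAngle = 10,
                               BeamLimitingDevicePositionSequence = mk_bld(30))
      cp <- rtmc:::dcm_set(cp, "IsocenterPosition", c(0, 0, 0))
      cp
    }),
    rtmc:::dcm_dataset(ControlPointIndex = 1L, CumulativeMetersetWeight = 0.5,
                       GantryAngle = 20,
                       BeamLimitingDevicePositionSequence = mk_bld(20)),
    rtmc:::dcm_dataset(ControlPointIndex = 2L, CumulativeMetersetWeight = 1,
                       GantryAngle = 30,
                       BeamLimitingDevicePositionSequence = mk_bld(10)))
  ds <- rtmc:::dcm_dataset(
    SOPClassUID = rtmc:::SOP_RTPLAN, SOPInstanceUID = rtmc:::dcm_uid(2, 1),
    Modality = "RTPLAN",
    FractionGroupSequence = list(rtmc:::dcm_dataset(
      ReferencedBeamSequence = list(rtmc:::dcm_dataset(
        ReferencedBeamNumber = 1L, BeamMeterset = 100)))),
    BeamSequence = list(rtmc:::dcm_dataset(
      BeamNumber = 1L, NumberOfControlPoints = 3L, ControlPointSequence = cps)))
  f <- withr::local_tempfile(fileext = ".dcm")
  rtmc:::dcm_write(ds, f)
  expect_error(parse_rtplan(f), class = "rtmc_unsupported_technique")
})

test_that("beam JSON round-trips the static-beam schema", {
  base <- withr::local_tempdir()
  spec <- fixture_spec("STATIC_SBRT_LUNG", seed = 4)
  make_plan(spec, file.path(base, "p.dcm"))
  beams <- discretize_plan(parse_rtplan(file.path(base, "p.dcm")))
  f <- file.path(base, "beams.json")
  write_beams_json(beams, f)
  back <- read_beams_json(f)
  expect_equal(back$mu, beams$mu)
  expect_equal(back$mlc_a_mm, beams$mlc_a_mm)
  expect_equal(attr(back, "leaf_bounds_mm"), attr(beams, "leaf_bounds_mm"))
})
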