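# ---------------------------------------------------------------------------
# Synthetic DICOM fixtures: seed-deterministic CT series, RT plans for the
# three delivery techniques, and structure sets, at desk-scale resolution.
# Anatomy is geometric (cylinders), not anthropomorphic: a water cylinder in
# air, with a bone insert (and a lung-like insert for the SBRT case).  All
# randomness flows through a local RNG scope seeded from the spec, and UIDs
# derive from the seed, so identical specs give byte-identical files.
# ---------------------------------------------------------------------------

#' Fixture specification
#'
#' @param case_kind `"MARC_HN"`, `"STEP_AND_SHOOT_PROSTATE"` or
#'   `"STATIC_SBRT_LUNG"`
#' @param dims CT dims (default 32 x 32 x 16; must stay desk scale, <= 64^3)
#' @param spacing_mm voxel spacing (default 4 x 4 x 5 mm)
#' @param n_arclets mArc arclet count (default 45: 4-degree arclets every 8
#'   degrees around the full circle)
#' @param n_segments step-and-shoot segment count (default 25, spread over 7
#'   gantry incidences)
#' @param n_beams static beam count (default 9)
#' @param seed integer driving all fixture randomness and UIDs
#' @return an `rtmc_fixture_spec`
#' @export
fixture_spec <- function(case_kind = c("MARC_HN", "STEP_AND_SHOOT_PROSTATE",
                                       "STATIC_SBRT_LUNG"),
                         dims = c(32, 32, 16), spacing_mm = c(4, 4, 5),
                         n_arclets = 45, n_segments = 25, n_beams = 9,
                         seed = 1L) {
  case_kind <- match.arg(case_kind)
  stopifnot(all(dims <= 64), all(dims >= 1), all(spacing_mm > 0))
  structure(list(case_kind = case_kind, dims = as.integer(dims),
                 spacing_mm = as.numeric(spacing_mm),
                 n_arclets = as.integer(n_arclets),
                 n_segments = as.integer(n_segments),
                 n_beams = as.integer(n_beams), seed = as.integer(seed)),
            class = "rtmc_fixture_spec")
}

# evaluate expr with a private RNG stream seeded from the spec
.with_fixture_rng <- function(spec, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  force(expr)
}

.fixture_center_mm <- function(spec) {
  # origin at 0: center of the volume
  (spec$dims - 1) * spec$spacing_mm / 2
}

#' Generate a synthetic CT series
#'
#' A water cylinder (HU 0) along z in air (HU -1000), with a bone insert
#' (HU 800) and, for the lung case, a low-density insert (HU -700).  HU
#' values are exact by construction.
#'
#' @param spec an `rtmc_fixture_spec`
#' @param dir output directory for the slice files (created)
#' @return `dir`, invisibly; slices are `ct_0001.dcm`, ...
#' @export
make_ct <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- spec$dims; sp <- spec$spacing_mm
  ctr <- .fixture_center_mm(spec)
  xc <- (seq_len(d[1]) - 1) * sp[1]
  yc <- (seq_len(d[2]) - 1) * sp[2]
  r2 <- outer((xc - ctr[1])^2, (yc - ctr[2])^2, `+`)
  extent_xy <- min(d[1] * sp[1], d[2] * sp[2])
  r_water <- 0.40 * extent_xy
  hu2d <- matrix(-1000, d[1], d[2])
  hu2d[r2 <= r_water^2] <- 0
  # bone insert: small cylinder off-center
  bone2 <- outer((xc - ctr[1] - 0.15 * extent_xy)^2, (yc - ctr[2])^2, `+`)
  hu2d[bone2 <= (0.08 * extent_xy)^2] <- 800
  if (spec$case_kind == "STATIC_SBRT_LUNG") {
    lung2 <- outer((xc - ctr[1] + 0.18 * extent_xy)^2, (yc - ctr[2])^2, `+`)
    hu2d[lung2 <= (0.12 * extent_xy)^2 & hu2d == 0] <- -700
  }
  study_uid <- dcm_uid(spec$seed, 1)
  series_uid <- dcm_uid(spec$seed, 2)
  frame_uid <- dcm_uid(spec$seed, 9)
  for (k in seq_len(d[3])) {
    stored <- as.integer(hu2d + 1024)   # RescaleIntercept -1024, slope 1
    ds <- dcm_dataset(
      SOPClassUID = SOP_CT,
      SOPInstanceUID = dcm_uid(spec$seed, 100, k),
      Modality = "CT",
      PatientID = sprintf("FIX-%s", spec$case_kind),
      PatientName = "Fixture^Synthetic",
      StudyInstanceUID = study_uid, SeriesInstanceUID = series_uid,
      FrameOfReferenceUID = frame_uid,
      InstanceNumber = k,
      ImagePositionPatient = c(0, 0, (k - 1) * sp[3]),
      ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
      SliceThickness = sp[3],
      SamplesPerPixel = 1L, PhotometricInterpretation = "MONOCHROME2",
      Rows = d[2], Columns = d[1],
      PixelSpacing = c(sp[2], sp[1]),
      BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L,
      PixelRepresentation = 0L,
      RescaleIntercept = -1024, RescaleSlope = 1,
      PixelData = writeBin(stored, raw(), size = 2, endian = "little"))
    dcm_write(ds, file.path(dir, sprintf("ct_%04d.dcm", k)))
  }
  invisible(dir)
}

# MLC geometry shared by all fixture plans: 20 leaf pairs, 10 mm at iso
.fixture_leaf_bounds <- function() seq(-100, 100, by = 10)

# a rectangular aperture opening expressed as MLC bank positions
.aperture_banks <- function(x1, x2, y1, y2, leaf_bounds) {
  n <- length(leaf_bounds) - 1
  a <- rep(0, n); b <- rep(0, n)   # closed leaves meet at 0
  open <- leaf_bounds[-length(leaf_bounds)] < y2 & leaf_bounds[-1] > y1
  a[open] <- x1; b[open] <- x2
  list(a = a, b = b)
}

.bld_items <- function(jaws, banks) {
  list(
    dcm_dataset(RTBeamLimitingDeviceType = "ASYMX",
                LeafJawPositions = jaws[1:2]),
    dcm_dataset(RTBeamLimitingDeviceType = "ASYMY",
                LeafJawPositions = jaws[3:4]),
    dcm_dataset(RTBeamLimitingDeviceType = "MLCX",
                LeafJawPositions = c(banks$a, banks$b)))
}

#' Generate a synthetic DICOM RT plan
#'
#' Control-point encoding follows the package's documented contract (see
#' [parse_rtplan()]): deliverable segments are maximal runs of nonzero
#' meterset-weight increments.
#' * `MARC_HN`: one rotational beam with `n_arclets` 4-degree arclets whose
#'   central angles are 8 degrees apart.
#' * `STEP_AND_SHOOT_PROSTATE`: `n_segments` segments distributed over 7
#'   gantry incidences with per-segment MLC apertures.
#' * `STATIC_SBRT_LUNG`: `n_beams` single-segment conformal beams.
#' Per-segment weights are random (seeded by the spec).
#'
#' @param spec an `rtmc_fixture_spec`
#' @param path output RTPLAN file
#' @return `path`, invisibly
#' @export
make_plan <- function(spec, path) {
  .with_fixture_rng(spec, {
    ctr <- .fixture_center_mm(spec)
    lb <- .fixture_leaf_bounds()
    total_mu <- round(stats::runif(1, 150, 350), 1)
    beams <- switch(spec$case_kind,
      MARC_HN = .marc_beams(spec, ctr, lb, total_mu),
      STEP_AND_SHOOT_PROSTATE = .sns_beams(spec, ctr, lb, total_mu),
      STATIC_SBRT_LUNG = .static_beams(spec, ctr, lb, total_mu))
    ref <- lapply(beams$meterset_by_beam, function(x)
      dcm_dataset(ReferencedBeamNumber = x$number, BeamMeterset = x$meterset))
    ds <- dcm_dataset(
      SOPClassUID = SOP_RTPLAN,
      SOPInstanceUID = dcm_uid(spec$seed, 300),
      Modality = "RTPLAN",
      RTPlanLabel = sprintf("FIX_%s", spec$case_kind),
      PatientID = sprintf("FIX-%s", spec$case_kind),
      PatientName = "Fixture^Synthetic",
      StudyInstanceUID = dcm_uid(spec$seed, 1),
      SeriesInstanceUID = dcm_uid(spec$seed, 3),
      FrameOfReferenceUID = dcm_uid(spec$seed, 9),
      FractionGroupSequence = list(
        dcm_dataset(NumberOfFractionsPlanned = 1L, ReferencedBeamSequence = ref)),
      BeamSequence = beams$beam_items)
    dcm_write(ds, path)
  })
  invisible(path)
}

.beam_level_mlc <- function(lb) {
  list(dcm_dataset(RTBeamLimitingDeviceType = "MLCX",
                   NumberOfLeafJawPairs = length(lb) - 1L,
                   LeafPositionBoundaries = lb))
}

# random weights summing to 1, rounded to 6 decimals with remainder on last
.random_weights <- function(n) {
  w <- stats::runif(n, 0.5, 1.5)
  w <- w / sum(w)
  w <- round(w, 6)
  w[n] <- 1 - sum(w[-n])
  w
}

.marc_beams <- function(spec, ctr, lb, total_mu) {
  n <- spec$n_arclets
  width <- 4
  centers <- (seq_len(n) - 1) * 8
  dw <- .random_weights(n)
  cum <- cumsum(c(0, dw))
  cps <- list()
  jaws <- c(-40, 40, -40, 40)
  banks <- .aperture_banks(-30, 30, -30, 30, lb)
  for (j in seq_len(n)) {
    start <- (centers[j] - width / 2) %% 360
    end <- (centers[j] + width / 2) %% 360
    first <- dcm_dataset(
      ControlPointIndex = as.integer(2 * j - 2),
      CumulativeMetersetWeight = cum[j],
      GantryAngle = start,
      BeamLimitingDevicePositionSequence = .bld_items(jaws, banks))
    if (j == 1) {
      first <- dcm_set(first, "BeamLimitingDeviceAngle", 0)
      first <- dcm_set(first, "PatientSupportAngle", 0)
      first <- dcm_set(first, "IsocenterPosition", ctr)
    }
    cps[[2 * j - 1]] <- first
    cps[[2 * j]] <- dcm_dataset(
      ControlPointIndex = as.integer(2 * j - 1),
      CumulativeMetersetWeight = cum[j + 1],
      GantryAngle = end)
  }
  beam <- dcm_dataset(
    BeamNumber = 1L, BeamName = "mArc1", BeamType = "DYNAMIC",
    RadiationType = "PHOTON",
    BeamLimitingDeviceSequence = .beam_level_mlc(lb),
    NumberOfControlPoints = length(cps),
    ControlPointSequence = cps)
  list(beam_items = list(beam),
       meterset_by_beam = list(list(number = 1L, meterset = total_mu)))
}

.sns_beams <- function(spec, ctr, lb, total_mu) {
  n_inc <- 7L
  gantries <- round((seq_len(n_inc) - 1) * 360 / n_inc, 1)
  seg_per <- rep(spec$n_segments %/% n_inc, n_inc)
  extra <- spec$n_segments - sum(seg_per)
  if (extra > 0) seg_per[seq_len(extra)] <- seg_per[seq_len(extra)] + 1L
  mu_beam <- .random_weights(n_inc) * total_mu
  beam_items <- list(); meters <- list()
  for (b in seq_len(n_inc)) {
    ns <- seg_per[b]
    dw <- .random_weights(ns)
    cum <- cumsum(c(0, dw))
    jaws <- c(-45, 45, -45, 45)
    cps <- list()
    for (s in seq_len(ns)) {
      half <- 30 - 4 * (s - 1)   # shrinking aperture per segment
      banks <- .aperture_banks(-half, half, -half, half, lb)
      first <- dcm_dataset(
        ControlPointIndex = as.integer(2 * s - 2),
        CumulativeMetersetWeight = cum[s],
        BeamLimitingDevicePositionSequence = .bld_items(jaws, banks))
      if (s == 1) {
        first <- dcm_set(first, "GantryAngle", gantries[b])
        first <- dcm_set(first, "BeamLimitingDeviceAngle", 0)
        first <- dcm_set(first, "PatientSupportAngle", 0)
        first <- dcm_set(first, "IsocenterPosition", ctr)
      }
      cps[[2 * s - 1]] <- first
      cps[[2 * s]] <- dcm_dataset(
        ControlPointIndex = as.integer(2 * s - 1),
        CumulativeMetersetWeight = cum[s + 1])
    }
    beam_items[[b]] <- dcm_dataset(
      BeamNumber = as.integer(b), BeamName = sprintf("IMRT%d", b),
      BeamType = "STATIC", RadiationType = "PHOTON",
      BeamLimitingDeviceSequence = .beam_level_mlc(lb),
      NumberOfControlPoints = length(cps),
      ControlPointSequence = cps)
    meters[[b]] <- list(number = as.integer(b), meterset = mu_beam[b])
  }
  list(beam_items = beam_items, meterset_by_beam = meters)
}

.static_beams <- function(spec, ctr, lb, total_mu) {
  n <- spec$n_beams
  gantries <- round((seq_len(n) - 1) * 360 / n, 1)
  mu_beam <- .random_weights(n) * total_mu
  beam_items <- list(); meters <- list()
  for (b in seq_len(n)) {
    jaws <- c(-35, 35, -35, 35)
    banks <- .aperture_banks(-25, 25, -25, 25, lb)
    cps <- list(
      dcm_dataset(
        ControlPointIndex = 0L, CumulativeMetersetWeight = 0,
        GantryAngle = gantries[b], BeamLimitingDeviceAngle = 0,
        PatientSupportAngle = 0, IsocenterPosition = ctr,
        BeamLimitingDevicePositionSequence = .bld_items(jaws, banks)),
      dcm_dataset(ControlPointIndex = 1L, CumulativeMetersetWeight = 1))
    beam_items[[b]] <- dcm_dataset(
      BeamNumber = as.integer(b), BeamName = sprintf("SBRT%d", b),
      BeamType = "STATIC", RadiationType = "PHOTON",
      BeamLimitingDeviceSequence = .beam_level_mlc(lb),
      NumberOfControlPoints = 2L,
      ControlPointSequence = cps)
    meters[[b]] <- list(number = as.integer(b), meterset = mu_beam[b])
  }
  list(beam_items = beam_items, meterset_by_beam = meters)
}

#' Generate a synthetic DICOM RT structure set
#'
#' A cylindrical PTV centered on the CT axis (radius 0.2 of the in-plane
#' extent, spanning the central half of the slices; analytic volume
#' `pi r^2 h`) plus a BODY contour at the water cylinder surface.
#'
#' @param spec an `rtmc_fixture_spec`
#' @param path output RTSTRUCT file
#' @param n_vertices polygon vertices per contour
#' @return `path`, invisibly; attribute `ptv_volume_cm3` carries the
#'   analytic PTV volume
#' @export
make_structset <- function(spec, path, n_vertices = 64) {
  d <- spec$dims; sp <- spec$spacing_mm
  ctr <- .fixture_center_mm(spec)
  extent_xy <- min(d[1] * sp[1], d[2] * sp[2])
  r_ptv <- 0.20 * extent_xy
  r_body <- 0.40 * extent_xy
  kz <- seq_len(d[3])
  zc <- (kz - 1) * sp[3]
  ptv_k <- kz[abs(zc - ctr[3]) <= d[3] * sp[3] / 4]
  ang <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  circle <- function(r, z) {
    cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang), z)
  }
  contour_item <- function(m) {
    dcm_dataset(ContourGeometricType = "CLOSED_PLANAR",
                NumberOfContourPoints = nrow(m),
                ContourData = as.numeric(t(m)))
  }
  ptv_contours <- lapply(zc[ptv_k], function(z) contour_item(circle(r_ptv, z)))
  body_contours <- lapply(zc, function(z) contour_item(circle(r_body, z)))
  ds <- dcm_dataset(
    SOPClassUID = SOP_RTSTRUCT,
    SOPInstanceUID = dcm_uid(spec$seed, 400),
    Modality = "RTSTRUCT",
    StructureSetLabel = "FIXTURE",
    PatientID = sprintf("FIX-%s", spec$case_kind),
    PatientName = "Fixture^Synthetic",
    StudyInstanceUID = dcm_uid(spec$seed, 1),
    SeriesInstanceUID = dcm_uid(spec$seed, 4),
    FrameOfReferenceUID = dcm_uid(spec$seed, 9),
    StructureSetROISequence = list(
      dcm_dataset(ROINumber = 1L, ROIName = "PTV"),
      dcm_dataset(ROINumber = 2L, ROIName = "BODY")),
    ROIContourSequence = list(
      dcm_dataset(ReferencedROINumber = 1L, ContourSequence = ptv_contours),
      dcm_dataset(ReferencedROINumber = 2L, ContourSequence = body_contours)))
  dcm_write(ds, path)
  out <- invisible(path)
  attr(out, "ptv_volume_cm3") <- pi * (r_ptv / 10)^2 * (length(ptv_k) * sp[3] / 10)
  out
}

#' Generate the complete fixture set for a case
#'
#' @param spec an `rtmc_fixture_spec`
#' @param dir output directory; creates `ct/`, `plan.dcm`, `structs.dcm`
#' @return list of paths
#' @export
make_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ct_dir <- file.path(dir, "ct")
  make_ct(spec, ct_dir)
  plan <- make_plan(spec, file.path(dir, "plan.dcm"))
  ss <- make_structset(spec, file.path(dir, "structs.dcm"))
  list(ct_dir = ct_dir, plan = file.path(dir, "plan.dcm"),
       structs = file.path(dir, "structs.dcm"),
       ptv_volume_cm3 = attr(ss, "ptv_volume_cm3"))
}
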