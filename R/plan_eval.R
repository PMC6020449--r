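# ---------------------------------------------------------------------------
# Plan evaluation: DICOM RTDOSE export/import, RTSTRUCT contour reading,
# voxel-center rasterization with the even-odd parity rule, cumulative DVHs
# and dose metrics.
# ---------------------------------------------------------------------------

SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"

#' Export a dose grid as DICOM RTDOSE
#'
#' Dose is scaled to 32-bit unsigned pixels with
#' `DoseGridScaling = max(dose_gy) / (2^32 - 1)` (or `scaling_floor` for an
#' all-zero grid), so the read-back quantization error is at most one
#' scaling step per voxel.
#'
#' @param grid an `rtmc_dose_grid` (per-history dose)
#' @param path output file
#' @param mu_scale multiplicative calibration from per-history dose to Gy
#'   (Gy-per-history-unit times delivered MU); a single config constant
#' @param ct_reference optional `rtmc_volume` or list with `frame_uid` /
#'   `patient_id`, copied into the geometry reference tags
#' @param scaling_floor DoseGridScaling used when the grid is all zero
#' @param seed integer from which the instance UIDs derive
#' @return `path`, invisibly
#' @export
export_rtdose <- function(grid, path, mu_scale = 1, ct_reference = NULL,
                          scaling_floor = 1e-9, seed = 1L) {
  stopifnot(inherits(grid, "rtmc_dose_grid"))
  dose_gy <- grid$dose * mu_scale
  if (any(!is.finite(dose_gy)) || any(dose_gy < 0)) {
    abort("dose must be finite and nonnegative for RTDOSE export",
          class = "rtmc_export_error")
  }
  dmax <- max(dose_gy)
  scaling <- if (dmax > 0) dmax / (2^32 - 1) else scaling_floor
  px <- round(dose_gy / scaling)
  d <- grid$dims
  # frame-major, row-major pixels: x fastest within a row, rows along y
  v <- as.numeric(px)
  v <- ifelse(v > 2147483647, v - 4294967296, v)
  pixel_raw <- writeBin(as.integer(v), raw(), size = 4, endian = "little")
  frame_uid <- if (is.list(ct_reference)) ct_reference$frame_uid %||% dcm_uid(seed, 9) else dcm_uid(seed, 9)
  patient_id <- if (is.list(ct_reference)) ct_reference$patient_id %||% "ANON" else "ANON"
  ds <- dcm_dataset(
    SOPClassUID = SOP_RTDOSE,
    SOPInstanceUID = dcm_uid(seed, 481, 2),
    Modality = "RTDOSE",
    PatientID = patient_id,
    StudyInstanceUID = dcm_uid(seed, 1),
    SeriesInstanceUID = dcm_uid(seed, 481, 20),
    FrameOfReferenceUID = frame_uid,
    ImagePositionPatient = grid$origin_mm,
    ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
    SamplesPerPixel = 1L,
    PhotometricInterpretation = "MONOCHROME2",
    NumberOfFrames = d[3],
    Rows = d[2], Columns = d[1],
    PixelSpacing = c(grid$spacing_mm[2], grid$spacing_mm[1]),
    BitsAllocated = 32L, BitsStored = 32L, HighBit = 31L,
    PixelRepresentation = 0L,
    DoseUnits = "GY", DoseType = "PHYSICAL", DoseSummationType = "PLAN",
    GridFrameOffsetVector = (seq_len(d[3]) - 1) * grid$spacing_mm[3],
    DoseGridScaling = scaling,
    PixelData = pixel_raw)
  dcm_write(ds, path)
  invisible(path)
}

#' Read a DICOM RTDOSE file into a dose grid
#'
#' Dose is `pixel * DoseGridScaling`; geometry comes from
#' ImagePositionPatient / PixelSpacing / GridFrameOffsetVector.  Both a
#' full-length per-frame offset vector and the two-element uniform-offset
#' shorthand are accepted.  RTDOSE carries no uncertainty: sigma is zero
#' with attribute `sigma_missing = TRUE`.
#'
#' @param path RTDOSE file
#' @return an `rtmc_dose_grid` (unit "Gy")
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read(path)
  if (!identical(dcm_get(ds, "Modality", ""), "RTDOSE")) {
    abort("not an RTDOSE dataset", class = "rtmc_format_error")
  }
  gfov <- dcm_get(ds, "GridFrameOffsetVector")
  if (is.null(gfov)) {
    abort("missing GridFrameOffsetVector (3004,000C)", class = "rtmc_format_error")
  }
  nx <- dcm_get(ds, "Columns"); ny <- dcm_get(ds, "Rows")
  nz <- as.integer(dcm_get(ds, "NumberOfFrames", 1))
  if (length(gfov) == nz) {
    dz <- if (nz > 1) mean(diff(gfov)) else 1
  } else if (length(gfov) == 2) {
    dz <- diff(gfov)  # uniform-offset shorthand
  } else {
    abort("GridFrameOffsetVector length matches neither frames nor 2",
          class = "rtmc_format_error")
  }
  ps <- dcm_get(ds, "PixelSpacing")
  scaling <- dcm_get(ds, "DoseGridScaling", 1)
  px <- readBin(dcm_get(ds, "PixelData"), "integer", n = nx * ny * nz,
                size = 4, endian = "little")
  px <- ifelse(px < 0, as.numeric(px) + 4294967296, as.numeric(px))
  dose <- array(px * scaling, dim = c(nx, ny, nz))
  ipp <- dcm_get(ds, "ImagePositionPatient")
  g <- dose_grid(dose, array(0, dim = dim(dose)),
                 spacing_mm = c(ps[2], ps[1], dz), origin_mm = ipp,
                 histories = 1, unit = "Gy")
  attr(g, "sigma_missing") <- TRUE
  g
}

#' Read a DICOM RT structure set
#'
#' @param path RTSTRUCT file
#' @return an `rtmc_structset`: named list of structures; each structure is
#'   a list of closed planar contours, `n x 3` matrices (x, y, z in mm,
#'   constant z per contour)
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_read(path)
  if (!identical(dcm_get(ds, "Modality", ""), "RTSTRUCT")) {
    abort("not an RTSTRUCT dataset", class = "rtmc_format_error")
  }
  rois <- dcm_get(ds, "StructureSetROISequence") %||% list()
  names_by_num <- list()
  for (r in rois) {
    names_by_num[[as.character(dcm_get(r, "ROINumber"))]] <- dcm_get(r, "ROIName")
  }
  out <- list()
  for (rc in dcm_get(ds, "ROIContourSequence") %||% list()) {
    num <- as.character(dcm_get(rc, "ReferencedROINumber"))
    nm <- names_by_num[[num]] %||% paste0("ROI", num)
    contours <- lapply(dcm_get(rc, "ContourSequence") %||% list(), function(cs) {
      cd <- dcm_get(cs, "ContourData")
      matrix(cd, ncol = 3, byrow = TRUE)
    })
    out[[nm]] <- contours
  }
  structure(out, class = "rtmc_structset")
}

.validate_structure <- function(contours) {
  if (length(contours) == 0) abort("structure has no contours",
                                   class = "rtmc_evaluation_error")
  for (m in contours) {
    if (nrow(m) < 3) abort("contour with fewer than 3 vertices")
    if (diff(range(m[, 3])) > 1e-3) abort("contour vertices not coplanar in z")
  }
  invisible(contours)
}

# even-odd crossing test, vectorized over points
.pip_even_odd <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xj <- c(xs[n], xs[-n]); yj <- c(ys[n], ys[-n])
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    yi <- ys[e]; yj_ <- yj[e]; xi <- xs[e]; xj_ <- xj[e]
    crosses <- ((yi > py) != (yj_ > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj_ - xi) / (yj_ - yi)
      hit <- crosses & (px < xint)
      inside <- xor(inside, hit)
    }
  }
  inside
}

#' Rasterize a structure onto a dose grid
#'
#' Contours are assigned to the nearest grid slice within half a slice
#' spacing; per slice, voxel centers inside the combined contours by the
#' even-odd (parity) rule are set, so nested contours punch holes.
#'
#' @param contours a structure: list of closed planar contour matrices
#'   (`n x 3`, mm), e.g. one element of [read_rtstruct()]
#' @param grid an `rtmc_dose_grid` (or any object with `dims`,
#'   `spacing_mm`, `origin_mm`)
#' @return logical array over the grid; attribute `empty_overlap = TRUE`
#'   with a warning if no contour maps onto any slice
#' @export
rasterize_structure <- function(contours, grid) {
  .validate_structure(contours)
  d <- grid$dims; sp <- grid$spacing_mm; o <- grid$origin_mm
  zc <- o[3] + (seq_len(d[3]) - 1) * sp[3]
  xc <- o[1] + (seq_len(d[1]) - 1) * sp[1]
  yc <- o[2] + (seq_len(d[2]) - 1) * sp[2]
  pts <- expand.grid(x = xc, y = yc)
  mask <- array(FALSE, dim = d)
  assigned <- FALSE
  for (m in contours) {
    z <- m[1, 3]
    k <- which.min(abs(zc - z))
    if (abs(zc[k] - z) > sp[3] / 2 + 1e-9) next
    assigned <- TRUE
    inside <- .pip_even_odd(pts$x, pts$y, m[, 1:2, drop = FALSE])
    mask[, , k] <- xor(mask[, , k], array(inside, dim = d[1:2]))
  }
  if (!assigned) {
    warn("structure does not overlap the grid: empty mask")
    attr(mask, "empty_overlap") <- TRUE
  }
  mask
}

#' Cumulative dose-volume histogram
#'
#' `volume_pct(d)` is the percentage of masked voxels receiving at least
#' dose `d`, evaluated on uniform bin edges from 0 to just above the
#' maximum dose (uniform voxel volume assumed within the grid).
#'
#' @param grid an `rtmc_dose_grid` with dose in Gy (apply calibration
#'   before evaluation)
#' @param mask logical array from [rasterize_structure()]
#' @param bin_width_gy histogram bin width (Gy), default 0.01
#' @return an `rtmc_dvh` tibble with columns `dose_gy`, `volume_pct`
#' @export
cumulative_dvh <- function(grid, mask, bin_width_gy = 0.01) {
  stopifnot(bin_width_gy > 0)
  if (!any(mask)) abort("empty mask", class = "rtmc_evaluation_error")
  doses <- grid$dose[mask]
  nbin <- ceiling(max(doses) / bin_width_gy) + 1
  edges <- (0:nbin) * bin_width_gy
  # fraction of voxels with dose >= edge
  cnt <- length(doses) - findInterval(edges - 1e-12, sort(doses))
  out <- tibble(dose_gy = edges, volume_pct = 100 * cnt / length(doses))
  class(out) <- c("rtmc_dvh", class(out))
  attr(out, "n_voxels") <- length(doses)
  attr(out, "voxel_volume_cm3") <- prod(grid$spacing_mm / 10)
  attr(out, "bin_width_gy") <- bin_width_gy
  out
}

#' Dose metrics from a cumulative DVH
#'
#' `Dmean` integrates the differential of the curve (mid-bin weighted);
#' `Dmax` is the highest bin edge with nonzero volume; `D95` is the maximum
#' dose covering at least 95% of the volume; `V_x` (for each `v_at_gy`) is
#' the volume percentage at dose x, linearly interpolated between bins and
#' clamped with a flag outside the curve range.
#'
#' @param curve an `rtmc_dvh`
#' @param d_at_pct coverage percentages for Dxx metrics (default 95)
#' @param v_at_gy dose levels (Gy) for Vx metrics
#' @return one-row tibble of metrics
#' @export
dose_metrics <- function(curve, d_at_pct = 95, v_at_gy = numeric(0)) {
  stopifnot(inherits(curve, "rtmc_dvh"))
  e <- curve$dose_gy; vf <- curve$volume_pct
  nz <- which(vf > 0)
  dmax <- if (length(nz)) e[max(nz)] else 0
  dvf <- -diff(vf) / 100
  mids <- (e[-1] + e[-length(e)]) / 2
  dmean <- sum(dvf * mids)
  out <- tibble(Dmean_gy = dmean, Dmax_gy = dmax)
  for (p in d_at_pct) {
    idx <- which(vf >= p)
    out[[sprintf("D%g_gy", p)]] <- if (length(idx)) e[max(idx)] else 0
  }
  clamped <- FALSE
  for (x in v_at_gy) {
    if (x > max(e)) { val <- 0; clamped <- TRUE }
    else if (x < 0) { val <- 100; clamped <- TRUE }
    else val <- approx(e, vf, xout = x)$y
    out[[sprintf("V%g_pct", x)]] <- val
  }
  attr(out, "clamped") <- clamped
  out
}
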